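#' Trimming configuration for vector-flank removal
#'
#' Reads of phagemid inserts carry vector sequence on both sides: the
#' forward sequencing-primer anchor, a short stretch of vector ("spacer"),
#' the insert, a 3' spacer and the reverse anchor (reverse complement of the
#' reverse primer). Trimming locates both anchors, verifies that the spacers
#' are intact — an expanded or truncated vector region would shift the
#' reading frame of the downstream analysis — and returns the interior
#' insert.
#'
#' @param forward_anchor Forward primer sequence as it appears at the 5' end
#'   of the read (default `GCTCAGCCGGCGATGG`).
#' @param reverse_anchor Reverse-complemented reverse primer as it appears
#'   near the 3' end of the read (default the reverse complement of
#'   `CAGCTCTGATATCTTTGGATCCC`).
#' @param five_prime_spacer,three_prime_spacer Vector sequence expected
#'   between each anchor and the insert. Their lengths define the expected
#'   geometry; their bases are checked so that indels in the vector region
#'   are caught.
#' @param max_anchor_mismatches Substitutions tolerated when locating each
#'   anchor (default 1). Indels are never tolerated.
#' @param max_spacer_mismatches Substitutions tolerated in each spacer
#'   (default 0: a frame-shifting indel slides insert bases into the spacer
#'   window and is rejected).
#' @return An object of class `trim_config`.
#' @export
trim_config <- function(forward_anchor = "GCTCAGCCGGCGATGG",
                        reverse_anchor = revcomp("CAGCTCTGATATCTTTGGATCCC"),
                        five_prime_spacer = "TGGCCCAG",
                        three_prime_spacer = "GGTGGA",
                        max_anchor_mismatches = 1L,
                        max_spacer_mismatches = 0L) {
  cfg <- list(
    forward_anchor = toupper(forward_anchor),
    reverse_anchor = toupper(reverse_anchor),
    five_prime_spacer = toupper(five_prime_spacer),
    three_prime_spacer = toupper(three_prime_spacer),
    max_anchor_mismatches = as.integer(max_anchor_mismatches),
    max_spacer_mismatches = as.integer(max_spacer_mismatches)
  )
  if (!nzchar(cfg$forward_anchor) || !nzchar(cfg$reverse_anchor)) {
    stop("anchors must be non-empty")
  }
  if (cfg$max_anchor_mismatches < 0 || cfg$max_spacer_mismatches < 0) {
    stop("mismatch budgets must be >= 0")
  }
  structure(cfg, class = "trim_config")
}

# positions (1-based) where `pattern` matches `subject` with <= max_mm
# substitutions, scanning left to right; returns the first best match
.match_with_mismatches <- function(subject, pattern, max_mm, from = 1L) {
  m <- nchar(pattern)
  L <- nchar(subject)
  if (from + m - 1L > L) return(NA_integer_)
  pos <- seq.int(from, L - m + 1L)
  mm <- integer(length(pos))
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  for (j in seq_len(m)) {
    mm <- mm + (substring(subject, pos + j - 1L, pos + j - 1L) != pat[j])
  }
  ok <- which(mm <= max_mm)
  if (!length(ok)) return(NA_integer_)
  best <- ok[which.min(mm[ok])]
  # prefer the leftmost among equally good matches
  best <- min(ok[mm[ok] == mm[best]])
  pos[best]
}

.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Trim vector flanks from one read
#'
#' Locates the forward and reverse anchors (each within the configured
#' substitution budget; the reverse complement of the read is tried once if
#' the forward anchor is absent), verifies both spacers, and returns the
#' insert between them. Reads whose vector region is truncated or expanded —
#' which would shift the reading frame — are rejected as
#' `"frame_shifted_vector"`.
#'
#' @param sequence Read sequence (single string).
#' @param config A [trim_config()].
#' @param id Optional read identifier, propagated to the result.
#' @return A list with `status = "ok"` and fields `id`, `insert`, `length`,
#'   or `status = "rejected"` with a `reason` among `"anchor_missing"`,
#'   `"frame_shifted_vector"`, `"empty_insert"`.
#' @examples
#' cfg <- trim_config()
#' read <- paste0(cfg$forward_anchor, cfg$five_prime_spacer, "ATGGCAA",
#'                cfg$three_prime_spacer, cfg$reverse_anchor)
#' trim_vector(read, cfg)$insert
#' @export
trim_vector <- function(sequence, config = trim_config(), id = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  fa <- .match_with_mismatches(s, config$forward_anchor,
                               config$max_anchor_mismatches)
  if (is.na(fa)) {
    s <- revcomp(s)
    fa <- .match_with_mismatches(s, config$forward_anchor,
                                 config$max_anchor_mismatches)
  }
  if (is.na(fa)) {
    return(list(status = "rejected", id = id, reason = "anchor_missing"))
  }
  fa_end <- fa + nchar(config$forward_anchor) - 1L
  ra <- .match_with_mismatches(s, config$reverse_anchor,
                               config$max_anchor_mismatches,
                               from = fa_end + 1L)
  if (is.na(ra)) {
    return(list(status = "rejected", id = id, reason = "anchor_missing"))
  }
  inner <- substring(s, fa_end + 1L, ra - 1L)
  len5 <- nchar(config$five_prime_spacer)
  len3 <- nchar(config$three_prime_spacer)
  if (nchar(inner) < len5 + len3) {
    return(list(status = "rejected", id = id, reason = "frame_shifted_vector"))
  }
  if (nchar(inner) == len5 + len3) {
    return(list(status = "rejected", id = id, reason = "empty_insert"))
  }
  sp5 <- substring(inner, 1L, len5)
  sp3 <- substring(inner, nchar(inner) - len3 + 1L, nchar(inner))
  if (.hamming(sp5, config$five_prime_spacer) > config$max_spacer_mismatches ||
      .hamming(sp3, config$three_prime_spacer) > config$max_spacer_mismatches) {
    return(list(status = "rejected", id = id, reason = "frame_shifted_vector"))
  }
  insert <- substring(inner, len5 + 1L, nchar(inner) - len3)
  list(status = "ok", id = id, insert = insert, length = nchar(insert))
}

#' Trim a set of reads
#'
#' @param reads Data frame with columns `id` and `sequence` (e.g. from
#'   [read_reads()]).
#' @param config A [trim_config()].
#' @return A list with `inserts` (data frame `id`, `sequence`, `length`),
#'   `rejected` (data frame `id`, `reason`) and a named integer vector
#'   `counts` over the rejection reasons plus `ok`.
#' @export
trim_reads <- function(reads, config = trim_config()) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  res <- lapply(seq_len(nrow(reads)), function(i) {
    trim_vector(reads$sequence[[i]], config, id = reads$id[[i]])
  })
  ok <- vapply(res, function(r) r$status == "ok", logical(1))
  inserts <- data.frame(
    id = vapply(res[ok], `[[`, character(1), "id"),
    sequence = vapply(res[ok], `[[`, character(1), "insert"),
    length = vapply(res[ok], `[[`, integer(1), "length"),
    stringsAsFactors = FALSE
  )
  rejected <- data.frame(
    id = vapply(res[!ok], `[[`, character(1), "id"),
    reason = vapply(res[!ok], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
  reasons <- c("anchor_missing", "frame_shifted_vector", "empty_insert")
  counts <- c(ok = sum(ok),
              table(factor(rejected$reason, levels = reasons)))
  list(inserts = inserts, rejected = rejected, counts = counts)
}

#' Decode a Phred+33 quality string to numeric scores
#'
#' @param quality Single quality string (Phred+33 / Sanger encoding).
#' @return Integer vector of Phred scores.
#' @export
decode_quality <- function(quality) {
  stopifnot(is.character(quality), length(quality) == 1L)
  utf8ToInt(quality) - 33L
}

#' Expected error rate of a read from its quality scores
#'
#' Each Phred score Q implies an error probability `10^(-Q/10)`; the read's
#' expected number of errors is the sum of these, and the expected error
#' *rate* divides by read length.
#'
#' @param qualities Numeric vector of Phred scores, or a single Phred+33
#'   quality string.
#' @param mode `"rate"` (default): expected errors per base; `"total"`:
#'   expected number of errors in the read.
#' @return A single number.
#' @examples
#' expected_error_rate(rep(30, 10))         # 0.001
#' expected_error_rate(c(10, 30, 30, 30))   # 0.02575
#' @export
expected_error_rate <- function(qualities, mode = c("rate", "total")) {
  mode <- match.arg(mode)
  if (is.character(qualities)) qualities <- decode_quality(qualities)
  if (length(qualities) == 0 || anyNA(qualities)) {
    stop("`qualities` must contain at least one Phred score")
  }
  ee <- sum(10^(-qualities / 10))
  if (mode == "rate") ee / length(qualities) else ee
}

#' Filter reads by expected error
#'
#' Keeps reads whose expected error rate is at or below the threshold
#' (strictly greater is discarded). Reads without quality strings (e.g. from
#' FASTA input) bypass the filter and are counted separately.
#'
#' @param reads Data frame with columns `id`, `sequence` and optionally
#'   `quality` (Phred+33 strings; `NA` allowed).
#' @param max_expected_error_rate Threshold (default 0.001, i.e. 0.1%).
#' @param mode Passed to [expected_error_rate()].
#' @return List with `kept` (data frame), `n_discarded` and
#'   `n_without_quality`.
#' @export
filter_reads <- function(reads, max_expected_error_rate = 0.001,
                         mode = c("rate", "total")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(reads))
  if (max_expected_error_rate <= 0 ||
      (mode == "rate" && max_expected_error_rate >= 1)) {
    stop("`max_expected_error_rate` must be in (0, 1)")
  }
  qual <- if ("quality" %in% names(reads)) reads$quality else
    rep(NA_character_, nrow(reads))
  has_q <- !is.na(qual) & nzchar(qual)
  ee <- rep(NA_real_, nrow(reads))
  ee[has_q] <- vapply(qual[has_q], expected_error_rate, numeric(1), mode = mode)
  keep <- !has_q | ee <= max_expected_error_rate
  list(
    kept = reads[keep, , drop = FALSE],
    n_discarded = sum(!keep),
    n_without_quality = sum(!has_q)
  )
}

#' Read sequencing reads from FASTQ or FASTA
#'
#' @param path Path to a FASTQ (Phred+33) or FASTA file.
#' @param format `"auto"` (by extension), `"fastq"` or `"fasta"`.
#' @return Data frame with columns `id`, `sequence` and `quality`
#'   (`NA` for FASTA input).
#' @export
read_reads <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (format == "fastq") {
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    data.frame(
      id = names(x),
      sequence = as.character(x),
      quality = as.character(Biostrings::quality(x)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    x <- Biostrings::readDNAStringSet(path)
    data.frame(
      id = names(x),
      sequence = as.character(x),
      quality = NA_character_,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
}

#' Write reads to FASTQ
#'
#' @param reads Data frame with `id`, `sequence`, `quality` columns.
#' @param path Output file path.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  q <- Biostrings::PhredQuality(reads$quality)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write insert sequences to FASTA
#'
#' @param inserts Data frame with `id` and `sequence` columns.
#' @param path Output file path.
#' @export
write_inserts_fasta <- function(inserts, path) {
  x <- Biostrings::DNAStringSet(inserts$sequence)
  names(x) <- inserts$id
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Write a classification table to TSV
#'
#' One row per insert: id, length, residue class, category, comma-joined
#' stop positions, rescue position and peptide.
#'
#' @param reports A `frame_report_set` from [classify_inserts()].
#' @param path Output file path.
#' @export
write_classification_tsv <- function(reports, path) {
  out <- data.frame(
    id = reports$insert_id,
    length = reports$length,
    residue_class = reports$residue_class,
    in_frame = reports$in_frame,
    category = reports$category,
    stop_positions = vapply(reports$stop_positions, paste,
                            character(1), collapse = ","),
    rescue_start_position = reports$rescue_start_position,
    potential_orf = reports$potential_orf,
    peptide = reports$peptide,
    copy_count = reports$copy_count,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a library profile to JSON
#'
#' @param profile A `library_profile` from [profile_library()].
#' @param path Output file path.
#' @export
write_profile_json <- function(profile, path) {
  x <- lapply(unclass(profile), function(v) {
    if (!is.null(names(v))) as.list(v) else v
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
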