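#' Residue class of an insert length
#'
#' Random fragmentation yields inserts of 3n, 3n + 1 and 3n + 2 nucleotides;
#' the class of `L %% 3` decides whether a blunt-cloned insert rejoins the
#' pIII reading frame.
#'
#' @param length Integer vector of insert lengths in nucleotides (>= 1).
#' @return Factor with levels `R0`, `R1`, `R2` (`R1` means `L %% 3 == 1`).
#' @examples
#' residue_class(c(7, 9, 476))
#' @export
residue_class <- function(length) {
  if (!is.numeric(length) || length(length) == 0 || anyNA(length) ||
      any(length < 1) || any(length != floor(length))) {
    stop("`length` must contain positive integers")
  }
  factor(paste0("R", as.integer(length) %% 3L), levels = c("R0", "R1", "R2"))
}

#' Scan an insert for in-frame stop codons
#'
#' Walks the insert from the 5' end in steps of one codon, starting at
#' position `scan_offset + 1`, and reports the first base of every codon that
#' matches a stop codon. Trailing bases that cannot form a complete
#' insert-internal codon are not scanned, and codons containing `N` never
#' count as stops.
#'
#' @param sequence Single nucleotide string over `A/C/G/T/N`.
#' @param model A [vector_frame_model()].
#' @return Integer vector of 1-based stop-codon start positions (possibly
#'   empty).
#' @examples
#' scan_stop_codons("TAATGA")   # both codons are stops
#' scan_stop_codons("ATAAGC")   # TAA present but out of the scanned frame
#' @export
scan_stop_codons <- function(sequence, model = vector_frame_model()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("`sequence` must be non-empty")
  L <- nchar(sequence)
  first <- model$scan_offset + 1L
  if (first + 2L > L) return(integer(0))
  starts <- seq.int(first, L - 2L, by = 3L)
  codons <- substring(sequence, starts, starts + 2L)
  starts[codons %in% model$stop_codons]
}

#' Find an alternative start codon able to rescue translation
#'
#' Searches the insert from the 3' end towards the 5' end for the 3'-most
#' start codon from which translation can still run into pIII in frame. A
#' position `p` qualifies when `(L - p + 1) %% 3 == required_residue` (the
#' fusion rejoins the vector frame); when, in strict mode, no stop codon lies
#' in the frame opened at `p` within the insert; and, for in-frame inserts,
#' when `p` lies in the scanned frame downstream of the last stop codon.
#'
#' @inheritParams scan_stop_codons
#' @return The 1-based position of the rescuing start codon, or `NA_integer_`
#'   if none qualifies.
#' @examples
#' find_rescuing_start("TAAATGGCAA")  # stop at 1, ATG at 4 rescues
#' find_rescuing_start("TAAA")        # no ATG: NA
#' @export
find_rescuing_start <- function(sequence, model = vector_frame_model()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  if (L < 3L) return(NA_integer_)
  in_frame <- (L %% 3L) == model$required_residue
  stops <- scan_stop_codons(sequence, model)
  last_stop <- if (length(stops)) max(stops) else 0L
  pos <- seq_len(L - 2L)
  cand <- pos[substring(sequence, pos, pos + 2L) == model$start_codon]
  cand <- cand[((L - cand + 1L) %% 3L) == model$required_residue]
  if (in_frame) {
    scan_frame <- (model$scan_offset + 1L) %% 3L
    cand <- cand[(cand %% 3L) == scan_frame & cand > last_stop]
  }
  if (!length(cand)) return(NA_integer_)
  for (p in sort(cand, decreasing = TRUE)) {  # 3'-most first
    if (model$rescue_mode == "presence") return(p)
    downstream <- seq.int(p, L - 2L, by = 3L)
    if (!any(substring(sequence, downstream, downstream + 2L) %in%
             model$stop_codons)) {
      return(p)
    }
  }
  NA_integer_
}

.orf_categories <- c("IN_FRAME_CLEAN", "IN_FRAME_RESCUED", "IN_FRAME_DEAD",
                     "OUT_FRAME_RESCUED", "OUT_FRAME_DEAD")
.potential_orf_categories <- c("IN_FRAME_CLEAN", "IN_FRAME_RESCUED",
                               "OUT_FRAME_RESCUED")

#' Classify a single insert by reading-frame fate
#'
#' Combines the length-residue rule, the stop-codon scan and the
#' alternative-start search into one of five categories:
#' * `IN_FRAME_CLEAN`: length in frame, no stop codon in the scanned frame;
#' * `IN_FRAME_RESCUED`: in-frame with stops, but an ATG in the scanned frame
#'   downstream of the last stop restores translation;
#' * `IN_FRAME_DEAD`: in-frame with stops and no rescue;
#' * `OUT_FRAME_RESCUED`: out-of-frame, but an internal ATG opens a
#'   stop-free frame that rejoins pIII;
#' * `OUT_FRAME_DEAD`: out-of-frame with no such start.
#' Inserts in the first, second and fourth categories carry a potential
#' oligopeptide::pIII gene product and their peptide is translated.
#'
#' @param sequence Single nucleotide string over `A/C/G/T/N`.
#' @param model A [vector_frame_model()].
#' @param id Optional insert identifier.
#' @param copy_count Copy count after dereplication (default 1).
#' @return An object of class `frame_report`: a list with `insert_id`,
#'   `sequence`, `length`, `copy_count`, `residue_class`, `in_frame`,
#'   `stop_positions`, `last_stop_position`, `rescue_start_position`,
#'   `category`, `potential_orf` and `peptide`.
#' @examples
#' classify_insert("ATGGCAA")$category     # IN_FRAME_CLEAN
#' classify_insert("TAAATGGCAA")$category  # IN_FRAME_RESCUED
#' @export
classify_insert <- function(sequence, model = vector_frame_model(),
                            id = NA_character_, copy_count = 1L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!.valid_insert_chars(sequence)) {
    stop("`sequence` must be non-empty and contain only A/C/G/T/N")
  }
  L <- nchar(sequence)
  rc <- as.character(residue_class(L))
  in_frame <- (L %% 3L) == model$required_residue
  stops <- scan_stop_codons(sequence, model)
  last_stop <- if (length(stops)) max(stops) else NA_integer_
  rescue <- NA_integer_
  if (in_frame && !length(stops)) {
    category <- "IN_FRAME_CLEAN"
  } else {
    rescue <- find_rescuing_start(sequence, model)
    category <- if (in_frame) {
      if (is.na(rescue)) "IN_FRAME_DEAD" else "IN_FRAME_RESCUED"
    } else {
      if (is.na(rescue)) "OUT_FRAME_DEAD" else "OUT_FRAME_RESCUED"
    }
  }
  potential_orf <- category %in% .potential_orf_categories
  peptide <- NA_character_
  if (potential_orf) {
    from <- if (category == "IN_FRAME_CLEAN") model$scan_offset + 1L else rescue
    peptide <- translate_from(sequence, from)
  }
  structure(
    list(
      insert_id = id,
      sequence = sequence,
      length = L,
      copy_count = as.integer(copy_count),
      residue_class = rc,
      in_frame = in_frame,
      stop_positions = stops,
      last_stop_position = last_stop,
      rescue_start_position = rescue,
      category = category,
      potential_orf = potential_orf,
      peptide = peptide
    ),
    class = "frame_report"
  )
}

#' @export
print.frame_report <- function(x, ...) {
  cat(sprintf("Frame report%s: %d nt, %s, %s\n",
              if (is.na(x$insert_id)) "" else paste0(" [", x$insert_id, "]"),
              x$length, x$residue_class, x$category))
  if (length(x$stop_positions)) {
    cat("  stop codons at:", paste(x$stop_positions, collapse = ", "), "\n")
  }
  if (!is.na(x$rescue_start_position)) {
    cat("  rescuing start at:", x$rescue_start_position, "\n")
  }
  if (!is.na(x$peptide)) cat("  peptide:", x$peptide, "\n")
  invisible(x)
}

#' Classify a set of inserts
#'
#' Vectorised driver over [classify_insert()].
#'
#' @param inserts Either a character vector of insert sequences (names used
#'   as ids when present) or a data frame with columns `id` and `sequence`
#'   (optionally `copy_count`).
#' @param model A [vector_frame_model()].
#' @return A data frame of class `frame_report_set`, one row per insert, with
#'   columns `insert_id`, `length`, `residue_class`, `in_frame`, `n_stops`,
#'   `last_stop_position`, `rescue_start_position`, `category`,
#'   `potential_orf`, `peptide`, `copy_count` and a list column
#'   `stop_positions`.
#' @examples
#' classify_inserts(c(a = "ATGGCAA", b = "TAAA"))
#' @export
classify_inserts <- function(inserts, model = vector_frame_model()) {
  if (is.data.frame(inserts)) {
    stopifnot(all(c("id", "sequence") %in% names(inserts)))
    ids <- as.character(inserts$id)
    seqs <- as.character(inserts$sequence)
    copies <- if ("copy_count" %in% names(inserts)) {
      as.integer(inserts$copy_count)
    } else {
      rep.int(1L, nrow(inserts))
    }
  } else {
    seqs <- as.character(inserts)
    ids <- if (!is.null(names(inserts))) names(inserts) else
      sprintf("insert_%d", seq_along(seqs))
    copies <- rep.int(1L, length(seqs))
  }
  reports <- lapply(seq_along(seqs), function(i) {
    classify_insert(seqs[[i]], model, id = ids[[i]], copy_count = copies[[i]])
  })
  out <- data.frame(
    insert_id = vapply(reports, `[[`, character(1), "insert_id"),
    length = vapply(reports, `[[`, integer(1), "length"),
    residue_class = vapply(reports, `[[`, character(1), "residue_class"),
    in_frame = vapply(reports, `[[`, logical(1), "in_frame"),
    n_stops = vapply(reports, function(r) length(r$stop_positions), integer(1)),
    last_stop_position = vapply(reports, `[[`, integer(1), "last_stop_position"),
    rescue_start_position = vapply(reports, `[[`, integer(1),
                                   "rescue_start_position"),
    category = vapply(reports, `[[`, character(1), "category"),
    potential_orf = vapply(reports, `[[`, logical(1), "potential_orf"),
    peptide = vapply(reports, `[[`, character(1), "peptide"),
    copy_count = vapply(reports, `[[`, integer(1), "copy_count"),
    stringsAsFactors = FALSE
  )
  out$stop_positions <- lapply(reports, `[[`, "stop_positions")
  class(out) <- c("frame_report_set", "data.frame")
  out
}

# translate complete codons from `from` through the last full insert codon;
# codons containing N (or otherwise untranslatable) become X
translate_from <- function(sequence, from) {
  L <- nchar(sequence)
  n_codons <- (L - from + 1L) %/% 3L
  if (n_codons < 1L) return("")
  starts <- from + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(sequence, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate the oligopeptide::pIII fusion encoded by a classified insert
#'
#' Translates from the scanned frame (clean in-frame inserts) or from the
#' rescuing start codon (rescued inserts) through the last complete
#' insert-internal codon, using the standard genetic code. Codons containing
#' `N` translate to `X`.
#'
#' @param report A `frame_report` from [classify_insert()] with
#'   `potential_orf = TRUE`.
#' @return Amino-acid string (may be `""` for inserts shorter than one codon).
#' @examples
#' translate_fusion(classify_insert("TAAATGGCAA"))  # "MA"
#' @export
translate_fusion <- function(report) {
  stopifnot(inherits(report, "frame_report"))
  if (!isTRUE(report$potential_orf)) {
    stop("`translate_fusion()` requires a report with a potential ORF")
  }
  report$peptide
}

#' Aggregate frame reports into a library profile
#'
#' @param reports A `frame_report_set` from [classify_inserts()].
#' @param weight_by_copies If `TRUE`, counts are weighted by `copy_count`
#'   (total reads); default `FALSE` counts unique inserts.
#' @return An object of class `library_profile` with `n_total`,
#'   `counts_by_residue`, `counts_by_category`, `stop_fraction_by_residue`
#'   (fraction of each residue class carrying at least one scanned stop),
#'   `rescue_fraction_in_frame_with_stop`, `alt_start_fraction_out_of_frame`
#'   (per out-of-frame residue class, the fraction rescued by an alternative
#'   start), `potential_orf_fraction` and length statistics.
#' @examples
#' rep <- classify_inserts(c("ATGGCAA", "TAAA", "TAAATGGCAA"))
#' profile_library(rep)$potential_orf_fraction  # 2/3
#' @export
profile_library <- function(reports, weight_by_copies = FALSE) {
  stopifnot(is.data.frame(reports))
  if (nrow(reports) == 0) stop("`reports` must be non-empty")
  w <- if (weight_by_copies) reports$copy_count else rep.int(1L, nrow(reports))
  n_total <- sum(w)
  rc <- factor(reports$residue_class, levels = c("R0", "R1", "R2"))
  cat_f <- factor(reports$category, levels = .orf_categories)
  counts_by_residue <- stats::setNames(
    as.numeric(tapply(w, rc, sum, default = 0)), levels(rc))
  counts_by_category <- stats::setNames(
    as.numeric(tapply(w, cat_f, sum, default = 0)), levels(cat_f))
  has_stop <- reports$n_stops > 0
  stop_fraction_by_residue <- vapply(levels(rc), function(cl) {
    sel <- rc == cl
    if (!any(sel)) return(NA_real_)
    sum(w[sel & has_stop]) / sum(w[sel])
  }, numeric(1))
  n_resc <- sum(w[reports$category == "IN_FRAME_RESCUED"])
  n_dead <- sum(w[reports$category == "IN_FRAME_DEAD"])
  rescue_fraction <- if (n_resc + n_dead > 0) n_resc / (n_resc + n_dead)
                     else NA_real_
  alt_start <- vapply(levels(rc), function(cl) {
    sel <- rc == cl & !reports$in_frame
    if (!any(sel)) return(NA_real_)
    sum(w[sel & reports$category == "OUT_FRAME_RESCUED"]) / sum(w[sel])
  }, numeric(1))
  structure(
    list(
      n_total = n_total,
      counts_by_residue = counts_by_residue,
      counts_by_category = counts_by_category,
      stop_fraction_by_residue = stop_fraction_by_residue,
      rescue_fraction_in_frame_with_stop = rescue_fraction,
      alt_start_fraction_out_of_frame = alt_start,
      potential_orf_fraction = sum(w[reports$potential_orf]) / n_total,
      length_mean = stats::weighted.mean(reports$length, w),
      length_min = min(reports$length),
      length_max = max(reports$length)
    ),
    class = "library_profile"
  )
}

#' @export
print.library_profile <- function(x, ...) {
  cat("ORFeome library profile (", x$n_total, " inserts )\n", sep = "")
  cat("  residue classes  :",
      paste(sprintf("%s %.1f%%", names(x$counts_by_residue),
                    100 * x$counts_by_residue / x$n_total), collapse = "  "),
      "\n")
  cat("  categories       :",
      paste(sprintf("%s %d", names(x$counts_by_category),
                    x$counts_by_category), collapse = "  "), "\n")
  cat(sprintf("  potential ORFs   : %.1f%%\n", 100 * x$potential_orf_fraction))
  if (!is.na(x$rescue_fraction_in_frame_with_stop)) {
    cat(sprintf("  in-frame rescues : %.1f%% of stop-carrying in-frame inserts\n",
                100 * x$rescue_fraction_in_frame_with_stop))
  }
  cat(sprintf("  insert length    : mean %.1f nt (range %d-%d)\n",
              x$length_mean, x$length_min, x$length_max))
  invisible(x)
}

#' Enumerate the configurations of non-directional blunt cloning
#'
#' A randomly fragmented coding sequence can enter the vector in two
#' orientations, cut in any of three phases relative to its source codon
#' boundaries, and with any of three length residues modulo 3. Only one of
#' the 2 x 3 x 3 = 18 equally likely configurations — forward orientation,
#' cut on a codon boundary, length residue matching the vector frame rule —
#' yields a continuous correct-frame fusion, the "one in eighteen" odds that
#' motivate ORF enrichment.
#'
#' @param required_residue The length residue the vector requires (default 1).
#' @return Data frame with 18 rows and columns `orientation`, `source_phase`,
#'   `length_residue` and `in_frame`; exactly one row has `in_frame = TRUE`.
#' @examples
#' cfg <- enumerate_cloning_configurations()
#' sum(cfg$in_frame) / nrow(cfg)  # 1/18
#' @export
enumerate_cloning_configurations <- function(required_residue = 1L) {
  required_residue <- as.integer(required_residue)
  stopifnot(required_residue %in% 0:2)
  grid <- expand.grid(
    orientation = c("forward", "reverse"),
    source_phase = 0:2,
    length_residue = 0:2,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  grid$in_frame <- grid$orientation == "forward" &
    grid$source_phase == 0L &
    grid$length_residue == required_residue
  grid
}
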