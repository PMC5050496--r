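#' Vector frame model for an ORFeome display phagemid
#'
#' Describes how insert coordinates relate to the reading frame of the
#' downstream pIII gene on the display vector. An insert of length `L` is
#' "in frame" when `L %% 3 == required_residue`: in the usual vector design
#' only inserts of `3n + 1` nucleotides fuse the oligopeptide to pIII without
#' a frameshift, so `required_residue = 1` is the default. Stop-codon scanning
#' proceeds codon-by-codon starting at insert position `scan_offset + 1`.
#'
#' @param upstream_flank Vector sequence immediately 5' of the insert
#'   (may be `""`). Informational; trimming uses [trim_config()].
#' @param downstream_flank Vector sequence immediately 3' of the insert.
#' @param required_residue Integer in `0:2`; the value of `L %% 3` that puts
#'   an insert in frame with pIII. Default `1` (the 3n + 1 rule).
#' @param scan_offset Integer in `0:2`; 0-based position inside the insert
#'   where the first scanned codon begins. Default `0`: the first insert base
#'   opens a codon, and junction codons spanning vector bases are not scanned.
#' @param stop_codons Character vector of stop trinucleotides
#'   (default `TAA`, `TGA`, `TAG`).
#' @param start_codon Trinucleotide recognised as a (rescuing) translation
#'   start; default `ATG`.
#' @param max_read_span Sequencing read-length ceiling in nucleotides
#'   (default 500); used by the read simulator.
#' @param rescue_mode `"strict"` (default) requires that no stop codon lies in
#'   the reading frame downstream of a rescuing start; `"presence"` only
#'   requires a frame-compatible start codon to exist.
#'
#' @return An object of class `vector_frame_model`.
#' @examples
#' m <- vector_frame_model()
#' m$required_residue
#' @export
vector_frame_model <- function(upstream_flank = "",
                               downstream_flank = "",
                               required_residue = 1L,
                               scan_offset = 0L,
                               stop_codons = c("TAA", "TGA", "TAG"),
                               start_codon = "ATG",
                               max_read_span = 500L,
                               rescue_mode = c("strict", "presence")) {
  rescue_mode <- match.arg(rescue_mode)
  required_residue <- as.integer(required_residue)
  scan_offset <- as.integer(scan_offset)
  if (!required_residue %in% 0:2) {
    stop("`required_residue` must be 0, 1 or 2")
  }
  if (!scan_offset %in% 0:2) {
    stop("`scan_offset` must be 0, 1 or 2")
  }
  stop_codons <- toupper(stop_codons)
  start_codon <- toupper(start_codon)
  if (!all(grepl("^[ACGT]{3}$", stop_codons))) {
    stop("stop codons must be trinucleotides over A/C/G/T")
  }
  if (!grepl("^[ACGT]{3}$", start_codon)) {
    stop("`start_codon` must be a trinucleotide over A/C/G/T")
  }
  if (start_codon %in% stop_codons) {
    stop("`start_codon` must not be a stop codon")
  }
  if (max_read_span < 1) {
    stop("`max_read_span` must be positive")
  }
  structure(
    list(
      upstream_flank = toupper(upstream_flank),
      downstream_flank = toupper(downstream_flank),
      required_residue = required_residue,
      scan_offset = scan_offset,
      stop_codons = stop_codons,
      start_codon = start_codon,
      max_read_span = as.integer(max_read_span),
      rescue_mode = rescue_mode
    ),
    class = "vector_frame_model"
  )
}

#' @export
print.vector_frame_model <- function(x, ...) {
  cat("Vector frame model\n")
  cat("  in-frame rule      : insert length %% 3 ==", x$required_residue, "\n")
  cat("  scan offset        :", x$scan_offset, "\n")
  cat("  stop codons        :", paste(x$stop_codons, collapse = ", "), "\n")
  cat("  start codon        :", x$start_codon, "\n")
  cat("  max read span (nt) :", x$max_read_span, "\n")
  cat("  rescue mode        :", x$rescue_mode, "\n")
  invisible(x)
}

# reverse complement over A/C/G/T/N without round-tripping through XStringSet
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

.valid_insert_chars <- function(sequence) {
  grepl("^[ACGTN]+$", sequence)
}
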