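#' Dereplicate sequences into a unique set with copy counts
#'
#' Exact-match grouping of nucleotide or peptide sequences, preserving read
#' counts — the first step when comparing unique reads across samples or
#' replicates.
#'
#' @param sequences Character vector of sequences (reads or peptides).
#' @param level `"nucleotide"` or `"peptide"`; recorded on the result.
#' @return An object of class `unique_set`: list with `level`, `counts`
#'   (named integer vector, sorted by decreasing count then sequence) and
#'   `n_total`.
#' @examples
#' dereplicate(c("A", "A", "B"))$counts
#' @export
dereplicate <- function(sequences, level = c("nucleotide", "peptide")) {
  level <- match.arg(level)
  sequences <- as.character(sequences)
  if (length(sequences) == 0) {
    counts <- integer(0)
  } else {
    tab <- table(sequences)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    counts <- counts[order(-counts, names(counts))]
  }
  structure(
    list(level = level, counts = counts, n_total = length(sequences)),
    class = "unique_set"
  )
}

#' @export
print.unique_set <- function(x, ...) {
  cat(sprintf("Unique %s set: %d unique / %d total\n",
              x$level, length(x$counts), x$n_total))
  invisible(x)
}

#' Redundancy statistics of a dereplicated set
#'
#' A sequence is redundant when it was read more than once. Reports the
#' fraction of total reads that fall on redundant sequences, the median copy
#' number among redundant sequences (lower midpoint for even counts) and the
#' maximum copy number.
#'
#' @param uset A `unique_set` from [dereplicate()].
#' @return List with `redundant_read_fraction`, `median_copy_number`
#'   (`NA` when no sequence is redundant) and `max_copy_number`.
#' @examples
#' redundancy_stats(dereplicate(c("A", "A", "B")))
#' @export
redundancy_stats <- function(uset) {
  stopifnot(inherits(uset, "unique_set"))
  if (uset$n_total < 1) stop("`uset` must contain at least one read")
  counts <- uset$counts
  red <- counts[counts >= 2L]
  median_copy <- if (length(red)) {
    s <- sort(red)
    as.numeric(s[floor((length(s) + 1) / 2)])  # lower midpoint when even
  } else {
    NA_real_
  }
  list(
    redundant_read_fraction = sum(red) / uset$n_total,
    median_copy_number = median_copy,
    max_copy_number = if (length(counts)) max(counts) else 0L
  )
}

#' Share of total reads held by the n most abundant sequences
#'
#' @param uset A `unique_set` from [dereplicate()].
#' @param n Number of top sequences (>= 1); ties are broken by lexicographic
#'   sequence order so the result is deterministic.
#' @return Fraction of total reads in `[0, 1]` (1 when `n` exceeds the number
#'   of unique sequences).
#' @examples
#' top_n_share(dereplicate(c("A","A","A","A","A","B","B","B","C","C")), 1)
#' @export
top_n_share <- function(uset, n) {
  stopifnot(inherits(uset, "unique_set"), n >= 1)
  if (uset$n_total < 1) stop("`uset` must contain at least one read")
  counts <- uset$counts[order(-uset$counts, names(uset$counts))]
  sum(utils::head(counts, n)) / uset$n_total
}

#' Venn overlap of three replicate unique sets
#'
#' Membership-based (counts ignored) partition of the union of unique
#' sequences across three replicates into the seven exclusive Venn regions,
#' with fractions relative to the union size.
#'
#' @param sets List of exactly three `unique_set` objects at the same level.
#' @return An object of class `overlap_report`: list with `region_counts`
#'   (named over `A_only`, `B_only`, `C_only`, `AB_only`, `AC_only`,
#'   `BC_only`, `ABC`), `union_size` and `fractions`.
#' @examples
#' s <- lapply(list(c("A","B"), c("B","C"), "B"), dereplicate)
#' replicate_overlap(s)$fractions[["ABC"]]  # 1/3
#' @export
replicate_overlap <- function(sets) {
  if (!is.list(sets) || length(sets) != 3 ||
      !all(vapply(sets, inherits, logical(1), "unique_set"))) {
    stop("`sets` must be a list of exactly three unique_set objects")
  }
  levels_ <- vapply(sets, `[[`, character(1), "level")
  if (length(unique(levels_)) != 1) {
    stop("all three sets must be dereplicated at the same level")
  }
  a <- names(sets[[1]]$counts)
  b <- names(sets[[2]]$counts)
  c_ <- names(sets[[3]]$counts)
  u <- union(union(a, b), c_)
  in_a <- u %in% a
  in_b <- u %in% b
  in_c <- u %in% c_
  region_counts <- c(
    A_only = sum(in_a & !in_b & !in_c),
    B_only = sum(!in_a & in_b & !in_c),
    C_only = sum(!in_a & !in_b & in_c),
    AB_only = sum(in_a & in_b & !in_c),
    AC_only = sum(in_a & !in_b & in_c),
    BC_only = sum(!in_a & in_b & in_c),
    ABC = sum(in_a & in_b & in_c)
  )
  union_size <- length(u)
  structure(
    list(
      region_counts = region_counts,
      union_size = union_size,
      fractions = if (union_size > 0) region_counts / union_size
                  else region_counts * NA_real_
    ),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Replicate overlap over", x$union_size, "unique sequences\n")
  for (r in names(x$region_counts)) {
    cat(sprintf("  %-8s %7d  (%.1f%%)\n", r, x$region_counts[[r]],
                100 * x$fractions[[r]]))
  }
  invisible(x)
}

#' Shannon effective number of a count vector
#'
#' The exponential of the Shannon entropy (natural log) over relative
#' abundances: the number of equally abundant categories that would give the
#' same entropy.
#'
#' @param counts Non-negative abundance vector with at least one positive
#'   entry; zero categories are omitted.
#' @return Effective count in `[1, number of nonzero categories]`.
#' @examples
#' shannon_effective(c(10, 10, 10, 10))  # 4
#' shannon_effective(c(8, 2))            # about 1.649
#' @export
shannon_effective <- function(counts) {
  if (!is.numeric(counts) || length(counts) == 0 || anyNA(counts) ||
      any(counts < 0)) {
    stop("`counts` must be non-negative numbers")
  }
  counts <- counts[counts > 0]
  if (!length(counts)) stop("`counts` must contain at least one positive value")
  p <- counts / sum(counts)
  exp(-sum(p * log(p)))
}
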