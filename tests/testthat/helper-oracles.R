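# Independent oracles used to cross-check the implementation.

# Brute-force frame classifier: enumerates every candidate translation start
# (the scanned-frame origin and every ATG position) and checks the frame
# arithmetic and stop content of each directly, via strsplit-based codon
# lists rather than the package's position stepping.
oracle_classify <- function(sequence, required_residue = 1L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  stops <- c("TAA", "TGA", "TAG")
  codons_from <- function(p) {
    n <- (L - p + 1L) %/% 3L
    if (n < 1L) return(character(0))
    vapply(seq_len(n), function(k) {
      paste(chars[(p + 3L * (k - 1L)):(p + 3L * (k - 1L) + 2L)],
            collapse = "")
    }, character(1))
  }
  frame_ok <- function(p) ((L - p + 1L) %% 3L) == required_residue
  stop_free <- function(p) !any(codons_from(p) %in% stops)
  atg <- integer(0)
  if (L >= 3L) {
    for (p in 1:(L - 2L)) {
      if (paste(chars[p:(p + 2L)], collapse = "") == "ATG") atg <- c(atg, p)
    }
  }
  in_frame <- (L %% 3L) == required_residue
  scan_stops <- which(codons_from(1L) %in% stops)  # codon indices
  if (in_frame) {
    if (!length(scan_stops)) return("IN_FRAME_CLEAN")
    last_stop_pos <- 1L + 3L * (max(scan_stops) - 1L)
    ok <- vapply(atg, function(p) {
      (p %% 3L) == 1L && p > last_stop_pos && frame_ok(p) && stop_free(p)
    }, logical(1))
    if (any(ok)) "IN_FRAME_RESCUED" else "IN_FRAME_DEAD"
  } else {
    ok <- vapply(atg, function(p) frame_ok(p) && stop_free(p), logical(1))
    if (length(ok) && any(ok)) "OUT_FRAME_RESCUED" else "OUT_FRAME_DEAD"
  }
}

random_inserts <- function(n, max_len = 60L, min_len = 1L, seed = 1L) {
  set.seed(seed)
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# Exact two-sided rank-sum p-value by full enumeration of rank assignments.
oracle_mann_whitney_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}
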