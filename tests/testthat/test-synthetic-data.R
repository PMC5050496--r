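test_that("metagenome generation honours GC content and seeds", {
  cfg <- synthetic_config(n_genomes = 1L, genome_length = 10000L,
                          gc_content = 0.5, seed = 4L)
  g <- generate_metagenome(cfg)
  gc <- sum(strsplit(g[[1]], "")[[1]] %in% c("G", "C")) / nchar(g[[1]])
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(gc - 0.5), 3 * se)
  expect_identical(g, generate_metagenome(cfg))

  at_only <- generate_metagenome(synthetic_config(n_genomes = 1L,
                                                  genome_length = 2000L,
                                                  gc_content = 0, seed = 4L))
  expect_false(grepl("[GC]", at_only[[1]]))
})

test_that("fragmentation respects the size window and samples evenly", {
  cfg <- synthetic_config(n_clones = 3000L, seed = 11L)
  clones <- fragment_and_clone(generate_metagenome(cfg), cfg)
  expect_equal(nrow(clones), 3000L)
  expect_true(all(clones$length >= cfg$fragment_min &
                    clones$length <= cfg$fragment_max))
  expect_equal(clones$length, nchar(clones$sequence))
  expect_equal(clones$length, clones$end - clones$start + 1L)

  # orientations near 1/2 and residue classes near 1/3, within 3 SE
  p_rev <- mean(clones$orientation == "reverse")
  expect_lt(abs(p_rev - 0.5), 3 * sqrt(0.25 / 3000))
  se3 <- sqrt((1 / 3) * (2 / 3) / 3000)
  for (r in 0:2) {
    expect_lt(abs(mean(clones$length %% 3 == r) - 1 / 3), 3 * se3)
  }
  # forward clones equal their source substring; reverse ones its complement
  g <- generate_metagenome(cfg)
  i_fwd <- which(clones$orientation == "forward")[1]
  expect_equal(clones$sequence[i_fwd],
               substring(g[[clones$source_genome[i_fwd]]],
                         clones$start[i_fwd], clones$end[i_fwd]))
  i_rev <- which(clones$orientation == "reverse")[1]
  expect_equal(clones$sequence[i_rev],
               orfdisplay:::revcomp(substring(g[[clones$source_genome[i_rev]]],
                                              clones$start[i_rev],
                                              clones$end[i_rev])))
  # ground truth matches the classifier
  expect_equal(clones$truth_category[1:50],
               classify_inserts(clones$sequence[1:50])$category)
})

test_that("ORF enrichment is all-or-nothing plus leakiness", {
  cfg <- synthetic_config(n_clones = 1200L, seed = 8L)
  clones <- fragment_and_clone(generate_metagenome(cfg), cfg)
  strict <- orf_enrich(clones, leakiness = 0, seed = 1)
  expect_true(all(strict$truth_potential_orf))
  everyone <- orf_enrich(clones, leakiness = 1, seed = 1)
  expect_equal(nrow(everyone), nrow(clones))
  expect_error(orf_enrich(clones, leakiness = 1.5), "leakiness")
  # leakiness admits non-ORF clones at about the configured rate
  leaky <- orf_enrich(clones, leakiness = 0.5, seed = 2)
  n_junk <- sum(!clones$truth_potential_orf)
  p_junk <- sum(!leaky$truth_potential_orf) / n_junk
  expect_lt(abs(p_junk - 0.5), 3 * sqrt(0.25 / n_junk))
})

test_that("simulated reads round-trip through trimming when error-free", {
  cfg <- synthetic_config(n_clones = 150L, read_error_rate = 0,
                          vector_anomaly_rate = 0, seed = 13L)
  tcfg <- trim_config()
  clones <- fragment_and_clone(generate_metagenome(cfg), cfg)
  reads <- simulate_reads(clones, cfg, tcfg)
  full <- !reads$truncated
  out <- trim_reads(reads[full, ], tcfg)
  expect_equal(nrow(out$rejected), 0L)
  expect_equal(out$inserts$sequence, clones$sequence[full])
})

test_that("reads are truncated at the span ceiling and carry matching quality", {
  cfg <- synthetic_config(read_error_rate = 0.01, vector_anomaly_rate = 0,
                          max_read_span = 500L, seed = 2L)
  tcfg <- trim_config()
  long_clone <- data.frame(clone_id = "c1",
                           sequence = strrep("ACGT", 150),  # 600 nt insert
                           stringsAsFactors = FALSE)
  rd <- simulate_reads(long_clone, cfg, tcfg)
  expect_equal(nchar(rd$sequence), 500L)
  expect_true(rd$truncated)
  # constant qualities encode the configured error rate (Q20 here)
  expect_equal(expected_error_rate(rd$quality), 0.01)
})

test_that("read errors appear at about the configured rate", {
  cfg <- synthetic_config(n_clones = 60L, read_error_rate = 0.01,
                          vector_anomaly_rate = 0, seed = 19L)
  tcfg <- trim_config()
  clones <- fragment_and_clone(generate_metagenome(cfg), cfg)
  reads <- simulate_reads(clones, cfg, tcfg)
  truth <- paste0(tcfg$forward_anchor, tcfg$five_prime_spacer,
                  clones$sequence, tcfg$three_prime_spacer,
                  tcfg$reverse_anchor)
  truth <- substring(truth, 1, cfg$max_read_span)
  mm <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, reads$sequence, truth)
  rate <- sum(mm) / sum(nchar(truth))
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / sum(nchar(truth))))
})

test_that("vector anomalies make reads untrimmable at about the set rate", {
  cfg <- synthetic_config(n_clones = 400L, read_error_rate = 0,
                          vector_anomaly_rate = 0.5, seed = 23L)
  tcfg <- trim_config()
  clones <- fragment_and_clone(generate_metagenome(cfg), cfg)
  reads <- simulate_reads(clones, cfg, tcfg)
  expect_lt(abs(mean(reads$anomalous) - 0.5), 3 * sqrt(0.25 / 400))
  out <- trim_reads(reads[reads$anomalous & !reads$truncated, ], tcfg)
  expect_gt(mean(out$rejected$reason == "frame_shifted_vector"), 0.9)
})

test_that("panning enrichment follows affinity-weighted resampling", {
  lib <- c(a = 10, b = 10)
  cfg <- panning_config(affinities = c(a = 1, b = 0), background = 0,
                        rounds = 1L, phage_per_round = 1000L,
                        colonies_screened = 10L, seed = 5L)
  res <- simulate_panning(lib, cfg)
  expect_equal(unname(res$trajectory["round_1", ]), c(1, 0))
  expect_true(all(names(res$screened) == "a"))

  # a single clone keeps its composition across rounds
  solo <- simulate_panning(c(only = 5),
                           panning_config(affinities = c(only = 2),
                                          rounds = 3L, seed = 1L))
  expect_true(all(solo$trajectory == 1))

  # zero rounds: output equals input proportions
  none <- simulate_panning(c(a = 3, b = 1),
                           panning_config(affinities = c(a = 1, b = 1),
                                          rounds = 0L, seed = 1L))
  expect_equal(unname(none$trajectory["round_0", ]), c(0.75, 0.25))

  # probability conservation every round
  set.seed(1)
  lib2 <- stats::setNames(stats::rpois(12, 40) + 1, sprintf("c%02d", 1:12))
  aff2 <- stats::setNames(stats::runif(12), names(lib2))
  traj <- simulate_panning(lib2, panning_config(aff2, rounds = 4L,
                                                seed = 3L))$trajectory
  expect_equal(unname(rowSums(traj)), rep(1, 5))

  expect_error(simulate_panning(c(a = 1), panning_config(c(a = 0),
                                                         background = 0)),
               "positive")
})

test_that("screened colonies yield hit-redundancy counts", {
  lib <- stats::setNames(rep(1, 50), sprintf("c%02d", 1:50))
  aff <- stats::setNames(c(5, rep(0.1, 49)), names(lib))
  res <- simulate_panning(lib, panning_config(aff, background = 0.01,
                                              rounds = 3L,
                                              colonies_screened = 92L,
                                              seed = 7L))
  expect_equal(sum(res$screened), 92L)
  expect_equal(res$hit_redundancy, sort(as.integer(res$screened),
                                        decreasing = TRUE))
})

test_that("serology simulation has exact structure in the noise-free case", {
  tab <- simulate_serology(5, 5, effect = 0.4, noise_sd = 0,
                           background_sd = 0.05, seed = 3L)
  corr <- background_subtract(tab)
  expect_equal(corr$corrected_od[corr$cohort == "case"], rep(0.4, 5))
  expect_equal(corr$corrected_od[corr$cohort == "control"], rep(0, 5))
  # reproducible under the same seed
  expect_identical(tab, simulate_serology(5, 5, effect = 0.4, noise_sd = 0,
                                          background_sd = 0.05, seed = 3L))
  expect_equal(nrow(tab), 10L)
  expect_equal(sum(tab$cohort == "case"), 5L)
})

test_that("generator stages are bit-reproducible and stream-independent", {
  cfg <- synthetic_config(n_clones = 100L, seed = 77L)
  run1 <- simulate_library(cfg)
  run2 <- simulate_library(cfg)
  expect_identical(run1$reads$sequence, run2$reads$sequence)
  expect_identical(run1$clones, run2$clones)
  # clone stream does not depend on how many genomes draws were consumed
  g <- generate_metagenome(cfg)
  set.seed(999)  # disturb the global stream
  stats::runif(1000)
  clones_again <- fragment_and_clone(g, cfg)
  expect_identical(run1$clones, clones_again)
})
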