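#' Configuration of the synthetic library generator
#'
#' Parameters of the simulated library-construction chain: random metagenome,
#' sonication-style fragmentation into 200-1500 bp pieces, blunt
#' non-directional cloning, ORF-enrichment survival during phage packaging,
#' and amplicon sequencing of the insert with a ~500 nt read ceiling.
#'
#' @param n_genomes Number of synthetic genomes in the metagenome (default 3).
#' @param genome_length Length of each genome in nt (default 50000).
#' @param gc_content GC fraction of the i.i.d. genome model (default 0.5).
#' @param fragment_min,fragment_max Fragmentation size window in nt
#'   (defaults 200 and 1500, the gel-checked window). `fragment_min` may be
#'   lowered (down to 8 nt) to emulate the small inserts observed after
#'   enrichment.
#' @param insert_meanlog,insert_sdlog Log-normal parameters of the insert
#'   length distribution before truncation to the window; defaults
#'   `log(300)` and `0.45` give a pre-enrichment mean insert near 300 bp.
#' @param n_clones Number of clones to draw (default 10000).
#' @param enrichment_leakiness Probability that a clone without a potential
#'   ORF survives packaging anyway (default 0: all-or-nothing enrichment).
#' @param read_error_rate Per-base substitution rate of simulated reads
#'   (default 0.001).
#' @param vector_anomaly_rate Fraction of reads carrying a one-base indel in
#'   the vector spacer (default 0.04, the typical share of frame-shifted
#'   vector reads).
#' @param max_read_span Read-length ceiling in nt (default 500).
#' @param seed Base seed; per-stage streams are derived from it so that one
#'   stage's draw count does not perturb the others.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genomes = 3L,
                             genome_length = 50000L,
                             gc_content = 0.5,
                             fragment_min = 200L,
                             fragment_max = 1500L,
                             insert_meanlog = log(300),
                             insert_sdlog = 0.45,
                             n_clones = 10000L,
                             enrichment_leakiness = 0,
                             read_error_rate = 0.001,
                             vector_anomaly_rate = 0.04,
                             max_read_span = 500L,
                             seed = 1L) {
  cfg <- list(
    n_genomes = as.integer(n_genomes),
    genome_length = as.integer(genome_length),
    gc_content = gc_content,
    fragment_min = as.integer(fragment_min),
    fragment_max = as.integer(fragment_max),
    insert_meanlog = insert_meanlog,
    insert_sdlog = insert_sdlog,
    n_clones = as.integer(n_clones),
    enrichment_leakiness = enrichment_leakiness,
    read_error_rate = read_error_rate,
    vector_anomaly_rate = vector_anomaly_rate,
    max_read_span = as.integer(max_read_span),
    seed = as.integer(seed)
  )
  if (cfg$fragment_min < 1 || cfg$fragment_min >= cfg$fragment_max) {
    stop("need 1 <= fragment_min < fragment_max")
  }
  if (cfg$gc_content < 0 || cfg$gc_content > 1) {
    stop("`gc_content` must be in [0, 1]")
  }
  if (cfg$enrichment_leakiness < 0 || cfg$enrichment_leakiness > 1) {
    stop("`enrichment_leakiness` must be in [0, 1]")
  }
  if (cfg$fragment_max > cfg$genome_length) {
    stop("`fragment_max` must not exceed `genome_length`")
  }
  structure(cfg, class = "synthetic_config")
}

# derived per-stage seeds keep the stage streams independent
stage_seed <- function(seed, stage) {
  offsets <- c(metagenome = 1L, clones = 2L, enrich = 3L, reads = 4L,
               panning = 5L, serology = 6L)
  as.integer((as.numeric(seed) + offsets[[stage]] * 1000003) %% 2147483629)
}

#' Generate a synthetic metagenome
#'
#' I.i.d. nucleotides at the configured GC content; a deliberately featureless
#' stand-in for caecal metagenomic DNA that makes frame statistics analytic.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional seed override (default derived from `config$seed`).
#' @return Named character vector of genome sequences.
#' @export
generate_metagenome <- function(config = synthetic_config(), seed = NULL) {
  set.seed(if (is.null(seed)) stage_seed(config$seed, "metagenome") else seed)
  gc <- config$gc_content
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  genomes <- vapply(seq_len(config$n_genomes), function(i) {
    paste(sample(names(probs), config$genome_length, replace = TRUE,
                 prob = probs), collapse = "")
  }, character(1))
  names(genomes) <- sprintf("genome_%d", seq_len(config$n_genomes))
  genomes
}

#' Fragment genomes and clone inserts non-directionally
#'
#' Draws insert lengths from the truncated log-normal, start positions
#' uniformly within each genome, and orientation uniformly over forward /
#' reverse (blunt cloning is non-directional). Each clone's ground-truth
#' frame category is computed with [classify_insert()].
#'
#' @param genomes Named character vector from [generate_metagenome()].
#' @param config A [synthetic_config()].
#' @param model A [vector_frame_model()] used for the ground truth.
#' @param seed Optional seed override.
#' @return Data frame of clones: `clone_id`, `source_genome`, `start`, `end`
#'   (1-based inclusive on the source), `orientation`, `sequence`, `length`,
#'   `truth_category`, `truth_potential_orf`.
#' @export
fragment_and_clone <- function(genomes, config = synthetic_config(),
                               model = vector_frame_model(), seed = NULL) {
  stopifnot(length(genomes) >= 1)
  set.seed(if (is.null(seed)) stage_seed(config$seed, "clones") else seed)
  n <- config$n_clones
  lengths <- integer(0)
  while (length(lengths) < n) {
    draw <- round(stats::rlnorm(2L * n, config$insert_meanlog,
                                config$insert_sdlog))
    draw <- draw[draw >= config$fragment_min & draw <= config$fragment_max]
    lengths <- c(lengths, as.integer(draw))
  }
  lengths <- lengths[seq_len(n)]
  gidx <- sample.int(length(genomes), n, replace = TRUE)
  glen <- nchar(genomes)[gidx]
  start <- floor(stats::runif(n, min = 1, max = glen - lengths + 1 + 1))
  start <- pmin(as.integer(start), glen - lengths + 1L)
  end <- start + lengths - 1L
  orientation <- sample(c("forward", "reverse"), n, replace = TRUE)
  seqs <- substring(genomes[gidx], start, end)
  rev_sel <- orientation == "reverse"
  seqs[rev_sel] <- revcomp(seqs[rev_sel])
  truth <- classify_inserts(stats::setNames(seqs, sprintf("clone_%05d",
                                                          seq_len(n))), model)
  data.frame(
    clone_id = sprintf("clone_%05d", seq_len(n)),
    source_genome = names(genomes)[gidx],
    start = start,
    end = end,
    orientation = orientation,
    sequence = seqs,
    length = lengths,
    truth_category = truth$category,
    truth_potential_orf = truth$potential_orf,
    stringsAsFactors = FALSE
  )
}

#' ORF-enrichment survival during phage packaging
#'
#' With a helper phage lacking its own pIII gene, only clones whose insert
#' can still be translated into an oligopeptide::pIII fusion yield infective
#' particles. Clones with a potential ORF survive with probability 1; all
#' others survive with the leakiness probability.
#'
#' @param clones Data frame from [fragment_and_clone()].
#' @param leakiness Survival probability of non-ORF clones in `[0, 1]`.
#' @param seed Seed for the survival draws.
#' @return The surviving subset of `clones`.
#' @export
orf_enrich <- function(clones, leakiness = 0, seed = 1L) {
  stopifnot(is.data.frame(clones), leakiness >= 0, leakiness <= 1)
  set.seed(seed)
  survive <- clones$truth_potential_orf |
    (stats::runif(nrow(clones)) < leakiness)
  clones[survive, , drop = FALSE]
}

#' Simulate merged amplicon reads of cloned inserts
#'
#' Each read is anchor + spacer + insert + spacer + anchor, truncated at the
#' read-length ceiling, with i.i.d. substitution errors and constant Phred
#' qualities matching the configured error rate. A configurable fraction of
#' reads carries a one-base insertion or deletion in the 5' spacer,
#' emulating the frame-shifted vector reads that trimming must reject.
#'
#' @param clones Data frame with `clone_id` and `sequence` columns.
#' @param config A [synthetic_config()].
#' @param trim A [trim_config()] supplying the vector flanks.
#' @param seed Optional seed override.
#' @return Data frame with `id`, `clone_id`, `sequence`, `quality`,
#'   `anomalous` (logical) and `truncated` (logical).
#' @export
simulate_reads <- function(clones, config = synthetic_config(),
                           trim = trim_config(), seed = NULL) {
  stopifnot(is.data.frame(clones), nrow(clones) >= 1)
  set.seed(if (is.null(seed)) stage_seed(config$seed, "reads") else seed)
  n <- nrow(clones)
  left <- paste0(trim$forward_anchor, trim$five_prime_spacer)
  right <- paste0(trim$three_prime_spacer, trim$reverse_anchor)
  reads <- paste0(left, clones$sequence, right)
  anomalous <- stats::runif(n) < config$vector_anomaly_rate
  sp_start <- nchar(trim$forward_anchor) + 1L
  sp_end <- nchar(left)
  for (i in which(anomalous)) {
    p <- sample(sp_start:sp_end, 1L)
    if (stats::runif(1) < 0.5) {  # deletion
      reads[i] <- paste0(substring(reads[i], 1L, p - 1L),
                         substring(reads[i], p + 1L))
    } else {                      # insertion
      reads[i] <- paste0(substring(reads[i], 1L, p),
                         sample(c("A", "C", "G", "T"), 1L),
                         substring(reads[i], p + 1L))
    }
  }
  truncated <- nchar(reads) > config$max_read_span
  reads[truncated] <- substring(reads[truncated], 1L, config$max_read_span)
  if (config$read_error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    n_err <- stats::rbinom(n, nchar(reads), config$read_error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(nchar(reads[i]), n_err[i])
      chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      for (p in pos) {
        chars[p] <- sample(setdiff(bases, chars[p]), 1L)
      }
      reads[i] <- paste(chars, collapse = "")
    }
  }
  q <- if (config$read_error_rate > 0) {
    as.integer(round(-10 * log10(config$read_error_rate)))
  } else {
    40L
  }
  quality <- strrep(intToUtf8(q + 33L), nchar(reads))
  data.frame(
    id = sprintf("read_%05d", seq_len(n)),
    clone_id = clones$clone_id,
    sequence = reads,
    quality = quality,
    anomalous = anomalous,
    truncated = truncated,
    stringsAsFactors = FALSE
  )
}

#' Run the full synthetic chain
#'
#' Convenience wrapper: metagenome, fragmentation and cloning, ORF
#' enrichment, and read simulation, each on its own derived random stream.
#'
#' @param config A [synthetic_config()].
#' @param model A [vector_frame_model()].
#' @param trim A [trim_config()].
#' @return List with `genomes`, `clones`, `survivors` and `reads`.
#' @export
simulate_library <- function(config = synthetic_config(),
                             model = vector_frame_model(),
                             trim = trim_config()) {
  genomes <- generate_metagenome(config)
  clones <- fragment_and_clone(genomes, config, model)
  survivors <- orf_enrich(clones, config$enrichment_leakiness,
                          seed = stage_seed(config$seed, "enrich"))
  reads <- simulate_reads(survivors, config, trim)
  list(genomes = genomes, clones = clones, survivors = survivors,
       reads = reads)
}

#' Configuration of a biopanning simulation
#'
#' @param affinities Named non-negative numeric vector: per-clone binding
#'   weight towards the immobilised serum antibodies.
#' @param background Non-negative background binding weight shared by all
#'   clones (default 0.01): even non-binders are carried through washing at
#'   a low rate.
#' @param rounds Number of panning rounds (default 3).
#' @param phage_per_round Phage sampled into each round (default 1e5).
#' @param colonies_screened Colonies picked for monoclonal screening after
#'   the last round (default 92).
#' @param seed Seed for the resampling draws.
#' @return An object of class `panning_config`.
#' @export
panning_config <- function(affinities, background = 0.01, rounds = 3L,
                           phage_per_round = 100000L,
                           colonies_screened = 92L, seed = 1L) {
  stopifnot(is.numeric(affinities), length(affinities) >= 1,
            !is.null(names(affinities)), all(affinities >= 0),
            background >= 0, rounds >= 0)
  if (all(affinities + background == 0)) {
    stop("at least one clone must have positive affinity or background")
  }
  structure(
    list(affinities = affinities, background = background,
         rounds = as.integer(rounds),
         phage_per_round = as.integer(phage_per_round),
         colonies_screened = as.integer(colonies_screened),
         seed = as.integer(seed)),
    class = "panning_config"
  )
}

#' Simulate multi-round biopanning enrichment
#'
#' Each round, a clone's expected output weight is proportional to its input
#' abundance times (affinity + background); the next round's input is a
#' multinomial resample of `phage_per_round` particles from those weights.
#' After the final round, `colonies_screened` colonies are picked from the
#' output to emulate monoclonal screening.
#'
#' @param library Named non-negative numeric vector of input clone
#'   abundances (counts or proportions).
#' @param config A [panning_config()]; its `affinities` must cover the
#'   library clones (missing clones get affinity 0).
#' @return List with `trajectory` (matrix, one row per round including round
#'   0, proportions summing to 1), `screened` (table of picked clone ids)
#'   and `hit_redundancy` (sorted screened counts).
#' @export
simulate_panning <- function(library, config) {
  stopifnot(inherits(config, "panning_config"), is.numeric(library),
            !is.null(names(library)), all(library >= 0), sum(library) > 0)
  set.seed(config$seed)
  aff <- config$affinities[names(library)]
  aff[is.na(aff)] <- 0
  p <- library / sum(library)
  traj <- matrix(NA_real_, nrow = config$rounds + 1L, ncol = length(library),
                 dimnames = list(paste0("round_", 0:config$rounds),
                                 names(library)))
  traj[1L, ] <- p
  if (config$rounds > 0) {
    for (r in seq_len(config$rounds)) {
      w <- p * (aff + config$background)
      if (sum(w) == 0) stop("all selection weights are zero")
      counts <- stats::rmultinom(1L, config$phage_per_round, w / sum(w))[, 1L]
      p <- counts / sum(counts)
      traj[r + 1L, ] <- p
    }
  }
  picked <- sample(names(library), config$colonies_screened,
                   replace = TRUE, prob = p)
  screened <- table(picked)
  list(
    trajectory = traj,
    screened = screened,
    hit_redundancy = sort(as.integer(screened), decreasing = TRUE)
  )
}

#' Simulate a two-cohort serology ELISA table
#'
#' Per mouse: duplicate peptide-well optical densities equal to that mouse's
#' streptavidin background plus the cohort effect (cases only) plus Gaussian
#' noise, and one streptavidin-only well equal to background plus noise.
#' Per-mouse backgrounds vary to emulate inter-individual differences in
#' streptavidin reactivity.
#'
#' @param n_case,n_control Cohort sizes (>= 1).
#' @param effect OD shift added to case peptide wells (default 0.4).
#' @param noise_sd Gaussian well noise SD in OD units (default 0.1).
#' @param background_mean,background_sd Per-mouse streptavidin background
#'   distribution (defaults 0.2 and 0.1; backgrounds are floored at 0).
#' @param peptide_id Peptide identifier recorded in the table.
#' @param age_weeks Optional age annotation.
#' @param seed Seed for all draws.
#' @return Data frame with `mouse_id`, `cohort` (`case` / `control`),
#'   `peptide_id`, `od_rep1`, `od_rep2`, `od_streptavidin`, `age_weeks`.
#' @export
simulate_serology <- function(n_case, n_control, effect = 0.4,
                              noise_sd = 0.1, background_mean = 0.2,
                              background_sd = 0.1, peptide_id = "peptide_1",
                              age_weeks = NA_integer_, seed = 1L) {
  stopifnot(n_case >= 1, n_control >= 1, noise_sd >= 0)
  set.seed(seed)
  n <- n_case + n_control
  cohort <- rep(c("case", "control"), c(n_case, n_control))
  bg <- pmax(stats::rnorm(n, background_mean, background_sd), 0)
  shift <- ifelse(cohort == "case", effect, 0)
  data.frame(
    mouse_id = sprintf("%s_%02d", cohort,
                       c(seq_len(n_case), seq_len(n_control))),
    cohort = cohort,
    peptide_id = peptide_id,
    od_rep1 = bg + shift + stats::rnorm(n, 0, noise_sd),
    od_rep2 = bg + shift + stats::rnorm(n, 0, noise_sd),
    od_streptavidin = bg + stats::rnorm(n, 0, noise_sd),
    age_weeks = age_weeks,
    stringsAsFactors = FALSE
  )
}
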