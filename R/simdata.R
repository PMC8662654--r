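#' Configure the forward-time serial-passage simulator
#'
#' Builds a validated configuration for [simulate_population()]. The defaults
#' emulate the design of a 90-day serial-transfer evolution experiment with
#' daily 1:100 dilutions (about 6.6 doublings per day), an average sequencing
#' depth of 617 +/- 142 reads, and optional mismatch-repair mutator lineages
#' with large (e.g. 116-fold or 16-fold) rate increases. Biofilm mode adds a
#' bead-propagule bottleneck: only a binomial `bead_fraction` of the census is
#' eligible for transfer before the dilution bottleneck, emulating the
#' attachment step of a bead transfer model without spatial structure.
#'
#' Drift operates at the bottleneck: the effective population is the
#' `n_bottleneck` cells that survive each transfer, and a new mutation enters
#' at single-cell frequency `1/n_bottleneck`. `mu` is therefore the
#' per-genome per-generation rate of *tracked* mutations in that effective
#' population, not the raw genomic rate of the census population (whose
#' mutations are overwhelmingly lost to dilution before ever reaching
#' sequencing-detectable frequency).
#'
#' @param n_bottleneck Cells surviving each transfer (default 1e5).
#' @param dilution_factor Daily fold-growth (default 100).
#' @param generations_per_day Doublings per day; defaults to
#'   `log2(dilution_factor)`.
#' @param n_days Number of daily transfers (default 90).
#' @param sample_days Days at which the population is sequenced. Defaults to
#'   c(17, 25, 44, 66, 75, 90) in biofilm mode and c(17, 44, 66, 90) in
#'   planktonic mode.
#' @param genome_length Genome size in bp (default 6,537,648).
#' @param mu Tracked-mutation rate per genome per generation in the
#'   effective (bottleneck) population (default 5e-7).
#' @param frac_beneficial Fraction of tracked mutations that are beneficial
#'   (default 0.1); the rest are strictly neutral.
#' @param dfe_mean_s Mean per-generation selection coefficient of the
#'   exponential distribution of beneficial effects (default 0.05).
#' @param mutator_target Per-division probability of acquiring a mutator
#'   allele (default 0, i.e. no mutator arises spontaneously).
#' @param mutator_multiplier Fold increase in mutation rate conferred by a
#'   mutator allele (default 116).
#' @param mode `"planktonic"` or `"biofilm"`.
#' @param bead_fraction Fraction of the census sampled into the bead
#'   propagule under biofilm mode (default 0.1).
#' @param depth_mean,depth_sd Sequencing depth model (default 617.1, 142.3).
#' @param detection_floor Minimum reported frequency (default 0.05).
#' @param ts_prob Probability that a simulated SNP is a transition
#'   (default 1/3, the unbiased value among three alternate bases).
#' @param indel_prob Probability that a tracked mutation is an indel
#'   (default 0.1).
#' @param population Label used in emitted call tables (default "sim1").
#' @param init Optional list with elements `freqs` (initial frequencies of
#'   extra marked founder lineages, summing to at most 1), `s` (their
#'   per-generation selection coefficients, recycled) and `multiplier`
#'   (their mutation-rate multipliers, recycled); the remainder of the
#'   population is the unmarked ancestor. Used for drift/selection/mutator
#'   calibration experiments.
#' @param seed RNG seed (default 42).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_bottleneck = 1e5, dilution_factor = 100,
                       generations_per_day = log2(dilution_factor),
                       n_days = 90, sample_days = NULL,
                       genome_length = 6537648, mu = 5e-7,
                       frac_beneficial = 0.1, dfe_mean_s = 0.05,
                       mutator_target = 0, mutator_multiplier = 116,
                       mode = c("planktonic", "biofilm"),
                       bead_fraction = 0.1,
                       depth_mean = 617.1, depth_sd = 142.3,
                       detection_floor = 0.05, ts_prob = 1 / 3,
                       indel_prob = 0.1, population = "sim1",
                       init = NULL, seed = 42) {
  mode <- match.arg(mode)
  if (is.null(sample_days)) {
    sample_days <- if (mode == "biofilm") c(17, 25, 44, 66, 75, 90)
                   else c(17, 44, 66, 90)
    sample_days <- sample_days[sample_days <= n_days]
    if (length(sample_days) == 0) sample_days <- n_days
  }
  cfg <- list(n_bottleneck = n_bottleneck, dilution_factor = dilution_factor,
              generations_per_day = generations_per_day, n_days = n_days,
              sample_days = sample_days, genome_length = genome_length,
              mu = mu, frac_beneficial = frac_beneficial,
              dfe_mean_s = dfe_mean_s, mutator_target = mutator_target,
              mutator_multiplier = mutator_multiplier, mode = mode,
              bead_fraction = bead_fraction, depth_mean = depth_mean,
              depth_sd = depth_sd, detection_floor = detection_floor,
              ts_prob = ts_prob, indel_prob = indel_prob,
              population = population, init = init, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_bottleneck < 1) abort("n_bottleneck must be >= 1")
    if (dilution_factor <= 1) abort("dilution_factor must exceed 1")
    if (genome_length <= 0) abort("genome_length must be positive")
    if (mu < 0 || mutator_target < 0 || depth_sd < 0)
      abort("rates must be non-negative")
    if (depth_mean <= 0) abort("depth_mean must be positive")
    if (frac_beneficial < 0 || frac_beneficial > 1)
      abort("frac_beneficial must lie in [0,1]")
    if (length(sample_days) == 0 || any(sample_days < 1) ||
        any(sample_days > n_days) || is.unsorted(sample_days, strictly = TRUE))
      abort("sample_days must be strictly increasing within [1, n_days]")
    if (bead_fraction <= 0 || bead_fraction > 1)
      abort("bead_fraction must lie in (0,1]")
    if (!is.null(init)) {
      if (sum(init$freqs) > 1 + 1e-12) abort("init$freqs must sum to at most 1")
      if (any(init$freqs < 0)) abort("init$freqs must be non-negative")
    }
  })
  invisible(cfg)
}

#' Simulate one serially passaged population
#'
#' Discrete-day Wright-Fisher simulation of a serial-transfer experiment.
#' Each day, genotype frequencies grow deterministically in expectation by
#' `(1 + s)^g` relative to mean fitness, new tracked mutations arrive as a
#' Poisson process per genotype (rate `mu x multiplier x frequency x
#' n_bottleneck x g` per day), each founding a new child genotype at
#' single-cell frequency `1/n_bottleneck`, and the population is then
#' bottlenecked by multinomial sampling to `n_bottleneck` cells (preceded in
#' biofilm mode by a binomial bead-propagule subsample). All stochasticity lives in the bottlenecks and mutation
#' arrivals. Mutator alleles are neutral, heritable, and multiply the mutation
#' rate of the carrying lineage and all of its descendants.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_result`: a list with
#' \describe{
#'   \item{lineage_tree}{data frame of genotypes (`genotype`, `parent`
#'     (0 = ancestral root), `s`, `mutator_multiplier`, `birth_day`).}
#'   \item{mutation_assignments}{data frame mapping mutation id to its
#'     originating genotype, with position, alleles, kind, effect, locus.}
#'   \item{true_genotype_freq}{genotype x sample-day matrix of inclusive
#'     (subtree) frequencies.}
#'   \item{true_mutation_freq}{mutation x sample-day matrix of true
#'     frequencies.}
#'   \item{observed_calls}{mutation-call data frame (native TSV dialect) of
#'     binomially sequenced, detected calls at each sample day.}
#'   \item{census}{population size at the end of each day.}
#' }
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$generations_per_day
  N_census <- config$n_bottleneck * config$dilution_factor
  # effective genome-generations per day at the bottleneck scale
  eff_divisions <- config$n_bottleneck * g

  # genotype state: exclusive frequencies; genotype 1 is the unmarked ancestor
  parent <- 0L; s <- 0; multiplier <- 1; birth_day <- 0L
  x <- 1
  if (!is.null(config$init)) {
    k <- length(config$init$freqs)
    init_s <- rep_len(config$init$s %||% 0, k)
    init_mult <- rep_len(config$init$multiplier %||% 1, k)
    parent <- c(parent, rep(1L, k))
    s <- c(s, init_s)
    multiplier <- c(multiplier, init_mult)
    birth_day <- c(birth_day, rep(0L, k))
    x <- c(1 - sum(config$init$freqs), config$init$freqs)
  }
  muts <- list()  # per-mutation: genotype id
  n_mut <- 0L
  census <- numeric(config$n_days)
  sample_idx <- match(config$sample_days, seq_len(config$n_days))
  geno_freq_days <- list(); mut_freq_days <- list()

  for (d in seq_len(config$n_days)) {
    # deterministic-expectation growth
    w <- (1 + s)^g
    x <- x * w
    x <- x / sum(x)
    census[d] <- N_census

    # mutation arrivals (tracked mutations + mutator acquisitions)
    lambda <- (config$mu + config$mutator_target) * multiplier * x *
      eff_divisions
    n_new <- rpois(length(x), lambda)
    for (i in which(n_new > 0)) {
      for (j in seq_len(n_new[i])) {
        is_mutator <- config$mutator_target > 0 &&
          runif(1) < config$mutator_target / (config$mu + config$mutator_target)
        delta <- if (!is_mutator && runif(1) < config$frac_beneficial)
          rexp(1, 1 / config$dfe_mean_s) else 0
        parent <- c(parent, i)
        # fitness is cumulative along the lineage: a child carries its
        # parent's mutations, so hitchhikers ride their background
        s <- c(s, s[i] + delta)
        multiplier <- c(multiplier,
                        multiplier[i] * if (is_mutator) config$mutator_multiplier else 1)
        birth_day <- c(birth_day, d)
        f0 <- min(1 / config$n_bottleneck, x[i])
        x[i] <- x[i] - f0
        x <- c(x, f0)
        n_mut <- n_mut + 1L
        muts[[n_mut]] <- length(x)  # genotype index carrying this mutation
      }
    }

    # bead propagule (biofilm mode): binomial subsample of the census
    if (config$mode == "biofilm") {
      cells <- round(N_census * x)
      prop <- rbinom(length(x), cells, config$bead_fraction)
      if (sum(prop) == 0) abort("census underflow: empty bead propagule")
      x <- prop / sum(prop)
    }

    # transfer bottleneck: multinomial sample of n_bottleneck cells
    counts <- rmultinom(1, config$n_bottleneck, x)[, 1]
    x <- counts / config$n_bottleneck

    if (d %in% config$sample_days) {
      incl <- pmin(pmax(inclusive_freq(x, parent), 0), 1)
      geno_freq_days[[length(geno_freq_days) + 1L]] <- incl
      mut_freq_days[[length(mut_freq_days) + 1L]] <-
        if (n_mut > 0) incl[unlist(muts)] else numeric(0)
    }
  }

  n_geno <- length(x)
  pad <- function(v) c(v, rep(0, n_geno - length(v)))
  geno_freq <- do.call(cbind, lapply(geno_freq_days, pad))
  day_names <- paste0("day", config$sample_days)
  dimnames(geno_freq) <- list(paste0("G", seq_len(n_geno)), day_names)

  lineage_tree <- data.frame(genotype = paste0("G", seq_len(n_geno)),
                             parent = ifelse(parent == 0, "ROOT",
                                             paste0("G", parent)),
                             s = s, mutator_multiplier = multiplier,
                             birth_day = birth_day, stringsAsFactors = FALSE)

  mut_tab <- simulate_mutation_identities(n_mut, config)
  mut_tab$genotype <- if (n_mut > 0) paste0("G", unlist(muts)) else character(0)
  mut_freq <- matrix(0, nrow = n_mut, ncol = length(config$sample_days),
                     dimnames = list(mut_tab$id, day_names))
  for (j in seq_along(mut_freq_days)) {
    v <- mut_freq_days[[j]]
    if (length(v) > 0) mut_freq[seq_along(v), j] <- v
  }

  observed <- observe_sample_days(mut_tab, mut_freq, config)

  structure(list(config = config, lineage_tree = lineage_tree,
                 mutation_assignments = mut_tab,
                 true_genotype_freq = geno_freq,
                 true_mutation_freq = mut_freq,
                 observed_calls = observed, census = census),
            class = "sim_result")
}

# inclusive (subtree) frequency for each genotype, given exclusive freqs and
# parent indices (0 = root); children always have larger indices than parents
inclusive_freq <- function(x, parent) {
  incl <- x
  for (i in rev(seq_along(x))) {
    if (parent[i] > 0) incl[parent[i]] <- incl[parent[i]] + incl[i]
  }
  incl
}

# draw unique positions, alleles, kinds and effects for tracked mutations
# (infinite-sites: one unique position per mutation, uniform on the genome)
simulate_mutation_identities <- function(n_mut, config) {
  bases <- c("A", "C", "G", "T")
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  if (n_mut == 0) {
    return(data.frame(id = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      kind = character(0), effect = character(0),
                      locus = character(0), stringsAsFactors = FALSE))
  }
  position <- sample.int(config$genome_length, n_mut, replace = FALSE)
  ref <- sample(bases, n_mut, replace = TRUE)
  is_indel <- runif(n_mut) < config$indel_prob
  is_ts <- !is_indel & runif(n_mut) < config$ts_prob
  alt <- character(n_mut)
  alt[is_ts] <- transition_of[ref[is_ts]]
  tv <- which(!is_indel & !is_ts)
  for (i in tv) {
    tv_choices <- setdiff(bases, c(ref[i], transition_of[ref[i]]))
    alt[i] <- sample(tv_choices, 1)
  }
  ins <- is_indel & runif(n_mut) < 0.5
  alt[ins] <- paste0(ref[ins], sample(bases, sum(ins), replace = TRUE))
  del <- is_indel & !ins
  ref[del] <- paste0(ref[del], sample(bases, sum(del), replace = TRUE))
  alt[del] <- substr(ref[del], 1, 1)
  kind <- ifelse(ins, "insertion", ifelse(del, "deletion", "SNP"))
  effect <- ifelse(is_indel, "indel",
                   sample(c("nonsynonymous", "synonymous", "intergenic"),
                          n_mut, replace = TRUE, prob = c(0.60, 0.15, 0.25)))
  locus <- sprintf("locus_%05d", (position - 1) %/% 1000L)
  data.frame(id = sprintf("%d:%s>%s", position, ref, alt),
             position = position, ref = ref, alt = alt, kind = kind,
             effect = effect, locus = locus, stringsAsFactors = FALSE)
}

observe_sample_days <- function(mut_tab, mut_freq, config) {
  out <- list()
  for (j in seq_along(config$sample_days)) {
    day <- config$sample_days[j]
    obs <- sequence_sample(mut_freq[, j],
                           depth_mean = config$depth_mean,
                           depth_sd = config$depth_sd,
                           detection_floor = config$detection_floor)
    det <- which(obs$detected)
    if (length(det) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      population = config$population, day = day,
      position = mut_tab$position[det], ref = mut_tab$ref[det],
      alt = mut_tab$alt[det], kind = mut_tab$kind[det],
      effect = mut_tab$effect[det], locus = mut_tab$locus[det],
      frequency = obs$frequency[det], fwd_reads = obs$fwd_reads[det],
      rev_reads = obs$rev_reads[det], depth = obs$depth[det],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    calls <- read_empty_calls()
  } else {
    calls <- do.call(rbind, out)
    rownames(calls) <- NULL
  }
  calls
}

read_empty_calls <- function() {
  data.frame(population = character(0), day = integer(0),
             position = integer(0), ref = character(0), alt = character(0),
             kind = character(0), effect = character(0), locus = character(0),
             frequency = numeric(0), fwd_reads = integer(0),
             rev_reads = integer(0), depth = integer(0),
             stringsAsFactors = FALSE)
}

#' Emulate whole-population sequencing of known frequencies
#'
#' For each true frequency, a sequencing depth is drawn from a normal
#' distribution (rounded, truncated at 1 read), alternate-allele reads are
#' binomial in the depth, and the alternate reads are split binomially (p =
#' 0.5) into forward and reverse strand support. The reported frequency is
#' alt/depth; records below the detection floor are flagged undetected.
#'
#' @param true_freqs Vector of true frequencies in \[0,1\].
#' @param depth_mean,depth_sd Depth model (defaults 617.1, 142.3).
#' @param detection_floor Minimum reported frequency (default 0.05).
#' @param seed Optional seed; by default the current RNG stream is used so
#'   the function composes with seeded simulations.
#' @return Data frame with columns `true_freq`, `depth`, `fwd_reads`,
#'   `rev_reads`, `frequency`, `detected`.
#' @export
sequence_sample <- function(true_freqs, depth_mean = 617.1, depth_sd = 142.3,
                            detection_floor = 0.05, seed = NULL) {
  if (depth_mean <= 0) abort("depth_mean must be positive")
  if (any(true_freqs < 0 | true_freqs > 1)) abort("frequencies must lie in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_freqs)
  depth <- pmax(1L, as.integer(round(rnorm(n, depth_mean, depth_sd))))
  alt <- rbinom(n, depth, true_freqs)
  fwd <- rbinom(n, alt, 0.5)
  freq <- alt / depth
  data.frame(true_freq = true_freqs, depth = depth, fwd_reads = fwd,
             rev_reads = alt - fwd, frequency = freq,
             detected = freq >= detection_floor)
}

#' Write a simulated dataset to disk
#'
#' Emits one mutation-call TSV per sample day (in the native dialect read by
#' [read_calls()]), a ground-truth TSV with genotype memberships and true
#' mutation trajectories, a genotype lineage-tree TSV, a locus annotation TSV
#' (simulated loci, fixed 1 kb length), and a JSON manifest recording the
#' configuration and seed.
#'
#' @param result A [simulate_population()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(result, outdir) {
  stopifnot(inherits(result, "sim_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pop <- result$config$population
  files <- character(0)
  for (day in result$config$sample_days) {
    f <- file.path(outdir, sprintf("%s_day%03d_calls.tsv", pop, day))
    calls <- result$observed_calls[result$observed_calls$day == day, , drop = FALSE]
    write.table(calls, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  truth <- cbind(result$mutation_assignments,
                 as.data.frame(result$true_mutation_freq))
  f <- file.path(outdir, sprintf("%s_truth_mutations.tsv", pop))
  write.table(truth, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(outdir, sprintf("%s_truth_genotypes.tsv", pop))
  write.table(cbind(result$lineage_tree,
                    as.data.frame(result$true_genotype_freq)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  loci <- unique(result$mutation_assignments$locus)
  f <- file.path(outdir, sprintf("%s_loci.tsv", pop))
  write.table(data.frame(locus = loci, length_bp = 1000L,
                         functional_class = "simulated"),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(outdir, sprintf("%s_manifest.json", pop))
  cfg <- result$config
  cfg$init <- NULL
  jsonlite::write_json(unclass(cfg), f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}

#' Planted-genotype benchmark dataset
#'
#' Constructs a small population with a known nested genealogy of five
#' genotype cohorts (two root clades, three nested descendants) whose
#' inclusive frequencies follow fixed, well-separated trajectories (pairwise
#' mean absolute separation >= 0.15), assigns `muts_per_genotype` mutations
#' to each cohort, and adds binomial sequencing noise at the given depth
#' (noise SD about 0.02 at depth 600). This is the standard fixture for
#' benchmarking genotype clustering and genealogy recovery.
#'
#' @param muts_per_genotype Mutations per planted cohort (default 4).
#' @param days Sampling days (default c(17, 25, 44, 66, 75, 90)).
#' @param depth_mean,depth_sd Sequencing depth model.
#' @param seed RNG seed.
#' @return List with `table` (a `trajectory_table`), `truth_membership`
#'   (named vector: mutation id -> true genotype), `truth_parent` (named
#'   vector: genotype -> parent or "ROOT"), and `true_freq` (genotype x day
#'   matrix).
#' @export
simulate_planted_cohorts <- function(muts_per_genotype = 4,
                                     days = c(17, 25, 44, 66, 75, 90),
                                     depth_mean = 617.1, depth_sd = 142.3,
                                     seed = 42) {
  set.seed(seed)
  true_freq <- rbind(
    G1 = c(0.10, 0.30, 0.55, 0.75, 0.85, 0.92),
    G2 = c(0.00, 0.10, 0.25, 0.45, 0.60, 0.70),
    G3 = c(0.00, 0.00, 0.05, 0.20, 0.35, 0.50),
    G4 = c(0.70, 0.55, 0.35, 0.20, 0.10, 0.05),
    G5 = c(0.25, 0.40, 0.20, 0.10, 0.04, 0.02))
  if (length(days) != ncol(true_freq))
    abort("simulate_planted_cohorts requires exactly ", ncol(true_freq), " days")
  colnames(true_freq) <- paste0("day", days)
  truth_parent <- c(G1 = "ROOT", G2 = "G1", G3 = "G2", G4 = "ROOT", G5 = "G4")

  n_geno <- nrow(true_freq)
  n_mut <- n_geno * muts_per_genotype
  position <- sort(sample.int(6537648L, n_mut))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_mut, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  geno <- rep(rownames(true_freq), each = muts_per_genotype)

  calls <- list()
  for (j in seq_along(days)) {
    f <- true_freq[geno, j]
    obs <- sequence_sample(f, depth_mean, depth_sd, detection_floor = 0.01)
    det <- which(obs$detected)
    if (length(det) == 0) next
    calls[[j]] <- data.frame(
      population = "planted", day = days[j], position = position[det],
      ref = ref[det], alt = alt[det], kind = "SNP", effect = "nonsynonymous",
      locus = sprintf("locus_%05d", (position[det] - 1) %/% 1000L),
      frequency = obs$frequency[det], fwd_reads = obs$fwd_reads[det],
      rev_reads = obs$rev_reads[det], depth = obs$depth[det],
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  table <- build_trajectories(calls, days = days)
  ids <- sprintf("%d:%s>%s", position, ref, alt)
  membership <- setNames(geno, ids)[table$mutations$id]
  list(table = table, truth_membership = membership,
       truth_parent = truth_parent, true_freq = true_freq)
}
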