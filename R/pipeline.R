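#' Apply the standard call filters in canonical order
#'
#' Convenience wrapper chaining ancestral subtraction, repeat masking,
#' strand-support filtering (at mutation scope: a mutation qualifying at one
#' timepoint keeps its whole trajectory) and dense-window exclusion. The
#' first three filters commute; dense-window exclusion depends on the
#' surviving call set and is therefore applied last.
#'
#' @param calls Mutation-call data frame.
#' @param ancestor Optional ancestral variant set (see [subtract_ancestor()]).
#' @param mask Optional repeat mask (see [filter_repeat_mask()]).
#' @param min_per_strand,window,max_neighbors Filter parameters.
#' @return The filtered calls.
#' @export
filter_calls <- function(calls, ancestor = NULL, mask = NULL,
                         min_per_strand = 3, window = 15, max_neighbors = 2) {
  calls <- subtract_ancestor(calls, ancestor)
  calls <- filter_repeat_mask(calls, mask)
  calls <- filter_strand_support(calls, min_per_strand, scope = "mutation")
  filter_dense_windows(calls, window, max_neighbors)
}

#' Run the full analysis pipeline on a dataset directory
#'
#' Executes, per population: filtering, trajectory consolidation, genotype
#' clustering, genealogy inference, fixation detection, Muller-table export
#' and diversity trajectories; then, across populations: the gene-level
#' parallelism table with Fisher/Benjamini-Hochberg enrichment. All outputs
#' are plain TSV/CSV plus a JSON manifest echoing every parameter, so a rerun
#' with the same configuration is byte-identical.
#'
#' @param config Either a path to a YAML file or a list, with elements:
#' \describe{
#'   \item{populations}{list of lists with `name`, `treatment`
#'     (`"biofilm"`/`"planktonic"`), `calls` (path to a multi-day TSV in the
#'     native dialect), and optional `cutoff`.}
#'   \item{annotations}{path to a locus-annotation TSV (`locus`,
#'     `length_bp`, optional `functional_class`).}
#'   \item{ancestor, repeat_mask}{optional paths (see [read_ancestor_set()],
#'     [read_repeat_mask()]).}
#'   \item{filters}{`min_per_strand` (3), `window` (15), `max_neighbors` (2).}
#'   \item{genotypes}{`cutoff` (0.1), `nest_tolerance` (0.05),
#'     `detection_floor` (0.05), `fixed_threshold` (0.97).}
#'   \item{parallelism}{`genome_length` (6537648), `fdr` (0.05),
#'     `min_cases_report` (2).}
#'   \item{outdir}{output directory.}
#' }
#' @return Invisibly, a list of per-population results (`table`, `forest`,
#'   `fixations`, `diversity`) plus the cross-population `multiplicity`
#'   table and the manifest path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- config$outdir %||% abort("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  filters <- config$filters %||% list()
  gt <- config$genotypes %||% list()
  par_cfg <- config$parallelism %||% list()

  ancestor <- if (!is.null(config$ancestor)) read_ancestor_set(config$ancestor)
  mask <- if (!is.null(config$repeat_mask)) read_repeat_mask(config$repeat_mask)
  annotations <- if (!is.null(config$annotations))
    read.delim(config$annotations, stringsAsFactors = FALSE)

  results <- list()
  final_calls <- list()
  for (pop_cfg in config$populations) {
    name <- pop_cfg$name
    calls <- read_calls(pop_cfg$calls)
    calls <- filter_calls(calls, ancestor, mask,
                          min_per_strand = filters$min_per_strand %||% 3,
                          window = filters$window %||% 15,
                          max_neighbors = filters$max_neighbors %||% 2)
    if (nrow(calls) == 0) abort("pipeline stage variants [", name,
                                "]: no calls survive filtering")
    pop_dir <- file.path(outdir, name)
    dir.create(pop_dir, showWarnings = FALSE)
    write.table(calls, file.path(pop_dir, "filtered_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    table <- build_trajectories(calls)
    traj_out <- cbind(table$mutations, as.data.frame(table$freq))
    write.table(traj_out, file.path(pop_dir, "trajectories.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        abort("pipeline stage ", what, " [", name, "]: ", conditionMessage(e))
      })
    }
    clusters <- stage("genotypes", cluster_genotypes(
      table, cutoff = pop_cfg$cutoff %||% gt$cutoff %||% 0.1,
      detection_floor = gt$detection_floor %||% 0.05))
    forest <- stage("genotypes", infer_genealogy(
      clusters, nest_tolerance = gt$nest_tolerance %||% 0.05,
      strict = FALSE))
    membership <- data.frame(
      mutation = unlist(forest$members, use.names = FALSE),
      genotype = rep(names(forest$members), lengths(forest$members)))
    write.table(membership, file.path(pop_dir, "genotype_membership.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cbind(genotype = rownames(forest$trajectory),
                      parent = forest$parent[rownames(forest$trajectory)],
                      as.data.frame(forest$trajectory)),
                file.path(pop_dir, "genotype_trajectories.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    stage("muller", write_muller_tables(forest, pop_dir, strict = FALSE))
    fixations <- stage("genotypes", detect_fixations(
      forest, fixed_threshold = gt$fixed_threshold %||% 0.97))
    write.table(fixations, file.path(pop_dir, "fixations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    diversity <- diversity_trajectory(table)
    write.table(diversity, file.path(pop_dir, "diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    # final mutation set: one row per mutation at its maximum frequency
    peak <- apply(table$freq, 1, max)
    final_calls[[name]] <- data.frame(
      population = name, table$mutations, frequency = peak,
      stringsAsFactors = FALSE)
    results[[name]] <- list(table = table, forest = forest,
                            fixations = fixations, diversity = diversity,
                            treatment = pop_cfg$treatment %||% NA_character_)
  }

  multiplicity <- NULL
  if (!is.null(annotations)) {
    all_final <- do.call(rbind, final_calls)
    multiplicity <- multiplicity_table(
      all_final, annotations,
      min_cases = par_cfg$min_cases_report %||% 2)
    if (nrow(multiplicity) > 0) {
      multiplicity <- add_enrichment_test(
        multiplicity, M = nrow(all_final),
        G = par_cfg$genome_length %||% 6537648,
        Q = par_cfg$fdr %||% 0.05)
    }
    write.table(multiplicity, file.path(outdir, "multiplicity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "evoreseq",
    version = as.character(utils::packageVersion("evoreseq")),
    parameters = list(filters = filters, genotypes = gt,
                      parallelism = par_cfg),
    populations = lapply(config$populations, function(p)
      list(name = p$name, treatment = p$treatment %||% NA,
           calls = p$calls, md5 = unname(tools::md5sum(p$calls)))),
    inputs = list(ancestor = config$ancestor, repeat_mask = config$repeat_mask,
                  annotations = config$annotations))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       null = "null", digits = NA)

  invisible(list(populations = results, multiplicity = multiplicity,
                 manifest = manifest_path))
}

#' Generate a small bundled simulation fixture
#'
#' Simulates a two-population dataset - one planktonic population and one
#' biofilm population seeded with a sweeping mutator lineage (116x rate
#' multiplier on a beneficial background) - small enough for continuous
#' testing, writes it with [write_dataset()], and returns the paths plus a
#' ready-made [run_pipeline()] configuration.
#'
#' @param outdir Output directory.
#' @param seed RNG seed (default 42).
#' @return List with `dir`, per-population call-table paths, and `config`
#'   (a list accepted by [run_pipeline()]).
#' @export
make_fixtures <- function(outdir, seed = 42) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_p <- sim_config(n_bottleneck = 5e4, n_days = 90, mu = 2e-5,
                      frac_beneficial = 0.2, mode = "planktonic",
                      population = "P1", seed = seed)
  cfg_b <- sim_config(n_bottleneck = 5e4, n_days = 90, mu = 2e-5,
                      frac_beneficial = 0.2, mode = "biofilm",
                      population = "B1", mutator_multiplier = 16,
                      init = list(freqs = 0.05, s = 0.04, multiplier = 16),
                      seed = seed + 1)
  res_p <- simulate_population(cfg_p)
  res_b <- simulate_population(cfg_b)
  write_dataset(res_p, outdir)
  write_dataset(res_b, outdir)

  # consolidated multi-day call tables, one per population
  paths <- list()
  loci <- list()
  for (res in list(res_p, res_b)) {
    pop <- res$config$population
    f <- file.path(outdir, sprintf("%s_calls.tsv", pop))
    write.table(res$observed_calls, f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths[[pop]] <- f
    loci[[pop]] <- unique(res$observed_calls$locus)
  }
  ann <- data.frame(locus = unique(unlist(loci)), length_bp = 1000L,
                    functional_class = "simulated")
  ann_path <- file.path(outdir, "loci.tsv")
  write.table(ann, ann_path, sep = "\t", quote = FALSE, row.names = FALSE)

  config <- list(
    populations = list(
      list(name = "P1", treatment = "planktonic", calls = paths$P1),
      list(name = "B1", treatment = "biofilm", calls = paths$B1)),
    annotations = ann_path,
    outdir = file.path(outdir, "pipeline"))
  list(dir = outdir, calls = paths, annotations = ann_path, config = config,
       results = list(P1 = res_p, B1 = res_b))
}
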