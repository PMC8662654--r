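#' Gene-level parallelism (multiplicity) accounting
#'
#' Tabulates, for every locus hit `min_cases` or more times, the number of
#' independent mutation cases, their breakdown by effect class (NS counts
#' include nonsense), per-population case counts, and the highest frequency
#' (in percent) reached by any member mutation. Multiple hits at the same
#' site in different populations count as independent cases.
#'
#' @param calls Final mutation set: one row per independent mutation (unique
#'   population/position/ref/alt) with `locus`, `effect` and `frequency` (the
#'   mutation's maximum trajectory value).
#' @param annotations Data frame with columns `locus`, `length_bp` and
#'   optionally `functional_class`; every locus in `calls` must be present.
#' @param min_cases Minimum number of cases for a locus to be reported
#'   (default 2, the screening set for enrichment testing).
#' @return Data frame with one row per reported locus: `locus`,
#'   `total_cases`, `ns`, `s`, `indel`, one count column per population,
#'   `max_frequency` (percent), `locus_length`, `functional_class`.
#' @export
multiplicity_table <- function(calls, annotations, min_cases = 2) {
  empty <- data.frame(locus = character(0), total_cases = integer(0),
                      ns = integer(0), s = integer(0), indel = integer(0),
                      max_frequency = numeric(0), locus_length = integer(0),
                      functional_class = character(0))
  if (nrow(calls) == 0) return(empty)
  key <- paste(calls$population, mutation_key(calls))
  if (anyDuplicated(key) > 0)
    abort("calls must contain one row per independent mutation")
  missing_loci <- setdiff(unique(calls$locus), annotations$locus)
  if (length(missing_loci) > 0)
    abort("locus missing from annotations: ",
          paste(head(missing_loci, 5), collapse = ", "))

  pops <- sort(unique(calls$population))
  loci <- names(which(table(calls$locus) >= min_cases))
  loci <- loci[order(match(loci, calls$locus))]  # first-appearance order
  if (length(loci) == 0) return(empty)
  rows <- lapply(loci, function(lc) {
    m <- calls[calls$locus == lc, , drop = FALSE]
    counts <- vapply(pops, function(p) sum(m$population == p), integer(1))
    ann <- annotations[match(lc, annotations$locus), ]
    out <- data.frame(locus = lc, total_cases = nrow(m),
                      ns = sum(m$effect %in% c("nonsynonymous", "nonsense")),
                      s = sum(m$effect == "synonymous"),
                      indel = sum(m$effect == "indel"),
                      stringsAsFactors = FALSE)
    out[pops] <- as.list(counts)
    out$max_frequency <- max(m$frequency) * 100
    out$locus_length <- ann$length_bp
    out$functional_class <- ann$functional_class %||% NA_character_
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Locus-length-aware Fisher enrichment test
#'
#' One-sided (greater) Fisher exact test that a locus carries more mutations
#' than expected if the `M` observed mutations were scattered uniformly over
#' the `G` bp genome. The 2x2 table contrasts mutated vs unmutated bases
#' inside vs outside the locus, so the p-value is exactly the hypergeometric
#' upper tail P(X >= k) with population `G`, `M` successes and `L` draws.
#'
#' @param k Mutation cases at the locus (vectorised).
#' @param L Locus length in bp.
#' @param M Total mutations observed genome-wide.
#' @param G Genome length in bp.
#' @return One-sided p-value(s).
#' @export
fisher_locus_test <- function(k, L, M, G) {
  n <- max(length(k), length(L))
  k <- rep_len(k, n); L <- rep_len(L, n)
  if (any(k < 0 | k > M)) abort("k must lie in [0, M]")
  if (any(L < 1 | L >= G)) abort("L must lie in [1, G)")
  if (any(k > L)) abort("more cases than bases at locus (k > L)")
  phyper(k - 1, M, G - M, L, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up significance flags
#'
#' Standard step-up procedure at false discovery rate `Q`: p-values are
#' ranked ascending, the largest rank `i` with `p_(i) <= (i/m) Q` is found,
#' and all p-values up to that rank are flagged significant. Tied p-values
#' share the better outcome.
#'
#' @param p_values Vector of p-values in \[0,1\].
#' @param Q False discovery rate (default 0.05).
#' @return Logical vector of significance flags, in input order.
#' @export
bh_correct <- function(p_values, Q = 0.05) {
  if (any(is.na(p_values) | p_values < 0 | p_values > 1))
    abort("p-values must lie in [0,1]")
  m <- length(p_values)
  if (m == 0) return(logical(0))
  ps <- sort(p_values)
  ok <- which(ps <= seq_len(m) / m * Q)
  if (length(ok) == 0) return(rep(FALSE, m))
  p_values <= ps[max(ok)]
}

#' Attach enrichment statistics to a multiplicity table
#'
#' Computes the Fisher locus test for every reported locus and flags
#' significance by Benjamini-Hochberg at rate `Q`. The number of tests `m`
#' is the number of loci actually tested (the rows of `records`).
#'
#' @param records A [multiplicity_table()] result.
#' @param M Total mutations observed genome-wide.
#' @param G Genome length in bp (default 6,537,648).
#' @param Q False discovery rate (default 0.05).
#' @return `records` with `p_value`, `bh_rank`, `bh_threshold` and
#'   `significant` columns appended.
#' @export
add_enrichment_test <- function(records, M, G = 6537648, Q = 0.05) {
  if (nrow(records) == 0) return(records)
  records$p_value <- fisher_locus_test(records$total_cases,
                                       records$locus_length, M, G)
  records$bh_rank <- rank(records$p_value, ties.method = "min")
  records$bh_threshold <- records$bh_rank / nrow(records) * Q
  records$significant <- bh_correct(records$p_value, Q)
  records
}

#' Normalised dN/dS ratio
#'
#' Observed nonsynonymous/synonymous count ratio standardised by the neutral
#' NS/S expectation of the genome's codon composition, so that 1 means the
#' neutral expectation.
#'
#' @param ns_count,s_count Observed NS and S mutation counts.
#' @param neutral_ratio Neutral NS/S expectation (default 2.96, a typical
#'   value for a GC-rich bacterial genome under a uniform substitution
#'   spectrum).
#' @return `(ns/s) / neutral_ratio`; `NA` when `s_count` is 0 (undefined,
#'   not infinite).
#' @export
normalized_dnds <- function(ns_count, s_count, neutral_ratio = 2.96) {
  if (any(ns_count < 0) || any(s_count < 0)) abort("counts must be non-negative")
  ifelse(s_count == 0, NA_real_, (ns_count / s_count) / neutral_ratio)
}

#' Neutral NS/S expectation from codon usage
#'
#' Expected ratio of nonsynonymous to synonymous changes if every
#' single-nucleotide substitution were equally likely: each of the nine
#' single-base changes of every codon is classified against the standard
#' genetic code (changes to or from a stop codon that alter the product
#' count as nonsynonymous), weighted by the codon's usage frequency.
#'
#' @param codon_frequencies Named numeric vector over the 64 codons (DNA
#'   alphabet), summing to 1 within 1e-6; stop codons may carry zero usage.
#' @return The neutral NS/S ratio.
#' @export
neutral_dnds_from_codon_usage <- function(codon_frequencies) {
  code <- genetic_code()
  codons <- names(codon_frequencies)
  if (is.null(codons) || !all(toupper(codons) %in% names(code)))
    abort("codon_frequencies must be named by DNA codons")
  if (abs(sum(codon_frequencies) - 1) > 1e-6)
    abort("codon frequencies must sum to 1")
  codons <- toupper(codons)
  bases <- c("A", "C", "G", "T")
  ns_w <- 0; s_w <- 0
  for (i in seq_along(codons)) {
    w <- codon_frequencies[i]
    if (w == 0) next
    cod <- strsplit(codons[i], "")[[1]]
    for (pos in 1:3) {
      for (b in setdiff(bases, cod[pos])) {
        alt <- cod; alt[pos] <- b
        if (code[paste(alt, collapse = "")] == code[codons[i]])
          s_w <- s_w + w
        else ns_w <- ns_w + w
      }
    }
  }
  if (s_w == 0) abort("no synonymous changes possible under this usage table")
  unname(ns_w / s_w)
}

# the standard genetic code over DNA codons ('*' = stop)
genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16),
                   rep(rep(bases, each = 4), 4),
                   rep(bases, 16))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",  # TTT..TGG
    "LLLLPPPPHHQQRRRR",  # CTT..CGG
    "IIIMTTTTNNKKSSRR",  # ATT..AGG
    "VVVVAAAADDEEGGGG"), "")[[1]]  # GTT..GGG
  setNames(aa, codons)
}

#' Classify loci by lifestyle specificity
#'
#' Labels each locus `biofilm-only`, `planktonic-only` or `shared` according
#' to which treatment arms contain populations carrying the mutation.
#' Occupancy is taken from per-population columns of `records`: a population
#' column with a nonzero, non-missing value counts as occupied (this works
#' both for case-count columns and for per-population maximum-frequency
#' columns).
#'
#' @param records Data frame with a `locus` column and one column per
#'   population named in `treatment_map`.
#' @param treatment_map Named character vector mapping population column
#'   names to `"biofilm"` or `"planktonic"`.
#' @return Data frame with `locus`, `n_biofilm_pops`, `n_planktonic_pops`
#'   and `specificity`.
#' @export
lifestyle_specificity <- function(records, treatment_map) {
  pops <- names(treatment_map)
  missing_pops <- setdiff(pops, names(records))
  if (length(missing_pops) > 0)
    abort("records lack population column(s): ",
          paste(missing_pops, collapse = ", "))
  occ <- sapply(pops, function(p) {
    v <- records[[p]]
    !is.na(v) & v > 0
  })
  occ <- matrix(occ, nrow = nrow(records), dimnames = list(NULL, pops))
  nb <- rowSums(occ[, treatment_map == "biofilm", drop = FALSE])
  np <- rowSums(occ[, treatment_map == "planktonic", drop = FALSE])
  specificity <- ifelse(nb > 0 & np == 0, "biofilm-only",
                        ifelse(np > 0 & nb == 0, "planktonic-only",
                               ifelse(nb > 0 & np > 0, "shared", "absent")))
  data.frame(locus = records$locus, n_biofilm_pops = nb,
             n_planktonic_pops = np, specificity = specificity,
             stringsAsFactors = FALSE)
}

#' Read a bundled or user gene-level parallelism table
#'
#' Reads a TSV with one row per repeatedly mutated locus (columns `locus`,
#' `total_cases`, `ns`, `s`, `indel`, per-population maximum-frequency
#' columns, `functional_class`). The package ships such a table for six
#' experimentally evolved P. aeruginosa PA14 populations (three biofilm,
#' three planktonic, 90 days) under
#' `system.file("extdata", "pa14_parallel_loci.tsv", package = "evoreseq")`.
#'
#' @param path Path to the TSV.
#' @return Data frame of locus records.
#' @export
read_parallel_loci <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("locus", "total_cases") %in% names(x)))
    abort("parallelism table needs 'locus' and 'total_cases' columns")
  x
}

#' Summarise a parallelism table
#'
#' @param records Locus records with a `total_cases` column.
#' @param min_cases Minimum case count (default 3).
#' @return List with `n_loci` (loci at or above `min_cases`) and `n_cases`
#'   (their summed cases).
#' @export
parallelism_summary <- function(records, min_cases = 3) {
  sel <- records$total_cases >= min_cases
  list(n_loci = sum(sel), n_cases = sum(records$total_cases[sel]))
}
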