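#' Alpha diversity of a frequency vector
#'
#' Treats mutation frequencies as abundances, normalises them to proportions
#' `p_i`, and returns Shannon entropy (`-sum p log p`, nats), the
#' Gini-Simpson index (`1 - sum p^2`) or inverse Simpson (`1 / sum p^2`,
#' an effective number of mutations).
#'
#' @param frequencies Non-negative vector with at least one positive entry.
#' @param mode `"shannon"`, `"simpson"` or `"invsimpson"`.
#' @return The diversity value.
#' @export
alpha_diversity <- function(frequencies,
                            mode = c("shannon", "simpson", "invsimpson")) {
  mode <- match.arg(mode)
  if (any(frequencies < 0)) abort("frequencies must be non-negative")
  if (sum(frequencies) == 0) abort("all-zero frequency vector")
  p <- frequencies[frequencies > 0]
  p <- p / sum(p)
  switch(mode,
         shannon = -sum(p * log(p)),
         simpson = 1 - sum(p^2),
         invsimpson = 1 / sum(p^2))
}

#' Diversity trajectory of a population
#'
#' Computes all three alpha-diversity indices per sampled day from the
#' mutations detected (nonzero frequency) at that day.
#'
#' @param table A [build_trajectories()] table.
#' @return Data frame with columns `population`, `day`, `n_detected`,
#'   `shannon`, `simpson`, `invsimpson` (NA at days with no detected
#'   mutation).
#' @export
diversity_trajectory <- function(table) {
  stopifnot(inherits(table, "trajectory_table"))
  rows <- lapply(seq_along(table$days), function(j) {
    f <- table$freq[, j]
    f <- f[f > 0]
    if (length(f) == 0) {
      data.frame(population = table$population, day = table$days[j],
                 n_detected = 0L, shannon = NA_real_, simpson = NA_real_,
                 invsimpson = NA_real_)
    } else {
      data.frame(population = table$population, day = table$days[j],
                 n_detected = length(f),
                 shannon = alpha_diversity(f, "shannon"),
                 simpson = alpha_diversity(f, "simpson"),
                 invsimpson = alpha_diversity(f, "invsimpson"))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample pooled-variance Student's t-test
#'
#' Classic equal-variance Student's test (df = n_a + n_b - 2), the form whose
#' degrees of freedom match small balanced designs such as three biofilm vs
#' three planktonic populations (df = 4). When the pooled variance is zero,
#' identical means give t = 0, p = 1 and different means give the degenerate
#' p = 0 edge case (reported, not an error).
#'
#' @param a,b Numeric vectors with at least two values each.
#' @param pooled Use the pooled-variance statistic (default TRUE); FALSE
#'   gives Welch's test via [stats::t.test()].
#' @return List with `t`, `df` and `p` (two-tailed).
#' @export
two_sample_ttest <- function(a, b, pooled = TRUE) {
  if (length(a) < 2 || length(b) < 2) abort("need at least two values per group")
  if (!pooled) {
    ht <- stats::t.test(a, b)
    return(list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value))
  }
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  s2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  delta <- mean(a) - mean(b)
  if (s2 == 0) {
    if (delta == 0) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(delta) * Inf, df = df, p = 0))
  }
  t <- delta / sqrt(s2 * (1 / na + 1 / nb))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Regression of biofilm on planktonic frequencies with influence measures
#'
#' Fits ordinary least squares of biofilm-arm mutation frequency (response)
#' on planktonic-arm frequency (predictor) and computes Cook's distance for
#' every mutation. Mutations whose frequencies depart strongly from the
#' population-wide trend between the two environments are candidates for
#' environment-specific selection. Only mutations detected in both arms
#' should enter the fit.
#'
#' @param freq_planktonic,freq_biofilm Paired frequency vectors (>= 3 pairs).
#' @param mutation Optional mutation identifiers carried into the output.
#' @return Data frame with columns `mutation`, `freq_planktonic`,
#'   `freq_biofilm`, `fitted`, `residual`, `cooks_d`; the fitted `lm` object
#'   is attached as `attr(x, "fit")`.
#' @export
enrichment_fit <- function(freq_planktonic, freq_biofilm, mutation = NULL) {
  x <- freq_planktonic; y <- freq_biofilm
  if (length(x) != length(y)) abort("paired vectors must have equal length")
  if (length(x) < 3) abort("at least three points are required")
  if (var(x) == 0) abort("degenerate predictor: planktonic frequencies are constant")
  fit <- lm(y ~ x)
  d <- unname(cooks.distance(fit))
  # an exact-line fit has zero residual variance; no point has influence
  if (sum(residuals(fit)^2) < 1e-28) d <- rep(0, length(x))
  out <- data.frame(mutation = mutation %||% paste0("m", seq_along(x)),
                    freq_planktonic = x, freq_biofilm = y,
                    fitted = unname(fitted(fit)),
                    residual = unname(residuals(fit)),
                    cooks_d = d,
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Classify environment-enriched mutations
#'
#' A mutation is flagged enriched when its Cook's distance is at least
#' `factor` times the mean distance over all mutations in the fit. The
#' direction is read off the residual sign: a biofilm frequency above the
#' regression prediction means biofilm-enriched, below means
#' planktonic-enriched.
#'
#' @param records An [enrichment_fit()] result.
#' @param factor Multiple of the mean Cook's distance required (default 4).
#' @return `records` with `enriched` (logical) and `direction`
#'   (`"biofilm"`, `"planktonic"` or `"none"`) appended.
#' @export
classify_enrichment <- function(records, factor = 4) {
  d <- records$cooks_d
  mean_d <- mean(d)
  enriched <- mean_d > 0 & d >= factor * mean_d
  records$enriched <- enriched
  records$direction <- ifelse(!enriched, "none",
                              ifelse(records$residual > 0, "biofilm",
                                     "planktonic"))
  records
}

#' Pair mutation frequencies across two selection arms
#'
#' Builds the input pairs for [enrichment_fit()] from two call tables of the
#' same population re-sequenced after biofilm-arm and planktonic-arm
#' selection. Only mutations detected in both arms are kept.
#'
#' @param biofilm_calls,planktonic_calls Mutation-call data frames (one
#'   timepoint each).
#' @return Data frame with `mutation`, `freq_planktonic`, `freq_biofilm`.
#' @export
pair_environment_calls <- function(biofilm_calls, planktonic_calls) {
  kb <- mutation_key(biofilm_calls)
  kp <- mutation_key(planktonic_calls)
  shared <- intersect(kb, kp)
  data.frame(mutation = shared,
             freq_planktonic = planktonic_calls$frequency[match(shared, kp)],
             freq_biofilm = biofilm_calls$frequency[match(shared, kb)],
             stringsAsFactors = FALSE)
}
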