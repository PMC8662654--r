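#' Selective rate constant from competition counts
#'
#' Head-to-head competition fitness of an evolved population against a marked
#' ancestor: the difference of the competitors' log fold-changes over one
#' transfer cycle, divided by `divisor`. The default divisor of 2 is kept for
#' comparability with published selective rate constants computed this way;
#' it is exposed as a parameter because other conventions divide by the
#' competition length in days or generations instead.
#'
#' Replicates in which either competitor was undetectable (a zero count)
#' yield `NA` - the replicate is invalid and must be omitted, not zero-filled.
#'
#' @param evolved_d0,evolved_d1 Evolved-competitor CFU counts at day 0 and 1.
#' @param ancestor_d0,ancestor_d1 Ancestral-competitor CFU counts.
#' @param divisor Denominator of the rate (default 2).
#' @return Selective rate constant(s) `r`; `NA` for invalid replicates.
#' @export
selection_rate <- function(evolved_d0, evolved_d1, ancestor_d0, ancestor_d1,
                           divisor = 2) {
  invalid <- evolved_d0 <= 0 | evolved_d1 <= 0 | ancestor_d0 <= 0 |
    ancestor_d1 <= 0
  r <- (log(evolved_d1 / evolved_d0) - log(ancestor_d1 / ancestor_d0)) / divisor
  r[invalid] <- NA_real_
  r
}

#' Maximum growth rate from an OD growth curve
#'
#' Vmax is the steepest log-linear stretch of the growth curve: the maximum
#' over sliding windows of `window` consecutive readings of the least-squares
#' slope of ln(OD) against time. Windows containing non-positive OD readings
#' are skipped. With readings every 10 minutes the default window of 4 spans
#' about half an hour of growth.
#'
#' @param times Time points in hours, strictly increasing.
#' @param od OD600 readings (same length as `times`).
#' @param window Number of consecutive readings per window (default 4).
#' @return Maximum growth rate in ln(OD) units per hour.
#' @export
vmax <- function(times, od, window = 4) {
  if (length(times) != length(od)) abort("times and od must have equal length")
  if (length(times) < 2 || is.unsorted(times, strictly = TRUE))
    abort("times must be strictly increasing with at least two readings")
  if (window < 2 || window > length(times))
    abort("window must lie in [2, number of readings]")
  best <- -Inf
  for (i in seq_len(length(times) - window + 1)) {
    idx <- i:(i + window - 1)
    if (any(od[idx] <= 0)) next
    t <- times[idx]; l <- log(od[idx])
    slope <- sum((t - mean(t)) * (l - mean(l))) / sum((t - mean(t))^2)
    best <- max(best, slope)
  }
  if (!is.finite(best)) abort("no window with all-positive OD readings")
  best
}

#' Luria-Delbruck mutant-count distribution
#'
#' Probabilities `p_0 .. p_r_max` of observing r mutant colonies in a
#' fluctuation-test culture with `m` expected mutation events, under the
#' Lea-Coulson model, computed by the Ma-Sandri-Sarkar recursion:
#' `p_0 = exp(-m)`; `p_r = (m/r) * sum_{i=0}^{r-1} p_i / (r - i + 1)`.
#'
#' @param m Expected mutations per culture (>= 0).
#' @param r_max Largest count to evaluate.
#' @return Numeric vector of length `r_max + 1` (probabilities of 0..r_max).
#' @export
luria_delbruck_pmf <- function(m, r_max) {
  if (m < 0) abort("m must be non-negative")
  p <- numeric(r_max + 1)
  p[1] <- exp(-m)
  if (r_max >= 1 && p[1] > 0) {
    winv <- 1 / (2:(r_max + 1))  # 1/(r - i + 1) for lag r - i = 1..r
    for (r in 1:r_max) {
      p[r + 1] <- m / r * sum(p[1:r] * winv[r:1])
    }
  }
  p
}

#' Maximum-likelihood number of mutations per culture (MSS method)
#'
#' Estimates `m`, the expected number of mutation events per culture, from
#' the mutant-colony counts of parallel cultures by maximising the
#' Ma-Sandri-Sarkar likelihood. The ML approach is robust to jackpot
#' cultures, which inflate naive mean-based estimators. Counts above
#' `r_cap` are treated as right-censored at `r_cap` (their probability is
#' the upper tail of the distribution), keeping the recursion tractable for
#' extreme jackpots. The 1-D optimisation is performed on the log(m) scale
#' to a relative tolerance of about 1e-6; an all-zero count vector returns
#' the boundary estimate m = 0.
#'
#' @param mutant_counts Non-negative integer counts, one per culture (>= 2).
#' @param r_cap Censoring bound for jackpot counts (default 1000).
#' @return The ML estimate `m_hat`.
#' @export
mss_mle <- function(mutant_counts, r_cap = 1000) {
  if (length(mutant_counts) < 2) abort("need at least two cultures")
  if (any(mutant_counts < 0)) abort("counts must be non-negative")
  if (all(mutant_counts == 0)) return(0)
  counts <- pmin(mutant_counts, r_cap)
  censored <- mutant_counts > r_cap
  r_need <- max(counts)
  tab <- table(counts[!censored])
  obs <- as.integer(names(tab))
  n_obs <- as.integer(tab)
  n_cens <- sum(censored)

  loglik <- function(log_m) {
    m <- exp(log_m)
    p <- luria_delbruck_pmf(m, r_need)
    ll <- sum(n_obs * log(pmax(p[obs + 1], 1e-300)))
    if (n_cens > 0) ll <- ll + n_cens * log(max(1 - sum(p), 1e-300))
    ll
  }
  upper <- log(max(2, max(counts)))
  opt <- optimize(loglik, interval = c(log(1e-6), upper), maximum = TRUE,
                  tol = 1e-6)
  exp(opt$maximum)
}

#' Fold change in mutation rate between two strains
#'
#' Mutation rate is `m / Nt` (expected mutations per culture over final cells
#' per culture); the fold change is the ratio of the two strains' rates.
#'
#' @param m_mut,Nt_mut Mutant-strain estimate and final census per culture.
#' @param m_anc,Nt_anc Ancestral-strain estimate and final census.
#' @return The fold change; `NA` when the ancestral estimate is 0.
#' @export
rate_fold_change <- function(m_mut, Nt_mut, m_anc, Nt_anc) {
  if (any(c(Nt_mut, Nt_anc) <= 0)) abort("final census must be positive")
  if (m_anc <= 0) return(NA_real_)
  (m_mut / Nt_mut) / (m_anc / Nt_anc)
}

#' Simulate a fluctuation assay
#'
#' Draws mutant counts for parallel cultures under the Lea-Coulson model:
#' the number of mutation events per culture is Poisson(`m`), and each event
#' founds a clone whose final size k has the classic size-biased tail
#' P(size >= k) = 1/k (sampled by inverse transform as floor(1/U)), capped
#' at the culture's final census.
#'
#' @param m Expected mutation events per culture.
#' @param Nt Final cells per culture (cap on clone size).
#' @param n_cultures Number of parallel cultures.
#' @param seed Optional RNG seed.
#' @return Integer vector of mutant counts, one per culture.
#' @export
simulate_fluctuation <- function(m, Nt, n_cultures, seed = NULL) {
  if (m < 0) abort("m must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  events <- rpois(n_cultures, m)
  total <- sum(events)
  if (total == 0) return(integer(n_cultures))
  sizes <- pmin(floor(1 / runif(total)), Nt)
  culture <- rep(seq_len(n_cultures), events)
  counts <- vapply(seq_len(n_cultures), function(i) {
    sum(sizes[culture == i])
  }, numeric(1))
  as.integer(pmin(counts, .Machine$integer.max))
}
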