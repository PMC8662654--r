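# small programmatic fixtures shared across test files

# one call row in the native dialect, with overridable fields
call_row <- function(position, frequency = 0.1, day = 17, population = "P1",
                     ref = "A", alt = "G", kind = "SNP",
                     effect = "nonsynonymous", locus = "geneA",
                     fwd_reads = 10, rev_reads = 10, depth = 100) {
  data.frame(population = population, day = day, position = position,
             ref = ref, alt = alt, kind = kind, effect = effect,
             locus = locus, frequency = frequency, fwd_reads = fwd_reads,
             rev_reads = rev_reads, depth = depth, stringsAsFactors = FALSE)
}

toy_calls <- function(...) do.call(rbind, list(...))

# hand-build a genotype_clusters object from named inclusive trajectories
fake_clusters <- function(traj, days = seq_len(ncol(traj)),
                          detection_floor = 0) {
  first_day <- apply(traj, 1, function(f) {
    det <- which(f > detection_floor)
    if (length(det) == 0) max(days) else days[det[1]]
  })
  members <- setNames(lapply(rownames(traj), function(id) paste0("m_", id)),
                      rownames(traj))
  structure(list(members = members, trajectory = traj, days = days,
                 first_detected_day = first_day,
                 detection_floor = detection_floor, population = "toy"),
            class = "genotype_clusters")
}

# leave-one-out Cook's distance oracle: refit without point i and accumulate
# squared shifts in the fitted values, scaled by p * s^2 from the full fit
cooks_loo_oracle <- function(x, y) {
  fit <- lm(y ~ x)
  s2 <- sum(residuals(fit)^2) / (length(x) - 2)
  yhat <- fitted(fit)
  vapply(seq_along(x), function(i) {
    fit_i <- lm(y[-i] ~ x[-i])
    yhat_i <- coef(fit_i)[1] + coef(fit_i)[2] * x
    sum((yhat - yhat_i)^2) / (2 * s2)
  }, numeric(1))
}

# hypergeometric upper tail by direct log-binomial summation (independent of
# phyper): P(X >= k) with population G, M successes, L draws
hyper_tail_oracle <- function(k, L, M, G) {
  x <- k:min(M, L)
  sum(exp(lchoose(M, x) + lchoose(G - M, L - x) - lchoose(G, L)))
}

# cluster labels aligned to a trajectory table's mutation order
cluster_labels <- function(clusters, table) {
  lab <- rep(names(clusters$members), lengths(clusters$members))
  names(lab) <- unlist(clusters$members, use.names = FALSE)
  unname(lab[table$mutations$id])
}
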