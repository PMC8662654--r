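toy_annotations <- data.frame(
  locus = c("geneA", "geneB", "geneC"),
  length_bp = c(1000L, 1500L, 800L),
  functional_class = c("transport", "regulation", "unknown"))

test_that("multiplicity accounting counts cases by class and population", {
  calls <- toy_calls(
    call_row(100, population = "B1", locus = "geneA", effect = "nonsynonymous",
             frequency = 0.2),
    call_row(200, population = "B2", locus = "geneA", effect = "nonsynonymous",
             frequency = 0.9),
    call_row(300, population = "P1", locus = "geneA", effect = "synonymous",
             frequency = 0.1),
    call_row(400, population = "P1", locus = "geneB", effect = "indel",
             frequency = 0.3))
  rec <- multiplicity_table(calls, toy_annotations)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$locus, "geneA")
  expect_equal(rec$total_cases, 3)
  expect_equal(c(rec$ns, rec$s, rec$indel), c(2L, 1L, 0L))
  expect_equal(c(rec$B1, rec$B2, rec$P1), c(1L, 1L, 1L))
  expect_equal(rec$max_frequency, 90)
  expect_equal(rec$locus_length, 1000L)

  # nonsense counts as NS; no locus hit twice -> empty table
  lonely <- calls[c(1, 4), ]
  expect_equal(nrow(multiplicity_table(lonely, toy_annotations)), 0)
  expect_error(multiplicity_table(transform(calls, locus = "geneX"),
                                  toy_annotations), "missing from annotations")
})

test_that("locus Fisher test equals the hypergeometric tail", {
  expect_equal(fisher_locus_test(0, 1000, 624, 6537648), 1)
  # boundary sanity: with all but one base inside the locus, p is just
  # 1 - M/G (the chance that no mutation sits on the excluded base)
  expect_equal(fisher_locus_test(624, 6537647, 624, 6537648),
               1 - 624 / 6537648, tolerance = 1e-9)

  p <- fisher_locus_test(3, 1000, 624, 6537648)
  expect_equal(p, hyper_tail_oracle(3, 1000, 624, 6537648),
               tolerance = 1e-12)
  # and it is what fisher.test computes for the 2x2 base-count table
  ft <- fisher.test(matrix(c(3, 1000 - 3, 624 - 3, 6537648 - 1000 - 621),
                           nrow = 2), alternative = "greater")
  expect_equal(p, ft$p.value, tolerance = 1e-9)
  expect_error(fisher_locus_test(5, 3, 624, 6537648), "k > L")
})

test_that("Fisher test matches brute-force tail sums on a reduced grid", {
  G <- 1e5; M <- 100
  for (L in c(10, 100, 1000, 10000)) {
    for (k in c(0:5, 10, 20)) {
      if (k > L) next
      p <- fisher_locus_test(k, L, M, G)
      oracle <- hyper_tail_oracle(k, L, M, G)
      expect_lt(abs(p - oracle) / oracle, 1e-9)
    }
  }
})

test_that("Benjamini-Hochberg step-up flags match hand evaluation", {
  expect_equal(bh_correct(rep(1, 5)), rep(FALSE, 5))
  # thresholds 0.0125/0.025/0.0375/0.05: all four pass
  expect_equal(bh_correct(c(0.001, 0.01, 0.02, 0.04)), rep(TRUE, 4))
  # 0.04 > 0.0125 and the rest are hopeless: none pass
  expect_equal(bh_correct(c(0.04, 0.9, 0.9, 0.9)), rep(FALSE, 4))
  # flags agree with p.adjust step-up in input order
  set.seed(4)
  for (i in 1:25) {
    p <- runif(20)^sample(1:4, 1)
    expect_equal(bh_correct(p, 0.05), p.adjust(p, "BH") <= 0.05)
  }
})

test_that("lowering a p-value never turns another locus non-significant", {
  set.seed(5)
  for (i in 1:20) {
    p <- runif(15)
    base <- bh_correct(p, 0.05)
    j <- sample(15, 1)
    p2 <- p; p2[j] <- p[j] / 10
    after <- bh_correct(p2, 0.05)
    expect_true(all(after[-j] >= base[-j]))
  }
})

test_that("uniform null placement keeps the flagged fraction near the FDR", {
  set.seed(6)
  # genome-scale null: 624 mutations scattered over a 6.5 Mb genome carved
  # into 1 kb loci, screening loci hit twice or more
  G <- 6537000; M <- 624; L <- 1000
  n_loci <- G / L
  flagged <- 0
  for (i in 1:200) {
    pos <- sample.int(G, M, replace = TRUE)
    k <- tabulate((pos - 1) %/% L + 1, nbins = n_loci)
    sel <- which(k >= 2)
    if (length(sel) == 0) next
    p <- fisher_locus_test(k[sel], L, M, G)
    flags <- bh_correct(p, 0.05)
    flagged <- flagged + sum(flags)
  }
  # fraction of the genome's loci flagged under the null stays below the FDR
  total <- 200 * n_loci
  frac <- flagged / total
  se <- sqrt(0.05 * 0.95 / total)
  expect_lte(frac, 0.05 + 3 * se)
})

test_that("dN/dS normalisation is the neutral identity", {
  expect_equal(normalized_dnds(2.96, 1), 1)
  for (x in c(0.5, 1, 3, 10)) expect_equal(normalized_dnds(2.96 * x, x), 1)
  expect_equal(normalized_dnds(10, 2), 5 / 2.96)
  expect_true(is.na(normalized_dnds(5, 0)))
  expect_error(normalized_dnds(-1, 2), "non-negative")
})

test_that("neutral NS/S enumeration classifies all nine changes per codon", {
  code <- evoreseq:::genetic_code()
  usage <- setNames(rep(0, 64), names(code))
  usage["AAA"] <- 1
  # AAA (Lys): only AAG is synonymous -> 8 NS / 1 S
  expect_equal(neutral_dnds_from_codon_usage(usage), 8)

  # uniform usage: cross-check by independent enumeration against the
  # Biostrings genetic code
  uniform <- setNames(rep(1 / 64, 64), names(code))
  got <- neutral_dnds_from_codon_usage(uniform)
  bs_code <- Biostrings::GENETIC_CODE
  ns <- 0; s <- 0
  for (cod in names(bs_code)) {
    for (pos in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(cod, pos, pos))) {
        alt <- cod; substr(alt, pos, pos) <- b
        if (bs_code[[alt]] == bs_code[[cod]]) s <- s + 1 else ns <- ns + 1
      }
    }
  }
  expect_equal(got, ns / s, tolerance = 1e-12)

  # two-codon mixture combines NS and S weights, not per-codon ratios:
  # AAA gives 8 NS / 1 S, CTT (Leu) gives 6 NS / 3 S, so the equal-weight
  # mixture is 7/2 = 3.5, not the mean of 8 and 2
  two <- setNames(rep(0, 64), names(code))
  two[c("AAA", "CTT")] <- 0.5
  expect_equal(neutral_dnds_from_codon_usage(two), 3.5)
  expect_error(neutral_dnds_from_codon_usage(uniform * 2), "sum to 1")
})

test_that("lifestyle specificity is read off per-population occupancy", {
  rec <- data.frame(locus = c("x", "y", "z"),
                    B1 = c(2, 0, 1), B2 = c(0, 0, 0), B3 = c(1, 0, 0),
                    P1 = c(0, 1, 2), P2 = c(0, 0, 0), P3 = c(0, 2, 0))
  tm <- c(B1 = "biofilm", B2 = "biofilm", B3 = "biofilm",
          P1 = "planktonic", P2 = "planktonic", P3 = "planktonic")
  ls <- lifestyle_specificity(rec, tm)
  expect_equal(ls$specificity, c("biofilm-only", "planktonic-only", "shared"))
  expect_error(lifestyle_specificity(rec[, 1:4], tm), "lack population")
})

test_that("the bundled parallelism table reproduces its printed accounting", {
  path <- system.file("extdata", "pa14_parallel_loci.tsv",
                      package = "evoreseq")
  rec <- read_parallel_loci(path)
  sm <- parallelism_summary(rec, min_cases = 3)
  expect_equal(sm$n_loci, 40)
  expect_equal(sm$n_cases, 179)

  tm <- c(B1 = "biofilm", B2 = "biofilm", B3 = "biofilm",
          P1 = "planktonic", P2 = "planktonic", P3 = "planktonic")
  ls <- lifestyle_specificity(rec, tm)
  biofilm_only <- ls$locus[ls$specificity == "biofilm-only"]
  expect_true(all(c("rpoB", "gacS", "PA14_71750", "PA14_13150") %in%
                    biofilm_only))
  expect_setequal(ls$locus[ls$specificity == "planktonic-only"],
                  c("PA14_51840", "PA14_47900"))
})

test_that("enrichment testing attaches p-values and BH flags to records", {
  calls <- do.call(rbind, c(
    lapply(1:5, function(i) call_row(i * 10, population = paste0("B", i %% 3 + 1),
                                     locus = "geneA")),
    lapply(1:2, function(i) call_row(5000 + i * 10, population = "P1",
                                     locus = "geneC"))))
  rec <- multiplicity_table(calls, toy_annotations)
  rec <- add_enrichment_test(rec, M = 7, G = 1e6, Q = 0.05)
  expect_true(all(rec$p_value >= 0 & rec$p_value <= 1))
  expect_equal(rec$p_value,
               fisher_locus_test(rec$total_cases, rec$locus_length, 7, 1e6))
  expect_type(rec$significant, "logical")
})
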