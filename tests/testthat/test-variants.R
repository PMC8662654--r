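test_that("read_calls parses the native TSV dialect and validates rows", {
  calls <- toy_calls(call_row(100), call_row(200, alt = "T"),
                     call_row(300, frequency = 0.9))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(calls, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_calls(f)
  expect_equal(nrow(got), 3)
  expect_equal(got$position, c(100L, 200L, 300L))
  expect_equal(got$frequency, c(0.1, 0.1, 0.9))

  # header-only file -> empty set
  write.table(calls[0, ], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_calls(f)), 0)

  # missing column
  write.table(calls[-1], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_calls(f), "missing required column")

  # out-of-range frequency reported with its row number
  bad <- calls; bad$frequency[2] <- 1.7
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_calls(f), "frequency outside \\[0,1\\] in row\\(s\\): 2")
})

test_that("a DP4-style VCF record maps onto frequency and strand support", {
  vcf <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"allele freq\">",
           "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"strand depths\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           "chr1\t1234\t.\tA\tG\t50\tPASS\tAF=0.25;DP4=30,30,11,9")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  got <- read_calls(f, dialect = "vcf", population = "P1", day = 17)
  expect_equal(got$position, 1234L)
  expect_equal(got$frequency, 0.25)
  expect_equal(got$fwd_reads, 11L)
  expect_equal(got$rev_reads, 9L)
  expect_equal(got$depth, 80L)
  expect_equal(got$kind, "SNP")
})

test_that("ancestral variants are subtracted as a set difference", {
  calls <- do.call(rbind, lapply(1:10, function(i) call_row(i * 100)))
  expect_identical(subtract_ancestor(calls, NULL), calls)
  anc_all <- data.frame(position = calls$position, alt = calls$alt)
  expect_equal(nrow(subtract_ancestor(calls, anc_all)), 0)
  anc3 <- anc_all[c(2, 5, 9), ]
  left <- subtract_ancestor(calls, anc3)
  expect_equal(nrow(left), 7)
  expect_false(any(left$position %in% anc3$position))
  # same position, different alt is a different mutation
  anc_other <- data.frame(position = 100, alt = "T")
  expect_equal(nrow(subtract_ancestor(calls, anc_other)), 10)
})

test_that("strand-support filter requires min reads on both strands", {
  support <- list(c(3, 3), c(2, 3), c(3, 2), c(0, 0), c(5, 5), c(4, 1))
  calls <- do.call(rbind, lapply(seq_along(support), function(i) {
    call_row(i * 50, fwd_reads = support[[i]][1], rev_reads = support[[i]][2],
             depth = 20)
  }))
  kept <- filter_strand_support(calls)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$position, c(50, 250))  # (3,3) and (5,5)
  # boundary: exactly 3 on each strand is retained; 10/2 is dropped
  expect_equal(nrow(filter_strand_support(call_row(1, fwd_reads = 10,
                                                   rev_reads = 2))), 0)
})

test_that("mutation-scope strand filtering keeps whole qualifying trajectories", {
  calls <- toy_calls(
    call_row(100, day = 17, fwd_reads = 5, rev_reads = 5),
    call_row(100, day = 44, fwd_reads = 6, rev_reads = 1),  # weak day kept
    call_row(200, day = 17, fwd_reads = 2, rev_reads = 2),
    call_row(200, day = 44, fwd_reads = 2, rev_reads = 9))  # never qualifies
  kept <- filter_strand_support(calls, scope = "mutation")
  expect_equal(sort(unique(kept$position)), 100)
  expect_equal(nrow(kept), 2)
})

test_that("dense-window exclusion drops calls with too many close neighbours", {
  lone <- call_row(5000)
  expect_equal(nrow(filter_dense_windows(lone)), 1)

  quad <- do.call(rbind, lapply(c(100, 105, 110, 112), call_row))
  expect_equal(nrow(filter_dense_windows(quad, window = 15, max_neighbors = 2)), 0)

  pair <- do.call(rbind, lapply(c(100, 140), call_row))
  expect_equal(nrow(filter_dense_windows(pair)), 2)

  # neighbour counts are per population+day: same positions on another day
  # do not interact
  two_days <- rbind(quad, transform(quad, day = 44))
  expect_equal(nrow(filter_dense_windows(two_days)), 0)
})

test_that("repeat masking drops positions inside intervals, ends inclusive", {
  calls <- do.call(rbind, lapply(c(10, 50, 100, 150, 200), call_row))
  expect_identical(filter_repeat_mask(calls, NULL), calls)
  mask <- data.frame(start = c(40, 150), end = c(60, 160))
  kept <- filter_repeat_mask(calls, mask)
  expect_equal(kept$position, c(10, 100, 200))  # 50 inside, 150 on boundary
})

test_that("ancestor/strand/mask filters commute as set operations", {
  set.seed(11)
  calls <- do.call(rbind, lapply(1:40, function(i) {
    call_row(sample.int(10000, 1), day = sample(c(17, 44), 1),
             fwd_reads = sample(0:6, 1), rev_reads = sample(0:6, 1),
             depth = 20)
  }))
  calls <- calls[!duplicated(paste(calls$position, calls$day)), ]
  anc <- data.frame(position = calls$position[1:5], alt = calls$alt[1:5])
  mask <- data.frame(start = 2000, end = 4000)
  filters <- list(
    a = function(x) subtract_ancestor(x, anc),
    s = function(x) filter_strand_support(x),
    m = function(x) filter_repeat_mask(x, mask))
  perms <- list(c("a", "s", "m"), c("a", "m", "s"), c("s", "a", "m"),
                c("s", "m", "a"), c("m", "a", "s"), c("m", "s", "a"))
  results <- lapply(perms, function(p) {
    out <- calls
    for (f in p) out <- filters[[f]](out)
    sort(paste(out$position, out$day))
  })
  for (r in results[-1]) expect_identical(r, results[[1]])
})

test_that("trajectory tables consolidate calls keyed on (position, ref, alt)", {
  calls <- toy_calls(call_row(100, day = 17, frequency = 0.2),
                     call_row(100, day = 44, frequency = 0.6))
  tab <- build_trajectories(calls, days = c(17, 44, 66, 90))
  expect_equal(unname(tab$freq[1, ]), c(0.2, 0.6, 0, 0))

  # disjoint mutation sets on two days union to five rows
  calls5 <- toy_calls(call_row(100, day = 17), call_row(200, day = 17),
                      call_row(300, day = 44), call_row(400, day = 44),
                      call_row(500, day = 44))
  tab5 <- build_trajectories(calls5)
  expect_equal(nrow(tab5$freq), 5)
  expect_true(all(rowSums(tab5$freq > 0) == 1))

  dup <- rbind(calls, call_row(100, day = 17, frequency = 0.3))
  expect_error(build_trajectories(dup), "duplicate")

  multi_pop <- rbind(calls, call_row(900, population = "P2"))
  expect_error(build_trajectories(multi_pop), "single population")
})

test_that("trajectory building inverts the simulator's written dataset", {
  cfg <- sim_config(n_bottleneck = 2e4, n_days = 60, mu = 5e-5,
                    frac_beneficial = 0.3, dfe_mean_s = 0.08,
                    sample_days = c(20, 40, 60), population = "rt",
                    seed = 7)
  res <- simulate_population(cfg)
  expect_gt(nrow(res$observed_calls), 0)
  outdir <- withr::local_tempdir()
  write_dataset(res, outdir)
  files <- list.files(outdir, pattern = "_calls\\.tsv$", full.names = TRUE)
  back <- do.call(rbind, lapply(sort(files), read_calls))
  rownames(back) <- NULL
  expect_equal(back, res$observed_calls, tolerance = 1e-12)

  tab <- build_trajectories(back, days = cfg$sample_days)
  key <- paste(back$position, back$day)
  expect_equal(tab$freq[cbind(match(sprintf("%d:%s>%s", back$position,
                                            back$ref, back$alt),
                                    rownames(tab$freq)),
                              match(back$day, tab$days))],
               back$frequency)
})

test_that("all twelve single-base substitutions classify 4:8 ts:tv", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_substitution(pairs$ref, pairs$alt)
  expect_equal(sum(cls == "transition"), 4)
  expect_equal(sum(cls == "transversion"), 8)
  expect_equal(classify_substitution("A", "AT"), "indel")
  expect_equal(classify_substitution("AC", "A"), "indel")
  expect_error(classify_substitution("N", "A"), "ambiguous")
})

test_that("spectrum summary reports class fractions", {
  empty <- spectrum_summary(read_calls_fixture <- call_row(1)[0, ])
  expect_equal(empty$count, c(0L, 0L, 0L))
  calls <- rbind(
    do.call(rbind, lapply(1:6, function(i) call_row(i, ref = "A", alt = "G"))),
    do.call(rbind, lapply(7:8, function(i) call_row(i, ref = "A", alt = "T"))),
    do.call(rbind, lapply(9:10, function(i) call_row(i, ref = "A", alt = "AT",
                                                     kind = "insertion"))))
  sp <- spectrum_summary(calls)
  expect_equal(sp$fraction, c(0.6, 0.2, 0.2))
  expect_equal(sum(sp$count), 10)
})

test_that("a transition-biased generator yields an elevated transition fraction", {
  cfg_bias <- sim_config(n_bottleneck = 2e4, n_days = 30, mu = 5e-5,
                         ts_prob = 0.9, indel_prob = 0.1, seed = 5,
                         sample_days = 30)
  cfg_null <- sim_config(n_bottleneck = 2e4, n_days = 30, mu = 5e-5,
                         ts_prob = 1 / 3, indel_prob = 0.1, seed = 5,
                         sample_days = 30)
  sp_bias <- spectrum_summary(simulate_population(cfg_bias)$mutation_assignments)
  sp_null <- spectrum_summary(simulate_population(cfg_null)$mutation_assignments)
  ts <- function(sp) sp$fraction[sp$class == "transition"]
  expect_gt(ts(sp_bias), ts(sp_null))
  expect_gt(ts(sp_bias), 0.6)
})
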