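cat_ <- stcdf1_catalog()

test_that("single reads classify by exact pattern on either strand", {
  r <- classify_read(table1_patterns$StCDF1.2a, cat_)
  expect_identical(r$allele, "StCDF1.2a")
  expect_identical(r$match_strand, "+")
  r2 <- classify_read(rc_chr(table1_patterns$StCDF1.1), cat_)
  expect_identical(r2$allele, "StCDF1.1")
  expect_identical(r2$match_strand, "-")
  # a full transposon amplicon contains both junction patterns -> one call
  amp <- assemble_allele_sequence("StCDF1.3", catalog = cat_)
  expect_true(all(vapply(table1_patterns$StCDF1.3,
                         function(p) grepl(p, amp, fixed = TRUE), TRUE)))
  r3 <- classify_read(amp, cat_)
  expect_identical(r3$allele, "StCDF1.3")
  expect_identical(r3$status, "classified")
  expect_error(classify_read("ACGTN", cat_), "non-ACGT")
  expect_error(classify_read("", cat_), "non-empty")
})

test_that("classification agrees with the naive substring oracle on random reads", {
  withr::with_seed(77, {
    pats <- unlist(cat_$patterns, use.names = FALSE)
    seqs <- vapply(1:2000, function(i) {
      s <- random_dna(sample(60:200, 1))
      roll <- runif(1)
      if (roll < 0.4) { # embed a pattern, sometimes reverse complemented
        p <- sample(pats, 1)
        if (runif(1) < 0.5) p <- rc_chr(p)
        cut <- sample(0:nchar(s), 1)
        s <- paste0(substr(s, 1, cut), p, substr(s, cut + 1, nchar(s)))
      }
      s
    }, "")
    got <- classify_reads(seqs, cat_)
    expect_identical(got$allele, oracle_classify(seqs, cat_))
    expect_true(all(got$status[is.na(got$allele)] %in% c("unclassified", "ambiguous")))
  })
})

test_that("count_alleles satisfies read accounting", {
  withr::with_seed(5, {
    reads <- c(rep(table1_patterns$StCDF1.1, 50),
               vapply(1:50, function(i) random_dna(80), ""))
  })
  cnt <- count_alleles(reads, cat_, sample_id = "s")
  expect_identical(cnt$count[cnt$allele == "StCDF1.1"], 50L)
  expect_identical(sum(cnt$count) + attr(cnt, "n_unclassified"),
                   attr(cnt, "n_total_reads"))
  g <- glance(cnt)
  expect_identical(g$n_unclassified, 50L)
})

test_that("simulated 2:2 mixture counts stay within binomial error of half", {
  r <- simulate_reads(c(StCDF1.1 = 2, StCDF1.3 = 2), cat_,
                      read_sim_config(n_reads = 5000, error_rate = 0, seed = 14))
  cnt <- count_alleles(r, cat_)
  se <- sqrt(0.25 * 5000)
  for (a in c("StCDF1.1", "StCDF1.3")) {
    expect_lt(abs(cnt$count[cnt$allele == a] - 2500), 3 * se)
  }
})

test_that("the minimum-frequency filter excludes below 5% and keeps the boundary", {
  mk <- function(counts) {
    tibble::tibble(sample_id = "s", allele = names(counts),
                   count = as.integer(counts))
  }
  f1 <- estimate_frequencies(mk(c(A = 97, B = 3)))
  expect_false(f1$retained[f1$allele == "B"])
  f2 <- estimate_frequencies(mk(c(A = 95, B = 5)))
  expect_true(all(f2$retained))
  f3 <- estimate_frequencies(mk(c(A = 100)))
  expect_identical(f3$freq, 1)
  expect_true(f3$retained)
  expect_error(estimate_frequencies(mk(c(A = 0))),
               class = "bolterseq_error_no_classified_reads")
  # frequencies over all alleles always sum to one
  expect_equal(sum(f1$freq), 1, tolerance = 1e-9)
})

test_that("dosage inference maximizes the multinomial likelihood", {
  mk <- function(counts) {
    estimate_frequencies(tibble::tibble(sample_id = "s", allele = names(counts),
                                        count = as.integer(counts)))
  }
  d1 <- infer_dosage(mk(c(StCDF1.1 = 2500, StCDF1.3 = 2500)))
  expect_identical(d1$dosage, c(2L, 2L))
  d2 <- infer_dosage(mk(c(StCDF1.1 = 1250, StCDF1.3 = 3750)))
  expect_identical(setNames(d2$dosage, d2$allele),
                   c(StCDF1.1 = 1L, StCDF1.3 = 3L))
  # eightfold PCR bias: observed 8/9 vs 1/9 is a balanced duplex genotype
  d3 <- infer_dosage(mk(c(StCDF1.1 = 4444, StCDF1.3 = 556)),
                     bias = c(StCDF1.1 = 8, StCDF1.3 = 1))
  expect_identical(d3$dosage, c(2L, 2L))
  expect_identical(sum(d3$dosage), 4L)
  expect_error(infer_dosage(mk(c(A = 20, B = 20, C = 20, D = 20, E = 20)),
                            ploidy = 4), "more retained alleles than ploidy")
  g <- glance(d1)
  expect_identical(g$ploidy, 4L)
  expect_lt(g$log_likelihood, 0)
})

test_that("dosage recovery from simulated reads succeeds across 2-3 allele genotypes", {
  genos <- list(
    c(StCDF1.1 = 2, StCDF1.3 = 2),
    c(StCDF1.1 = 1, StCDF1.3 = 3),
    c(StCDF1.1 = 3, StCDF1.2a = 1),
    c(StCDF1.1 = 2, StCDF1.3 = 1, StCDF1.2a = 1),
    c(StCDF1.2b = 2, StCDF1.7 = 1, StCDF1.8 = 1)
  )
  for (i in seq_along(genos)) {
    r <- simulate_reads(genos[[i]], cat_,
                        read_sim_config(n_reads = 5000, error_rate = 0.005,
                                        seed = 400 + i))
    call <- infer_dosage(estimate_frequencies(count_alleles(r, cat_)))
    got <- setNames(call$dosage, call$allele)
    expect_identical(got[order(names(got))],
                     vapply(genos[[i]], as.integer, 0L)[order(names(genos[[i]]))],
                     info = paste("genotype", i))
  }
})

test_that("compare_samples detects the excision signature", {
  mk <- function(counts, id) {
    estimate_frequencies(tibble::tibble(sample_id = id, allele = names(counts),
                                        count = as.integer(counts)))
  }
  ctrl <- mk(c(StCDF1.1 = 500, StCDF1.3 = 500), "ctrl")
  # excision in a simplex variety: transposon allele entirely absent
  cand <- mk(c(StCDF1.1 = 500, StCDF1.2a = 500), "cand")
  ev <- compare_samples(ctrl, cand, cat_)
  expect_identical(ev$te_allele_change, "absent")
  expect_identical(ev$new_alleles[[1]], "StCDF1.2a")
  expect_identical(ev$verdict, "bolter")
  # identical sample: true to type
  ev2 <- compare_samples(ctrl, mk(c(StCDF1.1 = 500, StCDF1.3 = 500), "c2"), cat_)
  expect_identical(ev2$verdict, "true_to_type")
  # duplex variety, one of two TE doses excised: ~50% reduction
  ev3 <- compare_samples(ctrl, mk(c(StCDF1.1 = 500, StCDF1.3 = 250,
                                    StCDF1.2a = 250), "c3"), cat_)
  expect_identical(ev3$te_allele_change, "reduced")
  expect_identical(ev3$verdict, "bolter")
  # control without the transposon allele cannot produce excision bolters
  noTE <- mk(c(StCDF1.1 = 1000), "c4")
  expect_warning(ev4 <- compare_samples(noTE, cand, cat_), "cannot produce")
  expect_identical(ev4$verdict, "inconclusive")
})

test_that("one excised dose out of two halves the transposon read frequency", {
  drops <- vapply(1:20, function(s) {
    ctrl <- simulate_reads(c(StCDF1.1 = 2, StCDF1.3 = 2), cat_,
                           read_sim_config(n_reads = 2000, error_rate = 0.005,
                                           seed = 2000 + s))
    bolt <- simulate_reads(c(StCDF1.1 = 2, StCDF1.3 = 1, StCDF1.2a = 1), cat_,
                           read_sim_config(n_reads = 2000, error_rate = 0.005,
                                           seed = 3000 + s))
    fc <- estimate_frequencies(count_alleles(ctrl, cat_))
    fb <- estimate_frequencies(count_alleles(bolt, cat_))
    te <- "StCDF1.3"
    1 - fb$freq[fb$allele == te] / fc$freq[fc$allele == te]
  }, 0)
  expect_gt(mean(drops), 0.40)
  expect_lt(mean(drops), 0.60)
})

test_that("frequency matrix widens to samples by alleles", {
  r <- simulate_reads(c(StCDF1.1 = 4), cat_, read_sim_config(n_reads = 50, seed = 1))
  f <- estimate_frequencies(count_alleles(r, cat_, sample_id = "s1"))
  wide <- frequency_matrix(f)
  expect_identical(nrow(wide), 1L)
  expect_identical(wide$StCDF1.1, 1)
})
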