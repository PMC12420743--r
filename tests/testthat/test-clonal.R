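cat_ <- stcdf1_catalog()

wide_calls <- function(...) {
  # build a wide call table from named lists: sample -> locus -> alleles
  rows <- list()
  args <- list(...)
  for (s in names(args)) {
    for (loc in names(args[[s]])) {
      a <- args[[s]][[loc]]
      a <- c(a, rep(NA_character_, 4 - length(a)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample = s, locus = loc,
        allele_1 = a[1], allele_2 = a[2], allele_3 = a[3], allele_4 = a[4])
    }
  }
  dplyr::bind_rows(rows)
}

test_that("mismatch distances count multiset symmetric differences per locus", {
  calls <- wide_calls(
    s1 = list(L1 = c("a", "a", "b", "c")),
    s2 = list(L1 = c("a", "b", "b", "c")),
    s3 = list(L1 = c("a", "a", "b", "c")))
  m <- mismatch_matrix(calls)
  expect_identical(m["s1", "s2"], 2L)
  expect_identical(m["s1", "s3"], 0L)
  # a bolter differing by a single allele swap sits at distance 2
  calls2 <- wide_calls(
    ctrl = list(L1 = c("TE", "x", "y", "z"), L2 = c("p", "p", "q", "q")),
    bolt = list(L1 = c("FP", "x", "y", "z"), L2 = c("p", "p", "q", "q")))
  expect_identical(mismatch_matrix(calls2)["ctrl", "bolt"], 2L)
})

test_that("missing loci are skipped pairwise and tracked in loci_used", {
  calls <- wide_calls(
    s1 = list(L1 = c("a", "a", "b", "b"), L2 = c("c", "c", "d", "d")),
    s2 = list(L1 = c("a", "a", "b", "b")),
    s3 = list(L1 = c("e", "e", "f", "f"), L2 = c("c", "d", "d", "d")))
  m <- mismatch_matrix(calls, min_shared_frac = 0.9)
  expect_identical(m["s1", "s2"], 0L)
  expect_identical(attr(m, "loci_used")["s1", "s2"], 1L)
  expect_identical(m["s1", "s3"], 8L + 2L)
  expect_true(attr(m, "low_confidence")["s1", "s2"])
  calls_empty <- wide_calls(s1 = list(L1 = c("a")), s2 = list(L1 = c("a")))
  calls_empty$allele_1[calls_empty$sample == "s2"] <- NA_character_
  expect_error(mismatch_matrix(calls_empty), "missing")
})

test_that("set mode collapses duplicate alleles before comparing", {
  calls <- wide_calls(
    s1 = list(L1 = c("a", "a", "a", "b")),
    s2 = list(L1 = c("a", "b", "b", "b")))
  expect_identical(mismatch_matrix(calls)["s1", "s2"], 4L)
  expect_identical(mismatch_matrix(calls, mode = "set")["s1", "s2"], 0L)
})

test_that("mismatch matrices satisfy metric axioms and match the pairwise oracle", {
  withr::with_seed(123, {
    for (rep in 1:10) {
      n_s <- sample(3:8, 1); n_l <- sample(5:20, 1)
      samples <- paste0("s", seq_len(n_s))
      loci <- paste0("L", seq_len(n_l))
      rows <- list()
      for (s in samples) {
        for (loc in loci) {
          if (runif(1) < 0.05) next # missing locus
          a <- sample(letters[1:4], 4, replace = TRUE)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample = s, locus = loc, allele_1 = a[1], allele_2 = a[2],
            allele_3 = a[3], allele_4 = a[4])
        }
      }
      calls <- dplyr::bind_rows(rows)
      m <- unclass(mismatch_matrix(calls))
      o <- oracle_mismatch_matrix(calls)
      expect_identical(m[rownames(o), colnames(o)], o)
      expect_true(isSymmetric(m))
      expect_true(all(diag(m) == 0L))
      for (i in seq_len(nrow(m))) for (j in seq_len(nrow(m))) for (k in seq_len(nrow(m))) {
        expect_lte(m[i, j], m[i, k] + m[k, j])
      }
    }
  })
})

test_that("complete linkage merges two tight groups at their inter-group distance", {
  d <- matrix(10, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  diag(d) <- 0
  hc <- cluster_complete_linkage(d)
  expect_equal(sort(hc$height), c(0, 0, 10))
  expect_identical(unname(stats::cutree(hc, k = 2)[c("s1", "s2", "s3", "s4")]),
                   c(1L, 1L, 2L, 2L))
})

test_that("complete-linkage heights match the naive agglomerative oracle", {
  withr::with_seed(321, {
    for (rep in 1:100) {
      n <- sample(3:6, 1)
      d <- matrix(0, n, n)
      d[upper.tri(d)] <- sample(1:20, n * (n - 1) / 2, replace = TRUE)
      d <- d + t(d)
      dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
      hc <- cluster_complete_linkage(d)
      expect_equal(sort(hc$height), oracle_complete_linkage_heights(d),
                   info = paste("matrix", rep))
    }
  })
})

test_that("permuting sample order yields an isomorphic dendrogram", {
  withr::with_seed(77, {
    n <- 6
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 1, 50)
    d <- d + t(d)
    dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    perm <- sample(n)
    hc1 <- cluster_complete_linkage(d)
    hc2 <- cluster_complete_linkage(d[perm, perm])
    co1 <- stats::cophenetic(hc1)
    co2 <- stats::cophenetic(hc2)
    m1 <- as.matrix(co1); m2 <- as.matrix(co2)
    expect_equal(m1, m2[rownames(m1), colnames(m1)])
  })
})

test_that("admixture flagging separates contaminants from isogenic bolters", {
  clones <- tibble::tibble(
    clone_id = c("V-C1", "V-B1", "V-B2", "V-X1", "V-X2"),
    variety = "V",
    role = c("control", "bolter", "bolter", "contaminant", "contaminant"),
    group = c("V-C1", "V-B1", "V-B2", "pair", "pair"))
  calls <- simulate_multilocus_calls(clones, n_loci = 790, share_frac = 0.7,
                                     seed = 51)
  m <- mismatch_matrix(calls)
  labels <- dplyr::rename(clones, sample = "clone_id")
  rep <- flag_admixture(m, labels)
  expect_identical(rep$flag[rep$role == "contaminant"], rep("admixture", 2))
  expect_identical(rep$flag[rep$role != "contaminant"], rep("isogenic", 3))
  expect_identical(m["V-X1", "V-X2"], 0L)
  # a variety with no control cannot be evaluated
  labels2 <- labels
  labels2$variety[labels2$role == "control"] <- "other"
  rep2 <- flag_admixture(m, labels2)
  expect_true(all(rep2$flag[rep2$variety == "V"] == "unevaluable"))
})

test_that("mosaic verdicts follow the per-stem retained allele sets", {
  mk <- function(counts, id) {
    estimate_frequencies(tibble::tibble(sample_id = id, allele = names(counts),
                                        count = as.integer(counts)))
  }
  stem1 <- mk(c(StCDF1.1 = 500, StCDF1.3 = 500), "p1-stemA")
  stem2 <- mk(c(StCDF1.1 = 500, StCDF1.2b = 500), "p1-stemB")
  mos <- detect_mosaic(list(stem1, stem2), cat_)
  expect_identical(mos$verdict, "mosaic")
  expect_false(mos$chimera_flag)
  uni <- detect_mosaic(list(mk(c(StCDF1.1 = 500, StCDF1.2a = 500), "a"),
                            mk(c(StCDF1.1 = 500, StCDF1.2a = 480), "b")), cat_)
  expect_identical(uni$verdict, "uniform")
  chim <- detect_mosaic(list(stem1,
                             mk(c(StCDF1.1 = 400, StCDF1.3 = 300,
                                  StCDF1.2a = 300), "c")), cat_)
  expect_identical(chim$verdict, "mosaic")
  expect_true(chim$chimera_flag)
  expect_warning(single <- detect_mosaic(list(stem1), cat_), "at least 2")
  expect_identical(single$verdict, "unevaluable")
})

test_that("mosaic verdicts match simulator truth for mixtures down to 0.2", {
  for (fr in c(0.2, 0.5)) {
    pop_mosaic <- cell_population(
      list(c(StCDF1.1 = 2, StCDF1.3 = 2),
           c(StCDF1.1 = 2, StCDF1.2a = 2)),
      fractions = c(1 - fr, fr))
    stems <- list(
      estimate_frequencies(count_alleles(
        simulate_reads(c(StCDF1.1 = 2, StCDF1.3 = 2), cat_,
                       read_sim_config(n_reads = 5000, error_rate = 0.005,
                                       seed = 61), sample_id = "stemA"),
        cat_, sample_id = "stemA")),
      estimate_frequencies(count_alleles(
        simulate_reads(pop_mosaic, cat_,
                       read_sim_config(n_reads = 5000, error_rate = 0.005,
                                       seed = 62), sample_id = "stemB"),
        cat_, sample_id = "stemB")))
    mos <- detect_mosaic(stems, cat_)
    expect_identical(mos$verdict, "mosaic", info = paste("fraction", fr))
    expect_true(mos$chimera_flag)
  }
})

test_that("welch_t reproduces the hand-computed statistic", {
  res <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(res$t, 3), -3.674)
  expect_equal(round(res$df, 1), 4.0)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("the simulated phenotype contrast is reliably significant", {
  hits <- vapply(1:200, function(s) {
    ph <- simulate_phenotypes(
      pheno_sim_config(n = c(bolter = 8, control = 4),
                       sds = list(bolter = c(total_inflorescences = 2,
                                             flowering_inflorescences = 1.5,
                                             stem_length_cm = 8),
                                  control = c(total_inflorescences = 2,
                                              flowering_inflorescences = 0.3,
                                              stem_length_cm = 6))),
      seed = 7000 + s)
    welch_t(ph$total_inflorescences[ph$group == "bolter"],
            ph$total_inflorescences[ph$group == "control"])$p < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("dendrograms export as Newick", {
  d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc <- cluster_complete_linkage(d)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
})
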