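cat_ <- stcdf1_catalog()
loc <- cat_$locus

test_that("aligning the wild-type region to itself yields no edits", {
  a <- align_to_wildtype(loc$variable_region, loc)
  expect_identical(nrow(a$edits), 0L)
  expect_identical(a$strand, "+")
})

test_that("footprint alleles align as a single insertion at the canonical site", {
  a <- align_to_wildtype(assemble_allele_sequence("StCDF1.2b", catalog = cat_), loc)
  expect_identical(nrow(a$edits), 1L)
  expect_identical(a$edits$kind, "insertion")
  expect_identical(a$edits$ref_position, loc$insertion_site)
  expect_identical(a$edits$sequence, "TCACTAG")
  a7 <- align_to_wildtype(assemble_allele_sequence("StCDF1.7", catalog = cat_), loc)
  expect_identical(a7$edits$sequence, "CACTAG")
  expect_identical(a7$edits$ref_position, loc$insertion_site)
})

test_that("a single substitution aligns as one mismatch at its position", {
  s <- loc$variable_region
  pos <- 60L # 0-based
  orig <- substr(s, pos + 1, pos + 1)
  repl <- setdiff(c("A", "C", "G", "T"), orig)[1]
  substr(s, pos + 1, pos + 1) <- repl
  a <- align_to_wildtype(s, loc)
  expect_identical(nrow(a$edits), 1L)
  expect_identical(a$edits$kind, "mismatch")
  expect_identical(a$edits$ref_position, pos)
  expect_identical(a$edits$sequence, repl)
})

test_that("reverse-complement reads align on the minus strand with the same edits", {
  a <- align_to_wildtype(rc_chr(assemble_allele_sequence("StCDF1.2a", catalog = cat_)), loc)
  expect_identical(a$strand, "-")
  expect_identical(a$edits$sequence, "CCACTAG")
})

test_that("alignment scores match the affine-gap DP oracle and edits reconstruct the read", {
  withr::with_seed(303, {
    for (i in 1:100) {
      ref_len <- sample(10:60, 1)
      ref <- random_dna(ref_len)
      # mutate ref into a query: substitutions plus an optional indel
      q <- ref
      nsub <- sample(0:3, 1)
      for (k in seq_len(nsub)) {
        p <- sample(nchar(q), 1)
        substr(q, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      if (runif(1) < 0.5) {
        p <- sample(0:nchar(q), 1)
        q <- paste0(substr(q, 1, p), random_dna(sample(1:8, 1)),
                    substr(q, p + 1, nchar(q)))
      }
      tmp_locus <- locus_model("t", "c", 1, paste0(ref, "ACACTAGG"),
                               insertion_site = nchar(ref) + 7L)
      res <- align_reads(q, tmp_locus)
      reference <- tmp_locus$variable_region
      oracle <- max(oracle_align_score(q, reference),
                    oracle_align_score(rc_chr(q), reference))
      expect_equal(res$score[[1]], oracle, info = paste("case", i))
      rebuilt <- bolterseq:::apply_edits(reference, res$edits[[1]])
      target <- if (res$strand[[1]] == "-") rc_chr(q) else q
      expect_identical(rebuilt, target, info = paste("reconstruction", i))
    }
  })
})

test_that("haplotype grouping recovers mixture frequencies and filters rare profiles", {
  reads <- c(rep(assemble_allele_sequence("StCDF1.2b", catalog = cat_), 60),
             rep(loc$variable_region, 40))
  h <- call_haplotypes(reads, loc)
  expect_identical(nrow(h), 2L)
  expect_equal(sort(h$frequency), c(0.4, 0.6))
  expect_lte(sum(h$frequency), 1)
  # three error reads out of 100 fall below the 5% rule
  err <- loc$variable_region
  substr(err, 30, 30) <- "A"
  h2 <- call_haplotypes(c(rep(loc$variable_region, 97), rep(err, 3)), loc)
  expect_identical(nrow(h2), 1L)
  expect_identical(h2$profile, "ref")
})

test_that("both footprint haplotypes of a mosaic mixture are recovered", {
  pop <- cell_population(
    list(c(StCDF1.1 = 2, StCDF1.2a = 2), c(StCDF1.1 = 2, StCDF1.2b = 2)),
    fractions = c(0.5, 0.5))
  r <- simulate_reads(pop, cat_, read_sim_config(n_reads = 300, error_rate = 0,
                                                 seed = 17))
  h <- call_haplotypes(r, loc)
  named <- discover_alleles(h, cat_)
  expect_setequal(named$known_match, c("StCDF1.1", "StCDF1.2a", "StCDF1.2b"))
})

test_that("te-like detection groups near-miss junction reads by mismatch profile", {
  pat <- cat_$patterns$StCDF1.3[[1]]
  mut <- pat
  substr(mut, 31, 31) <- "C" # inside the element fragment
  substr(mut, 40, 40) <- "G"
  expect_true(substr(pat, 31, 31) != "C" && substr(pat, 40, 40) != "G")
  withr::with_seed(9, {
    reads <- c(paste0(random_dna(20), mut, random_dna(20)),
               paste0(random_dna(10), mut, random_dna(30)),
               paste0(random_dna(20), pat, random_dna(20)), # exact: excluded
               vapply(1:5, function(i) random_dna(90), ""))
  })
  tl <- detect_te_like(reads, cat_)
  expect_identical(nrow(tl), 1L)
  expect_identical(tl$support_count, 2L)
  expect_true(tl$te_like && tl$incomplete)
  expect_identical(length(strsplit(tl$profile, ";")[[1]]), 2L)
  expect_identical(nrow(detect_te_like(vapply(1:5, function(i) random_dna(90), ""),
                                       cat_)), 0L)
})

test_that("known footprints are re-identified and new edits get fresh series names", {
  mk_hap <- function(edits) list(edits = edits)
  ins <- function(seq, pos) tibble::tibble(kind = "insertion", ref_position = pos,
                                           length = nchar(seq), sequence = seq)
  c1 <- classify_novel(mk_hap(ins("CCACTAG", loc$insertion_site)), cat_)
  expect_identical(c1$known_match, "StCDF1.2a")
  expect_identical(c1$assigned_name, "StCDF1.2a")
  c2 <- classify_novel(mk_hap(ins("CACTAG", loc$insertion_site)), cat_)
  expect_identical(c2$known_match, "StCDF1.7")
  expect_true(c2$footprint_compatible)
  # a 5-nt insertion away from the canonical site is novel and incompatible
  c3 <- classify_novel(mk_hap(ins("AAGGT", 30L)), cat_)
  expect_identical(c3$known_match, NA_character_)
  expect_identical(c3$assigned_name, "StCDF1.9")
  expect_false(c3$footprint_compatible)
})

test_that("every assemblable catalog allele round-trips through discovery", {
  for (nm in setdiff(names(cat_$alleles), "StCDF1.1")) {
    reads <- rep(assemble_allele_sequence(nm, catalog = cat_), 20)
    h <- call_haplotypes(reads, loc)
    got <- discover_alleles(h, cat_)
    expect_identical(got$known_match, nm)
    if (cat_$alleles[[nm]]$kind %in% c("footprint_insertion", "deletion", "user_defined")) {
      expect_true(got$footprint_compatible, info = nm)
    }
  }
})

test_that("tsd similarity is the Levenshtein distance", {
  expect_identical(tsd_similarity("CCACTAG", "ACACTAG"), 1L)
  expect_identical(tsd_similarity("CACTAG", "ACACTAG"), 1L)
  expect_identical(tsd_similarity("ACACTAG", "ACACTAG"), 0L)
  withr::with_seed(55, {
    for (i in 1:30) {
      a <- random_dna(sample(3:12, 1)); b <- random_dna(sample(3:12, 1))
      expect_identical(tsd_similarity(a, b), oracle_levenshtein(a, b))
    }
  })
})

test_that("all packaged footprint insertions sit at edit distance 1 from the TSD motif", {
  for (nm in c("StCDF1.2a", "StCDF1.2b", "StCDF1.4", "StCDF1.7")) {
    ins <- cat_$alleles[[nm]]$insertion_seq
    expect_identical(tsd_similarity(ins, loc$tsd_motif), 1L, info = nm)
  }
})
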