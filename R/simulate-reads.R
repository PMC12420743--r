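# Seeded read simulator emulating the two sequencing designs of the bolter
# assay: ~150-nt targeted probe-capture reads and full-length long-amplicon
# reads of the variable region, with per-allele PCR amplification bias and
# substitution errors.

#' Genotype of one cell lineage
#'
#' @param dosages Named integer vector: allele name -> copy number; must sum
#'   to the catalog ploidy when validated against a catalog.
#' @return Named integer vector of class `genotype_spec`.
#' @examples
#' genotype_spec(c(StCDF1.1 = 2, StCDF1.3 = 2))
#' @export
genotype_spec <- function(dosages) {
  if (is.null(names(dosages)) || any(!nzchar(names(dosages)))) {
    abort("dosages must be a named vector")
  }
  d <- as.integer(dosages)
  if (any(d < 0)) abort("dosages must be non-negative")
  structure(setNames(d, names(dosages)), class = "genotype_spec")
}

#' Mixture of cell lineages within one sampled tissue
#'
#' A uniform sample has one component; a mosaic (periclinal chimera) stem is
#' a mixture of two or more genotypes with the given cell fractions.
#'
#' @param genotypes List of [genotype_spec()] (or named dosage vectors).
#' @param fractions Numeric cell fractions, summing to 1.
#' @return Object of class `cell_population`.
#' @export
cell_population <- function(genotypes, fractions = 1) {
  if (inherits(genotypes, "genotype_spec") || (is.numeric(genotypes) && !is.list(genotypes))) {
    genotypes <- list(genotypes)
  }
  genotypes <- lapply(genotypes, genotype_spec)
  if (length(fractions) != length(genotypes)) {
    abort("fractions and genotypes must have the same length")
  }
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9) {
    abort("fractions must be positive and sum to 1")
  }
  structure(list(genotypes = genotypes, fractions = as.numeric(fractions)),
            class = "cell_population")
}

#' Read-simulation configuration
#'
#' @param platform `"long_amplicon"` emits the full assembled allele
#'   sequence per read; `"targeted_short"` samples `read_length`-nt windows
#'   over the variable region (probe capture emulation).
#' @param read_length Read length in nt for the targeted design.
#' @param n_reads Reads per sample (the assay yields ~5,000).
#' @param error_rate Per-base substitution probability (< 0.2). Substitutions
#'   only: the downstream classifier is exact-match, so indel errors are kept
#'   out of the default model.
#' @param amplification_bias Optional named positive weights multiplying each
#'   allele's template probability (PCR efficiency); default all 1.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return Object of class `read_sim_config`.
#' @export
read_sim_config <- function(platform = c("long_amplicon", "targeted_short"),
                            read_length = 150L, n_reads = 5000L,
                            error_rate = 0, amplification_bias = NULL,
                            seed = 1L) {
  platform <- match.arg(platform)
  if (n_reads <= 0) abort("n_reads must be positive")
  if (error_rate < 0 || error_rate >= 0.2) abort("error_rate must be in [0, 0.2)")
  if (!is.null(amplification_bias)) {
    if (is.null(names(amplification_bias)) || any(amplification_bias <= 0)) {
      abort("amplification_bias must be a named vector of positive weights")
    }
  }
  structure(
    list(platform = platform, read_length = as.integer(read_length),
         n_reads = as.integer(n_reads), error_rate = error_rate,
         amplification_bias = amplification_bias, seed = as.integer(seed)),
    class = "read_sim_config"
  )
}

#' PCR-bias preset for the long-amplicon design
#'
#' Short alleles amplify more efficiently than the transposon-bearing long
#' allele; the assay shows roughly an eightfold depth skew against the long
#' allele. This preset gives every short allele weight `short_weight` and the
#' transposon allele weight `te_weight`.
#'
#' @param catalog An [allele_catalog()].
#' @param short_weight,te_weight Positive weights.
#' @return Named numeric weight vector.
#' @export
pcr_bias_preset <- function(catalog, short_weight = 8, te_weight = 1) {
  w <- setNames(rep(short_weight, length(catalog$alleles)), names(catalog$alleles))
  te <- te_allele_name(catalog)
  if (!is.na(te)) w[te] <- te_weight
  w
}

# Vectorized substitution errors on a character vector of reads (grouped by
# length internally); exact per-base rate, errors never reproduce the
# original base.
apply_substitution_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  bases_raw <- charToRaw("ACGT")
  lens <- nchar(reads)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    n <- length(idx)
    m <- matrix(unlist(lapply(reads[idx], charToRaw), use.names = FALSE),
                nrow = L, ncol = n)
    k <- rbinom(1L, L * n, error_rate)
    if (k > 0) {
      pos <- sample.int(L * n, k)
      orig <- match(m[pos], bases_raw)
      shift <- sample.int(3L, k, replace = TRUE)
      m[pos] <- bases_raw[(orig + shift - 1L) %% 4L + 1L]
    }
    big <- rawToChar(as.vector(m))
    reads[idx] <- substring(big, (seq_len(n) - 1L) * L + 1L, seq_len(n) * L)
  }
  reads
}

#' Simulate sequencing reads for one sample with known truth
#'
#' Each read is drawn by (i) choosing a cell-population component by its
#' fraction, (ii) choosing a template allele with probability proportional to
#' dosage times amplification bias, (iii) taking the full assembled sequence
#' (long amplicon) or a uniformly placed window over the variable region
#' (targeted short), (iv) applying substitution errors, and (v) flipping
#' strand with probability 0.5. The returned table doubles as the truth
#' table: one row per emitted read with its source component and allele.
#'
#' @param population A [cell_population()] (or a bare named dosage vector for
#'   a uniform sample).
#' @param catalog An [allele_catalog()].
#' @param config A [read_sim_config()].
#' @param sample_id Sample label stored with the reads.
#' @return A tibble with columns `read_id`, `sample_id`, `component`,
#'   `allele` (truth), `strand`, `sequence`; the seed is attached as
#'   attribute `seed`.
#' @examples
#' reads <- simulate_reads(c(StCDF1.1 = 2, StCDF1.3 = 2), stcdf1_catalog(),
#'                         read_sim_config(n_reads = 100, seed = 7))
#' table(reads$allele)
#' @export
simulate_reads <- function(population, catalog, config = read_sim_config(),
                           sample_id = "sample1") {
  if (!inherits(population, "cell_population")) {
    population <- cell_population(population)
  }
  stopifnot(inherits(catalog, "allele_catalog"), inherits(config, "read_sim_config"))
  all_alleles <- unique(unlist(lapply(population$genotypes, names)))
  unknown <- setdiff(all_alleles, names(catalog$alleles))
  if (length(unknown)) {
    abort(sprintf("genotype references unknown allele(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  for (g in population$genotypes) {
    if (sum(g) != catalog$ploidy) {
      abort(sprintf("each genotype must sum to the catalog ploidy (%d)", catalog$ploidy))
    }
  }
  templates <- allele_sequences(catalog)
  bias <- config$amplification_bias %||% setNames(rep(1, length(templates)), names(templates))
  withr::with_seed(config$seed, {
    n <- config$n_reads
    comp <- sample.int(length(population$genotypes), n, replace = TRUE,
                       prob = population$fractions)
    allele <- character(n)
    for (ci in seq_along(population$genotypes)) {
      g <- population$genotypes[[ci]]
      g <- g[g > 0]
      w <- as.numeric(g) * bias[names(g)]
      if (anyNA(w)) abort("amplification_bias is missing weights for some genotype alleles")
      take <- which(comp == ci)
      allele[take] <- sample(names(g), length(take), replace = TRUE, prob = w)
    }
    seqs <- character(n)
    for (a in unique(allele)) {
      idx <- which(allele == a)
      tmpl <- templates[[a]]
      if (config$platform == "long_amplicon") {
        seqs[idx] <- tmpl
      } else {
        L <- nchar(tmpl)
        if (L <= config$read_length) {
          seqs[idx] <- tmpl
        } else {
          starts <- sample.int(L - config$read_length + 1L, length(idx), replace = TRUE)
          seqs[idx] <- substring(tmpl, starts, starts + config$read_length - 1L)
        }
      }
    }
    seqs <- apply_substitution_errors(seqs, config$error_rate)
    flip <- runif(n) < 0.5
    if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
    out <- tibble(
      read_id = sprintf("%s_read%05d", sample_id, seq_len(n)),
      sample_id = sample_id,
      component = comp,
      allele = allele,
      strand = ifelse(flip, "-", "+"),
      sequence = seqs
    )
    attr(out, "seed") <- config$seed
    attr(out, "platform") <- config$platform
    out
  })
}

#' Write simulated reads as FASTQ and their truth table as TSV
#'
#' FASTQ qualities are constant Q30 (Sanger/Phred+33). Both writers prepend a
#' `#`-comment header with the seed (TSV) so runs are traceable.
#'
#' @param reads Output of [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$sequence), function(L) strrep("?", L), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual), con)
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_truth_table <- function(reads, path) {
  con <- file(path, "w")
  writeLines(sprintf("# bolterseq truth table; seed=%s",
                     attr(reads, "seed") %||% "NA"), con)
  close(con)
  readr::write_tsv(reads[c("read_id", "sample_id", "component", "allele", "strand")],
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}
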