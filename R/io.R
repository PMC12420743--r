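# Readers and writers for the pipeline's plain-text formats, plus the
# end-to-end demo pipeline runner.

#' Read sequences from FASTA or FASTQ
#'
#' Format is chosen by extension (`.fq`/`.fastq` vs anything else) unless
#' given. Lowercase sequence is uppercased with a warning; malformed FASTQ
#' records raise an error naming the offending line.
#'
#' @param path Input file.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return Tibble with `read_id` and `sequence`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  if (format == "fastq") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    if (length(lines) %% 4L != 0L) {
      abort(sprintf("truncated FASTQ: %d lines (not a multiple of 4) near line %d",
                    length(lines), length(lines)))
    }
    ids <- lines[seq(1L, length(lines), 4L)]
    seqs <- lines[seq(2L, length(lines), 4L)]
    plus <- lines[seq(3L, length(lines), 4L)]
    bad_id <- which(!startsWith(ids, "@"))
    if (length(bad_id)) {
      abort(sprintf("malformed FASTQ header at line %d", (bad_id[1] - 1L) * 4L + 1L))
    }
    bad_plus <- which(!startsWith(plus, "+"))
    if (length(bad_plus)) {
      abort(sprintf("malformed FASTQ separator at line %d", (bad_plus[1] - 1L) * 4L + 3L))
    }
    ids <- sub("\\s.*$", "", substring(ids, 2L))
  } else {
    raw <- readLines(path)
    if (any(grepl("[a-z]", raw[!startsWith(raw, ">")]))) {
      warn("lowercase bases found; uppercasing")
    }
    set <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(set))
    seqs <- as.character(set)
  }
  if (any(grepl("[a-z]", seqs))) {
    warn("lowercase bases found; uppercasing")
    seqs <- toupper(seqs)
  }
  tibble(read_id = ids, sequence = unname(seqs))
}

#' Write a FASTA file from sequences
#'
#' @param seqs Named character vector, or a data frame with `read_id` and
#'   `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$read_id)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write a stage report as TSV with a comment header
#'
#' List columns are collapsed to semicolon-separated strings. The header records
#' the package version and any parameters given.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param params Named list echoed into the `#` header.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, params = list()) {
  df <- as_tibble(df)
  for (cl in names(df)) {
    if (is.list(df[[cl]])) {
      df[[cl]] <- vapply(df[[cl]], function(x) paste(unlist(x), collapse = ";"), "")
    }
  }
  hdr <- sprintf("# bolterseq %s%s",
                 as.character(utils::packageVersion("bolterseq")),
                 if (length(params)) paste0("; ", paste(names(params), unlist(params),
                                                        sep = "=", collapse = "; "))
                 else "")
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV/CSV table written by the pipeline
#'
#' Skips `#` comment lines.
#'
#' @param path Input path.
#' @return Tibble.
#' @export
read_allele_calls <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' @rdname read_allele_calls
#' @export
read_phenotypes <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Configure the demo pipeline
#'
#' Thresholds mirror the analysis defaults: 5% allele-frequency filter,
#' 3-read haplotype floor, 30% transposon-reduction threshold, admixture
#' floor of 5 mismatches.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; every stage derives its own stream from it.
#' @param varieties Variety names for the simulated cohort.
#' @param n_bolters Bolters per variety.
#' @param n_loci Panel size for the multilocus table.
#' @param n_reads Reads per sample.
#' @param error_rate Per-base substitution error.
#' @param min_frac,min_reads,reduction_threshold,admixture_floor Stage
#'   thresholds.
#' @param simulate Include the simulation stage (the demo always does).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            varieties = c("Agata", "Nicola"),
                            n_bolters = 2L, n_loci = 790L, n_reads = 2000L,
                            error_rate = 0.005, min_frac = 0.05,
                            min_reads = 3L, reduction_threshold = 0.3,
                            admixture_floor = 5, simulate = TRUE) {
  stopifnot(min_frac >= 0, min_frac <= 1, min_reads >= 1,
            reduction_threshold > 0, reduction_threshold < 1)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), varieties = varieties,
         n_bolters = as.integer(n_bolters), n_loci = as.integer(n_loci),
         n_reads = as.integer(n_reads), error_rate = error_rate,
         min_frac = min_frac, min_reads = as.integer(min_reads),
         reduction_threshold = reduction_threshold,
         admixture_floor = admixture_floor, simulate = simulate),
    class = "pipeline_config")
}

#' Run the end-to-end demo pipeline
#'
#' Simulates a cohort (per variety: one control, `n_bolters` excision
#' bolters, one contaminant, plus one two-stem mosaic plant in the first
#' variety), then runs allele typing, bolter comparison, footprint
#' discovery, consequence prediction and clonal-identity analysis, writing
#' one TSV per stage (plus FASTQ, FASTA and Newick side outputs) into
#' `config$out_dir`. All randomness derives from `config$seed`, so two runs
#' with the same config are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param catalog An [allele_catalog()]; default the packaged one.
#' @return A `run_report` list: per-stage record counts, read accounting,
#'   the config echo, and paths of all outputs.
#' @export
run_pipeline <- function(config, catalog = stcdf1_catalog()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  written <- character()
  on.exit(if (!ok) unlink(written), add = TRUE)
  emit <- function(df, name, params = list()) {
    p <- file.path(config$out_dir, name)
    write_report_tsv(df, p, params)
    written <<- c(written, p)
    p
  }
  seeds <- derive_seeds(config$seed, 6L)
  vs <- config$varieties
  fps <- c("StCDF1.2a", "StCDF1.2b")
  te <- te_allele_name(catalog)

  # -- simulate cohort ------------------------------------------------------
  clones <- bind_rows(lapply(vs, function(v) {
    tibble(clone_id = c(paste0(v, "-C1"),
                        paste0(v, "-B", seq_len(config$n_bolters)),
                        paste0(v, "-X1")),
           variety = v,
           role = c("control", rep("bolter", config$n_bolters), "contaminant"))
  }))
  calls <- simulate_multilocus_calls(clones, n_loci = config$n_loci,
                                     seed = seeds[[1]])
  geno_control <- c(StCDF1.1 = 2, StCDF1.3 = 2)
  sample_plan <- clones
  sample_plan$genotype <- lapply(seq_len(nrow(clones)), function(i) {
    role <- clones$role[[i]]
    if (role %in% c("control", "contaminant")) {
      cell_population(geno_control)
    } else {
      fp <- fps[[(i %% length(fps)) + 1L]]
      g <- setNames(c(2, 1, 1), c("StCDF1.1", te, fp))
      cell_population(g)
    }
  })
  # two-stem mosaic plant in the first variety
  mosaic_id <- paste0(vs[[1]], "-M1")
  stem_plan <- tibble(
    sample = paste0(mosaic_id, c("-stemA", "-stemB")),
    population = list(
      cell_population(geno_control),
      cell_population(list(geno_control,
                           setNames(c(2, 1, 1), c("StCDF1.1", te, "StCDF1.2a"))),
                      fractions = c(0.5, 0.5)))
  )
  read_seeds <- derive_seeds(seeds[[2]], nrow(sample_plan) + nrow(stem_plan))
  sim_one <- function(pop, id, sd) {
    simulate_reads(pop, catalog,
                   read_sim_config(n_reads = config$n_reads,
                                   error_rate = config$error_rate,
                                   seed = sd),
                   sample_id = id)
  }
  reads <- c(
    lapply(seq_len(nrow(sample_plan)), function(i) {
      sim_one(sample_plan$genotype[[i]], sample_plan$clone_id[[i]], read_seeds[[i]])
    }),
    lapply(seq_len(nrow(stem_plan)), function(i) {
      sim_one(stem_plan$population[[i]], stem_plan$sample[[i]],
              read_seeds[[nrow(sample_plan) + i]])
    }))
  names(reads) <- c(sample_plan$clone_id, stem_plan$sample)
  phenos <- simulate_phenotypes(seed = seeds[[3]])
  emit(calls, "multilocus_calls.tsv", list(seed = seeds[[1]]))
  p_pheno <- file.path(config$out_dir, "phenotypes.csv")
  readr::write_csv(phenos, p_pheno)
  written <- c(written, p_pheno)
  p_fq <- file.path(config$out_dir, "reads_demo.fastq")
  write_fastq(bind_rows(reads[1]), p_fq)
  written <- c(written, p_fq)

  # -- allele typing --------------------------------------------------------
  freqs <- lapply(names(reads), function(id) {
    estimate_frequencies(count_alleles(reads[[id]], catalog, sample_id = id),
                         min_frac = config$min_frac)
  })
  names(freqs) <- names(reads)
  freq_tbl <- bind_rows(freqs)
  emit(freq_tbl, "allele_frequencies.tsv",
       list(min_frac = config$min_frac))
  genos <- bind_rows(lapply(freqs, function(f) infer_dosage(f, catalog$ploidy)))
  emit(genos, "genotype_calls.tsv")
  n_unclassified <- sum(vapply(names(reads), function(id) {
    attr(count_alleles(reads[[id]], catalog, sample_id = id), "n_unclassified")
  }, 0L))

  # -- bolter evidence ------------------------------------------------------
  evidence <- bind_rows(lapply(seq_len(nrow(sample_plan)), function(i) {
    if (sample_plan$role[[i]] == "control") return(NULL)
    ctrl <- freqs[[paste0(sample_plan$variety[[i]], "-C1")]]
    compare_samples(ctrl, freqs[[sample_plan$clone_id[[i]]]], catalog,
                    reduction_threshold = config$reduction_threshold)
  }))
  emit(evidence, "bolter_evidence.tsv",
       list(reduction_threshold = config$reduction_threshold))

  # -- footprint discovery (first bolter, subsampled) -----------------------
  b1 <- sample_plan$clone_id[sample_plan$role == "bolter"][1]
  sub <- head(reads[[b1]][nchar(reads[[b1]]$sequence) <
                            nchar(te_sequence(catalog$te)), ], 300L)
  haps <- call_haplotypes(sub, catalog$locus, min_frac = config$min_frac,
                          min_reads = config$min_reads)
  disc <- discover_alleles(haps, catalog)
  emit(disc[setdiff(names(disc), "sequence")], "footprint_discovery.tsv",
       list(min_frac = config$min_frac, min_reads = config$min_reads,
            sample = b1, n_reads_used = nrow(sub)))

  # -- consequence prediction ----------------------------------------------
  cons <- predict_consequences(catalog)
  emit(cons[setdiff(names(cons), "protein")], "consequences.tsv")
  p_prot <- file.path(config$out_dir, "proteins.fasta")
  write_protein_fasta(cons, p_prot)
  written <- c(written, p_prot)

  # -- clonal identity ------------------------------------------------------
  m <- mismatch_matrix(calls)
  emit(tidy(m), "mismatch_matrix.tsv")
  hc <- cluster_complete_linkage(m)
  p_nwk <- file.path(config$out_dir, "dendrogram.nwk")
  write_dendrogram_newick(hc, p_nwk)
  written <- c(written, p_nwk)
  adm <- flag_admixture(m, clones |> dplyr::rename(sample = "clone_id"),
                        floor = config$admixture_floor)
  emit(adm, "admixture_report.tsv", list(floor = config$admixture_floor))
  mos <- detect_mosaic(freqs[stem_plan$sample], catalog)
  mos$plant <- mosaic_id
  emit(mos, "mosaic_report.tsv")
  pcomp <- compare_phenotypes(phenos)
  emit(pcomp, "phenotype_tests.tsv")

  ok <- TRUE
  report <- list(
    seed = config$seed,
    config = unclass(config),
    n_samples = length(reads),
    n_reads_total = sum(vapply(reads, nrow, 0L)),
    n_reads_unclassified = n_unclassified,
    n_bolters_called = sum(evidence$verdict == "bolter"),
    n_admixture_flagged = sum(adm$flag == "admixture"),
    mosaic_verdict = mos$verdict,
    outputs = written
  )
  class(report) <- "run_report"
  p_rep <- file.path(config$out_dir, "run_report.json")
  jsonlite::write_json(report, p_rep, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d: %d samples, %d reads (%d unclassified), %d bolters called, %d admixture flags, mosaic: %s\n",
              x$seed, x$n_samples, x$n_reads_total, x$n_reads_unclassified,
              x$n_bolters_called, x$n_admixture_flagged, x$mosaic_verdict))
  invisible(x)
}
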