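# Allele typing: exact junction-pattern read classification, per-sample
# counting, the 5% frequency filter, bias-aware tetraploid dosage inference,
# and control-vs-candidate comparison.

# Hit matrix (reads x alleles) of exact pattern matches on either strand.
# A transposon read matching one or both junction patterns scores one hit.
pattern_hits <- function(seqs, catalog) {
  set <- Biostrings::DNAStringSet(seqs)
  rset <- Biostrings::reverseComplement(set)
  nms <- names(catalog$alleles)
  hits <- matrix(FALSE, length(seqs), length(nms), dimnames = list(NULL, nms))
  strand_fwd <- matrix(FALSE, length(seqs), length(nms), dimnames = list(NULL, nms))
  pat_index <- matrix(NA_integer_, length(seqs), length(nms), dimnames = list(NULL, nms))
  for (a in nms) {
    pats <- catalog$patterns[[a]]
    for (pi in seq_along(pats)) {
      fwd <- Biostrings::vcountPattern(pats[[pi]], set) > 0L
      rev <- Biostrings::vcountPattern(pats[[pi]], rset) > 0L
      new <- (fwd | rev) & !hits[, a]
      pat_index[new, a] <- pi
      strand_fwd[, a] <- strand_fwd[, a] | fwd
      hits[, a] <- hits[, a] | fwd | rev
    }
  }
  list(hits = hits, strand_fwd = strand_fwd, pat_index = pat_index)
}

#' Classify reads into catalog alleles by exact junction patterns
#'
#' Every catalog pattern is searched as an exact substring of the read and
#' of its reverse complement. A read matching one or both junction patterns
#' of the transposon allele is assigned that allele once. A read matching
#' patterns of two distinct alleles is `ambiguous` (cannot occur for the
#' packaged catalog, whose patterns are mutually non-contained); a read with
#' no match is `unclassified`.
#'
#' @param reads A data frame with a `sequence` column (e.g. from
#'   [simulate_reads()] or [read_sequences()]), or a character vector.
#' @param catalog An [allele_catalog()].
#' @return The input as a tibble with added columns `allele` (name or `NA`),
#'   `status` (`classified` / `unclassified` / `ambiguous`),
#'   `matched_pattern_index` and `match_strand` (`+`/`-`).
#' @examples
#' cat <- stcdf1_catalog()
#' classify_reads(allele_sequences(cat)["StCDF1.2a"], cat)$allele
#' @export
classify_reads <- function(reads, catalog) {
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read%05d", seq_along(reads)),
                    sequence = unname(reads))
  }
  reads <- as_tibble(reads)
  if (!"sequence" %in% names(reads)) abort("reads must have a `sequence` column")
  seqs <- check_dna(reads$sequence, "read sequence")
  ph <- pattern_hits(seqs, catalog)
  nhit <- rowSums(ph$hits)
  allele <- rep(NA_character_, length(seqs))
  one <- nhit == 1L
  allele[one] <- colnames(ph$hits)[apply(ph$hits[one, , drop = FALSE], 1, which)]
  status <- dplyr::case_when(nhit == 1L ~ "classified",
                             nhit == 0L ~ "unclassified",
                             TRUE ~ "ambiguous")
  mpi <- rep(NA_integer_, length(seqs))
  strand <- rep(NA_character_, length(seqs))
  ai <- match(allele, colnames(ph$hits))
  ok <- which(!is.na(ai))
  mpi[ok] <- ph$pat_index[cbind(ok, ai[ok])]
  strand[ok] <- ifelse(ph$strand_fwd[cbind(ok, ai[ok])], "+", "-")
  reads$allele <- allele
  reads$status <- status
  reads$matched_pattern_index <- mpi
  reads$match_strand <- strand
  reads
}

#' Classify a single read
#'
#' @param seq A single DNA string.
#' @inheritParams classify_reads
#' @return One-row tibble as in [classify_reads()].
#' @export
classify_read <- function(seq, catalog) {
  if (length(seq) != 1L) abort("classify_read takes a single sequence")
  classify_reads(seq, catalog)
}

#' Count classified reads per allele
#'
#' @inheritParams classify_reads
#' @param sample_id Sample label for the output.
#' @return An `allele_counts` tibble with columns `sample_id`, `allele`,
#'   `count` (one row per catalog allele) and attributes `n_total_reads` and
#'   `n_unclassified` (ambiguous reads count as unclassified). Conservation:
#'   `sum(count) + n_unclassified == n_total_reads`.
#' @export
count_alleles <- function(reads, catalog, sample_id = NULL) {
  cl <- classify_reads(reads, catalog)
  sample_id <- sample_id %||% (if ("sample_id" %in% names(cl)) cl$sample_id[1] else "sample1")
  counts <- table(factor(cl$allele, levels = names(catalog$alleles)))
  out <- tibble(sample_id = sample_id,
                allele = names(catalog$alleles),
                count = as.integer(counts))
  attr(out, "n_total_reads") <- nrow(cl)
  attr(out, "n_unclassified") <- sum(cl$status != "classified")
  class(out) <- c("allele_counts", class(out))
  out
}

#' @export
glance.allele_counts <- function(x, ...) {
  tibble(sample_id = x$sample_id[1],
         n_total_reads = attr(x, "n_total_reads"),
         n_classified = sum(x$count),
         n_unclassified = attr(x, "n_unclassified"))
}

#' Allele frequencies with the minimum-frequency filter
#'
#' Frequencies are computed over classified reads only (unclassified reads
#' are reported separately by [count_alleles()]). An allele is retained when
#' its frequency is at least `min_frac`: read groups *below* 5% are
#' excluded, so exactly 5% is retained.
#'
#' @param counts An `allele_counts` table from [count_alleles()], or any
#'   data frame with `sample_id`, `allele`, `count`.
#' @param min_frac Minimum retained frequency (default 0.05).
#' @return A `frequency_table` tibble with columns `sample_id`, `allele`,
#'   `count`, `freq`, `retained`.
#' @export
estimate_frequencies <- function(counts, min_frac = 0.05) {
  counts <- as_tibble(counts)
  total <- sum(counts$count)
  if (total == 0L) {
    abort("no classified reads: frequencies are undefined",
          class = "bolterseq_error_no_classified_reads")
  }
  out <- counts |>
    mutate(freq = .data$count / total,
           retained = .data$freq >= min_frac)
  attr(out, "min_frac") <- min_frac
  class(out) <- c("frequency_table", setdiff(class(out), "allele_counts"))
  out
}

#' Retained allele names of a frequency table
#'
#' @param freqs A `frequency_table`.
#' @return Character vector of retained allele names.
#' @export
retained_alleles <- function(freqs) {
  freqs$allele[freqs$retained]
}

# All dosage vectors over k alleles summing to `ploidy` with every part >= 1.
dosage_vectors <- function(k, ploidy) {
  if (k == 1L) return(matrix(ploidy, 1L, 1L))
  grid <- as.matrix(expand.grid(rep(list(seq_len(ploidy)), k)))
  grid[rowSums(grid) == ploidy, , drop = FALSE]
}

#' Infer integer allele dosage from retained read counts
#'
#' Maximizes the multinomial log-likelihood of the retained allele counts
#' over all integer dosage vectors summing to `ploidy`, with the expected
#' frequency of allele *a* proportional to `dosage(a) * bias(a)`. The
#' enumeration is exhaustive (tiny at ploidy 4). Ties are broken toward the
#' most balanced vector, then by lexicographic allele order (earlier-named
#' alleles take the smaller dosage).
#'
#' @param freqs A `frequency_table` from [estimate_frequencies()].
#' @param ploidy Total copy number (default 4).
#' @param bias Optional named positive weights (PCR amplification
#'   efficiency); default all 1.
#' @return A `genotype_call` tibble with columns `sample_id`, `allele`,
#'   `dosage` over retained alleles, and attributes `log_likelihood`,
#'   `ploidy` and `bias_used`.
#' @examples
#' cnt <- tibble::tibble(sample_id = "s", allele = c("StCDF1.1", "StCDF1.3"),
#'                       count = c(2500L, 2500L))
#' infer_dosage(estimate_frequencies(cnt))
#' @export
infer_dosage <- function(freqs, ploidy = 4L, bias = NULL) {
  keep <- freqs[freqs$retained, , drop = FALSE]
  keep <- keep[order(keep$allele), , drop = FALSE]
  k <- nrow(keep)
  if (k < 1L) abort("no retained alleles")
  if (k > ploidy) abort("more retained alleles than ploidy")
  b <- if (is.null(bias)) rep(1, k) else {
    bb <- bias[keep$allele]
    if (anyNA(bb)) abort("bias is missing weights for some retained alleles")
    as.numeric(bb)
  }
  cand <- dosage_vectors(k, as.integer(ploidy))
  ll <- apply(cand, 1, function(d) {
    p <- d * b
    dmultinom(keep$count, prob = p / sum(p), log = TRUE)
  })
  balance <- apply(cand, 1, function(d) max(d) - min(d))
  lex <- apply(cand, 1, paste, collapse = " ")
  best <- order(-ll, balance, lex)[1]
  out <- tibble(sample_id = keep$sample_id, allele = keep$allele,
                dosage = as.integer(cand[best, ]))
  attr(out, "log_likelihood") <- ll[[best]]
  attr(out, "ploidy") <- as.integer(ploidy)
  attr(out, "bias_used") <- setNames(b, keep$allele)
  class(out) <- c("genotype_call", class(out))
  out
}

#' @export
glance.genotype_call <- function(x, ...) {
  tibble(sample_id = x$sample_id[1],
         ploidy = attr(x, "ploidy"),
         n_alleles = nrow(x),
         log_likelihood = attr(x, "log_likelihood"))
}

#' Compare a candidate sample against its variety control
#'
#' Detects the excision signature: new retained alleles absent from the
#' control, and loss or reduction of the transposon allele. The verdict is
#' `bolter` when either signal is present, `true_to_type` when retained
#' allele sets and frequencies agree within `freq_tol`, else `inconclusive`.
#' A control lacking the transposon allele cannot produce excision bolters;
#' the verdict is then `inconclusive` with a warning.
#'
#' @param control,candidate `frequency_table`s from the same catalog.
#' @param catalog The [allele_catalog()] used for typing.
#' @param reduction_threshold Minimum relative drop in transposon-allele
#'   frequency called a reduction (default 0.3).
#' @param freq_tol Per-allele frequency tolerance for `true_to_type`.
#' @return One-row tibble: `te_allele`, `te_freq_control`,
#'   `te_freq_candidate`, `te_allele_change` (`absent`/`reduced`/
#'   `unchanged`), `new_alleles` (list column), `verdict`.
#' @export
compare_samples <- function(control, candidate, catalog,
                            reduction_threshold = 0.3, freq_tol = 0.1) {
  te <- te_allele_name(catalog)
  ctrl_set <- retained_alleles(control)
  cand_set <- retained_alleles(candidate)
  new_alleles <- setdiff(cand_set, ctrl_set)
  freq_of <- function(tbl, a) {
    f <- tbl$freq[tbl$allele == a]
    if (length(f)) f[[1]] else 0
  }
  te_ctrl <- if (!is.na(te)) freq_of(control, te) else NA_real_
  te_cand <- if (!is.na(te)) freq_of(candidate, te) else NA_real_
  te_in_ctrl <- !is.na(te) && te %in% ctrl_set
  if (!te_in_ctrl) {
    warn("control does not retain the transposon allele: variety cannot produce excision bolters")
    change <- "unchanged"
    verdict <- "inconclusive"
  } else {
    change <- if (te_cand == 0) "absent"
      else if ((te_ctrl - te_cand) / te_ctrl >= reduction_threshold) "reduced"
      else "unchanged"
    shared <- union(ctrl_set, cand_set)
    agree <- setequal(ctrl_set, cand_set) &&
      all(vapply(shared, function(a) abs(freq_of(control, a) - freq_of(candidate, a)), 0) <= freq_tol)
    verdict <- if (length(new_alleles) > 0 || change %in% c("absent", "reduced")) "bolter"
      else if (agree) "true_to_type"
      else "inconclusive"
  }
  tibble(
    control_id = control$sample_id[1],
    candidate_id = candidate$sample_id[1],
    te_allele = te,
    te_freq_control = te_ctrl,
    te_freq_candidate = te_cand,
    te_allele_change = change,
    new_alleles = list(new_alleles),
    verdict = verdict
  )
}

#' Wide sample-by-allele frequency matrix
#'
#' Heatmap-ready relative frequencies, one row per sample and one column per
#' allele.
#'
#' @param freqs One or more `frequency_table`s row-bound together.
#' @return A tibble with `sample_id` and one column per allele.
#' @export
frequency_matrix <- function(freqs) {
  as_tibble(freqs) |>
    select("sample_id", "allele", "freq") |>
    tidyr::pivot_wider(names_from = "allele", values_from = "freq",
                       values_fill = 0)
}
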