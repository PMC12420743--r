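# Clonal identity: genome-wide allelic mismatch matrix, complete-linkage
# clustering, admixture flagging, per-stem mosaic detection and the
# phenotype group comparison.

# Long form (sample, locus, allele, copies) from a wide allele-call table.
calls_long <- function(calls) {
  calls <- as_tibble(calls)
  acols <- grep("^allele_", names(calls), value = TRUE)
  if (!length(acols)) abort("allele-call table needs allele_1.. columns")
  long <- tidyr::pivot_longer(calls, dplyr::all_of(acols),
                              names_to = NULL, values_to = "allele")
  long[!is.na(long$allele) & nzchar(long$allele), c("sample", "locus", "allele")]
}

#' Genome-wide allelic mismatch matrix
#'
#' For every pair of samples, the distance is the sum over loci (present in
#' both) of the size of the multiset symmetric difference of their allele
#' calls -- the number of allele copies that differ. The multiset symmetric
#' difference is a metric, so the matrix is symmetric with zero diagonal and
#' satisfies the triangle inequality. Loci missing in either sample are
#' skipped; pairs compared on fewer than `min_shared_frac` of all loci are
#' marked low-confidence.
#'
#' @param calls Wide allele-call table: columns `sample`, `locus`,
#'   `allele_1` .. (NA = no call), as from [simulate_multilocus_calls()] or
#'   [read_allele_calls()].
#' @param mode `"multiset"` counts allele copies; `"set"` collapses each
#'   call to its distinct alleles first.
#' @param min_shared_frac Minimum fraction of loci a pair must share.
#' @return A `mismatch_matrix` object: the integer distance matrix with
#'   attributes `loci_used` (pairwise matrix) and `low_confidence` (logical
#'   matrix).
#' @export
mismatch_matrix <- function(calls, mode = c("multiset", "set"),
                            min_shared_frac = 0.5) {
  mode <- match.arg(mode)
  all_samples <- unique(as_tibble(calls)$sample)
  if (length(all_samples) < 2L) abort("need at least 2 samples")
  long <- calls_long(calls)
  if (mode == "set") long <- dplyr::distinct(long)
  samples <- unique(long$sample)
  if (length(samples) < length(all_samples)) {
    abort("sample with all loci missing")
  }
  loci <- unique(long$locus)
  # counts: samples x (locus:allele) key
  long$key <- paste(long$locus, long$allele, sep = "\r")
  keys <- unique(long$key)
  cnt <- matrix(0L, length(samples), length(keys),
                dimnames = list(samples, keys))
  tab <- table(long$sample, long$key)
  cnt[rownames(tab), colnames(tab)] <- as.integer(tab)
  key_locus <- sub("\r.*$", "", keys)
  # presence: sample x locus has any call
  pres <- matrix(FALSE, length(samples), length(loci),
                 dimnames = list(samples, loci))
  pl <- unique(long[c("sample", "locus")])
  pres[cbind(match(pl$sample, samples), match(pl$locus, loci))] <- TRUE
  if (any(rowSums(pres) == 0L)) abort("sample with all loci missing")
  n <- length(samples)
  d <- matrix(0L, n, n, dimnames = list(samples, samples))
  used <- matrix(length(loci), n, n, dimnames = list(samples, samples))
  locus_of_key <- match(key_locus, loci)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- pres[i, ] & pres[j, ]
      keep <- both[locus_of_key]
      d[i, j] <- d[j, i] <- sum(abs(cnt[i, keep] - cnt[j, keep]))
      used[i, j] <- used[j, i] <- sum(both)
    }
  }
  structure(d,
            loci_used = used,
            low_confidence = used < min_shared_frac * length(loci),
            class = c("mismatch_matrix", "matrix", "array"))
}

#' @export
print.mismatch_matrix <- function(x, ...) {
  cat(sprintf("<mismatch_matrix> %d samples\n", nrow(x)))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' @rdname mismatch_matrix
#' @param x A `mismatch_matrix`.
#' @param ... Unused.
#' @export
tidy.mismatch_matrix <- function(x, ...) {
  m <- unclass(x)
  as_tibble(as.table(m), .name_repair = ~ c("sample_a", "sample_b", "mismatches")) |>
    mutate(loci_used = as.integer(as.table(attr(x, "loci_used"))))
}

#' Complete-linkage clustering of a mismatch matrix
#'
#' Agglomerative clustering with complete linkage on the allelic mismatch
#' distances, as used to group candidate bolters with their varieties.
#'
#' @param m A `mismatch_matrix` (or any symmetric distance matrix).
#' @return An [stats::hclust] tree.
#' @export
cluster_complete_linkage <- function(m) {
  hclust(as.dist(unclass(m)), method = "complete")
}

#' Export a dendrogram as Newick
#'
#' @param hc An [stats::hclust] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Flag admixed samples by distance to their variety controls
#'
#' A sample is admixture when its distance to every control of its labeled
#' variety exceeds the cutoff; the cutoff is the larger of the observed
#' within-variety control-control distance and an absolute floor. Flagged
#' samples should be excluded from downstream bolter analysis. Samples of a
#' variety without any control are `unevaluable`; a variety's only control
#' is `isogenic` by definition (it is the reference).
#'
#' @param m A `mismatch_matrix`.
#' @param labels Data frame with columns `sample`, `variety`, `role`
#'   (`"control"` marks controls; other roles are evaluated).
#' @param floor Absolute cutoff floor (default 5 mismatches).
#' @return Tibble: `sample`, `variety`, `role`, `min_dist_to_controls`,
#'   `cutoff`, `flag` (`isogenic` / `admixture` / `unevaluable`).
#' @export
flag_admixture <- function(m, labels, floor = 5) {
  labels <- as_tibble(labels)
  stopifnot(all(c("sample", "variety", "role") %in% names(labels)))
  d <- unclass(m)
  out <- vector("list", nrow(labels))
  for (i in seq_len(nrow(labels))) {
    s <- labels$sample[[i]]
    v <- labels$variety[[i]]
    ctrls <- setdiff(labels$sample[labels$variety == v & labels$role == "control"], s)
    all_ctrls <- labels$sample[labels$variety == v & labels$role == "control"]
    if (length(all_ctrls) == 0L) {
      out[[i]] <- tibble(sample = s, variety = v, role = labels$role[[i]],
                         min_dist_to_controls = NA_real_, cutoff = NA_real_,
                         flag = "unevaluable")
      next
    }
    cutoff <- floor
    if (length(all_ctrls) >= 2L) {
      cc <- d[all_ctrls, all_ctrls, drop = FALSE]
      cutoff <- max(cutoff, max(cc[upper.tri(cc)]))
    }
    if (length(ctrls) == 0L) { # the variety's only control
      out[[i]] <- tibble(sample = s, variety = v, role = labels$role[[i]],
                         min_dist_to_controls = 0, cutoff = cutoff,
                         flag = "isogenic")
      next
    }
    md <- min(d[s, ctrls])
    out[[i]] <- tibble(sample = s, variety = v, role = labels$role[[i]],
                       min_dist_to_controls = md, cutoff = cutoff,
                       flag = if (md > cutoff) "admixture" else "isogenic")
  }
  bind_rows(out)
}

#' Detect mosaic plants from per-stem allele frequencies
#'
#' A plant sampled as several stems is mosaic when the retained allele sets
#' at the target locus differ between stems. A stem retaining both the
#' ancestral transposon allele and a footprint allele carries two cell
#' lineages in one tissue (periclinal chimerism) and sets the chimera flag.
#'
#' @param stems Named list of `frequency_table`s, one per stem, or a single
#'   row-bound frequency table with distinct `sample_id` per stem.
#' @param catalog The [allele_catalog()] used for typing.
#' @return One-row tibble: `n_stems`, `verdict` (`mosaic` / `uniform` /
#'   `unevaluable`), `chimera_flag`, `stem_alleles` (list of per-stem
#'   retained sets).
#' @export
detect_mosaic <- function(stems, catalog) {
  if (is.data.frame(stems)) {
    stems <- split(as_tibble(stems), as_tibble(stems)$sample_id)
  }
  sets <- lapply(stems, retained_alleles)
  if (length(sets) < 2L) {
    warn("mosaic detection needs at least 2 stem samples")
    return(tibble(n_stems = length(sets), verdict = "unevaluable",
                  chimera_flag = NA, stem_alleles = list(sets)))
  }
  key <- vapply(sets, function(s) paste(sort(s), collapse = "|"), "")
  te <- te_allele_name(catalog)
  fps <- footprint_allele_names(catalog)
  chimera <- any(vapply(sets, function(s) {
    !is.na(te) && te %in% s && any(fps %in% s)
  }, TRUE))
  tibble(
    n_stems = length(sets),
    verdict = if (length(unique(key)) > 1L) "mosaic" else "uniform",
    chimera_flag = chimera,
    stem_alleles = list(sets)
  )
}

#' Welch's unequal-variance t test
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @param trait Optional trait label carried into the output.
#' @return One-row tibble: `trait`, `mean_x`, `mean_y`, `t`, `df`, `p`.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t <- function(x, y, trait = NA_character_) {
  if (length(x) < 2L || length(y) < 2L) abort("need at least 2 values per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(tibble(trait = trait, mean_x = mean(x), mean_y = mean(y),
                    t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    abort("zero variance in both groups")
  }
  tt <- t.test(x, y, var.equal = FALSE)
  tibble(trait = trait, mean_x = mean(x), mean_y = mean(y),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
}

#' Compare bolter and control phenotypes trait by trait
#'
#' Welch t tests of each trait between the two groups of a phenotype table.
#' A trait that is constant and equal in both groups (e.g. flowering
#' inflorescences when every control count is zero and every bolter count is
#' zero) is reported with `t = 0`, `p = 1`; a trait constant in one group
#' only is tested normally.
#'
#' @param phenotypes Table from [simulate_phenotypes()] or
#'   [read_phenotypes()]: `group` plus numeric trait columns.
#' @param groups Length-2 character: which `group` values to compare
#'   (x then y).
#' @return Tibble with one [welch_t()] row per trait.
#' @export
compare_phenotypes <- function(phenotypes,
                               groups = c("bolter", "control")) {
  phenotypes <- as_tibble(phenotypes)
  traits <- names(phenotypes)[vapply(phenotypes, is.numeric, TRUE)]
  bind_rows(lapply(traits, function(tr) {
    x <- phenotypes[[tr]][phenotypes$group == groups[[1]]]
    y <- phenotypes[[tr]][phenotypes$group == groups[[2]]]
    welch_t(x, y, trait = tr)
  }))
}
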