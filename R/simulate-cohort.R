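# Cohort-level simulators: genome-wide multilocus allele-call tables for
# clonal-identity analysis, and bolter/control phenotype tables.

#' Simulate a genome-wide multilocus allele-call table
#'
#' Emulates a targeted genotyping panel in which, at each locus, up to
#' `ploidy` alleles per sample are called and encoded as opaque identifiers.
#' Each variety gets a random tetraploid profile over `n_loci` loci.
#' Controls carry their variety's profile everywhere. Bolters carry the
#' variety profile except at the target locus, where one copy of the
#' transposon-allele token is swapped for a clone-specific footprint token
#' (the somatic excision event). Contaminants get an independent profile
#' that shares a configurable fraction of loci with their labeled variety;
#' contaminants given the same `group` share one profile (genetically
#' identical clones).
#'
#' @param clones Data frame with columns `clone_id`, `variety`, `role`
#'   (`"control"`, `"bolter"` or `"contaminant"`) and optionally `group`
#'   (contaminant profile sharing).
#' @param n_loci Number of loci in the panel (assay default 790).
#' @param alleles_per_locus Integer range `c(min, max)` of distinct allele
#'   identifiers segregating at each locus.
#' @param ploidy Alleles called per locus per sample.
#' @param target_locus Index of the locus carrying the somatic edit.
#' @param share_frac Fraction of loci a contaminant shares with its labeled
#'   variety.
#' @param seed Integer seed.
#' @return A tibble with columns `sample`, `locus`, `allele_1` ..
#'   `allele_<ploidy>`; allele identifiers are `L<locus>_<k>` tokens, with
#'   `L<target>_TE` marking the transposon allele at the target locus.
#' @examples
#' clones <- tibble::tibble(clone_id = c("C1", "B1"),
#'                          variety = "Nicola", role = c("control", "bolter"))
#' calls <- simulate_multilocus_calls(clones, n_loci = 20, seed = 1)
#' @export
simulate_multilocus_calls <- function(clones, n_loci = 790L,
                                      alleles_per_locus = c(2L, 6L),
                                      ploidy = 4L, target_locus = 1L,
                                      share_frac = 0.7, seed = 1L) {
  clones <- as_tibble(clones)
  stopifnot(all(c("clone_id", "variety", "role") %in% names(clones)))
  if (!all(clones$role %in% c("control", "bolter", "contaminant"))) {
    abort("role must be one of control, bolter, contaminant")
  }
  if (n_loci < 1L) abort("n_loci must be >= 1")
  if (target_locus < 1L || target_locus > n_loci) {
    abort("edit specified at unknown locus")
  }
  if (!"group" %in% names(clones)) clones$group <- clones$clone_id
  withr::with_seed(seed, {
    loci <- sprintf("L%04d", seq_len(n_loci))
    n_all <- sample(seq(alleles_per_locus[1], alleles_per_locus[2]),
                    n_loci, replace = TRUE)
    pools <- lapply(seq_len(n_loci), function(i) {
      toks <- sprintf("%s_%d", loci[i], seq_len(n_all[i]))
      if (i == target_locus) toks[1] <- sprintf("%s_TE", loci[i])
      toks
    })
    draw_profile <- function(force_te = TRUE) {
      prof <- lapply(seq_len(n_loci), function(i) {
        sort(sample(pools[[i]], ploidy, replace = TRUE))
      })
      if (force_te && !any(prof[[target_locus]] == pools[[target_locus]][1])) {
        prof[[target_locus]][1] <- pools[[target_locus]][1]
        prof[[target_locus]] <- sort(prof[[target_locus]])
      }
      prof
    }
    varieties <- unique(clones$variety)
    var_prof <- setNames(lapply(varieties, function(v) draw_profile()), varieties)
    contam_prof <- list()
    rows <- vector("list", nrow(clones))
    for (r in seq_len(nrow(clones))) {
      cl <- clones[r, ]
      base <- var_prof[[cl$variety]]
      prof <- switch(
        cl$role,
        control = base,
        bolter = {
          p <- base
          cell <- p[[target_locus]]
          te_tok <- sprintf("%s_TE", loci[target_locus])
          hit <- which(cell == te_tok)[1]
          cell[hit] <- sprintf("%s_FP_%s", loci[target_locus], cl$clone_id)
          p[[target_locus]] <- sort(cell)
          p
        },
        contaminant = {
          key <- as.character(cl$group)
          if (is.null(contam_prof[[key]])) {
            keep <- runif(n_loci) < share_frac
            p <- draw_profile(force_te = FALSE)
            p[keep] <- base[keep]
            contam_prof[[key]] <- p
          }
          contam_prof[[key]]
        }
      )
      m <- do.call(rbind, prof)
      colnames(m) <- paste0("allele_", seq_len(ploidy))
      rows[[r]] <- dplyr::bind_cols(tibble(sample = cl$clone_id, locus = loci),
                                    as_tibble(m))
    }
    out <- bind_rows(rows)
    attr(out, "seed") <- seed
    attr(out, "target_locus") <- loci[target_locus]
    out
  })
}

#' Phenotype-simulation configuration
#'
#' Group means default to the measured bolter-syndrome values: total
#' inflorescences 9.5 (bolter) vs 1.0 (control), flowering inflorescences
#' 3.5 vs 0.0 (all control inflorescences senesced), and main-stem length
#' 93.9 cm vs 74.8 cm. Variances are not reported for these traits, so the
#' SDs are free parameters with documented defaults.
#'
#' @param n Named vector: plants per group (8 bolters vs 4 controls).
#' @param means,sds Named lists (`bolter`, `control`) of per-trait values
#'   for `total_inflorescences`, `flowering_inflorescences`,
#'   `stem_length_cm`.
#' @return Object of class `pheno_sim_config`.
#' @export
pheno_sim_config <- function(n = c(bolter = 8L, control = 4L),
                             means = list(
                               bolter = c(total_inflorescences = 9.5,
                                          flowering_inflorescences = 3.5,
                                          stem_length_cm = 93.9),
                               control = c(total_inflorescences = 1.0,
                                           flowering_inflorescences = 0.0,
                                           stem_length_cm = 74.8)),
                             sds = list(
                               bolter = c(total_inflorescences = 2.0,
                                          flowering_inflorescences = 1.5,
                                          stem_length_cm = 8.0),
                               control = c(total_inflorescences = 0.5,
                                           flowering_inflorescences = 0.3,
                                           stem_length_cm = 6.0))) {
  if (any(unlist(sds) <= 0)) abort("SDs must be positive")
  if (any(n < 2)) abort("need at least 2 plants per group")
  structure(list(n = n, means = means, sds = sds), class = "pheno_sim_config")
}

#' Simulate a bolter/control phenotype table
#'
#' Per-plant values are drawn from per-group normal distributions;
#' inflorescence counts are truncated at zero and rounded to integers. A
#' count trait with group mean exactly 0 is emitted as all zeros (the
#' degenerate "all senesced" case).
#'
#' @param config A [pheno_sim_config()].
#' @param seed Integer seed.
#' @return Tibble with columns `sample`, `group`, `total_inflorescences`,
#'   `flowering_inflorescences`, `stem_length_cm`.
#' @export
simulate_phenotypes <- function(config = pheno_sim_config(), seed = 1L) {
  stopifnot(inherits(config, "pheno_sim_config"))
  count_traits <- c("total_inflorescences", "flowering_inflorescences")
  withr::with_seed(seed, {
    out <- lapply(names(config$n), function(grp) {
      ng <- config$n[[grp]]
      vals <- lapply(names(config$means[[grp]]), function(trait) {
        mu <- config$means[[grp]][[trait]]
        sd <- config$sds[[grp]][[trait]]
        x <- rnorm(ng, mu, sd)
        if (trait %in% count_traits) {
          if (mu == 0) x <- rep(0, ng) else x <- round(pmax(x, 0))
        }
        x
      })
      names(vals) <- names(config$means[[grp]])
      dplyr::bind_cols(
        tibble(sample = sprintf("%s_%02d", grp, seq_len(ng)), group = grp),
        as_tibble(vals)
      )
    })
    out <- bind_rows(out)
    attr(out, "seed") <- seed
    out
  })
}
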