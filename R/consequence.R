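# Protein-consequence prediction: translate each allele's variable region in
# a user-supplied coding context and classify the effect of its indel.

#' Coding context around the variable region
#'
#' The variable region sits inside an exon; to translate an allele one needs
#' the in-frame coding sequence upstream, the phase of the region's first
#' base, and the coding sequence downstream through (and past) the wild-type
#' stop codon, so that frameshifted alleles can find a later stop.
#'
#' @param cds_upstream In-frame coding sequence ending at the region start
#'   (begins with ATG in the packaged fixture).
#' @param frame_offset 0..2; index within the variable region of the first
#'   base that starts a complete codon. Must satisfy
#'   `(nchar(cds_upstream) + frame_offset) %% 3 == 0`.
#' @param cds_downstream Coding sequence from the region end, containing the
#'   wild-type stop codon and additional sequence past it.
#' @param locus Optional [locus_model()] used to validate that the wild-type
#'   CDS has length divisible by 3 and exactly one in-frame stop.
#' @return Object of class `coding_context`.
#' @seealso [stcdf1_coding_context()] for the packaged synthetic fixture.
#' @export
coding_context <- function(cds_upstream, frame_offset, cds_downstream,
                           locus = NULL) {
  cds_upstream <- check_dna(cds_upstream, "cds_upstream")
  cds_downstream <- check_dna(cds_downstream, "cds_downstream")
  frame_offset <- as.integer(frame_offset)
  if (frame_offset < 0L || frame_offset > 2L) abort("frame_offset must be 0..2")
  if ((nchar(cds_upstream) + frame_offset) %% 3L != 0L) {
    abort("frame inconsistency: cds_upstream length and frame_offset disagree")
  }
  ctx <- structure(
    list(cds_upstream = cds_upstream, frame_offset = frame_offset,
         cds_downstream = cds_downstream),
    class = "coding_context")
  if (!is.null(locus)) {
    cds <- paste0(cds_upstream, locus$variable_region, cds_downstream)
    if (nchar(cds) %% 3L != 0L) {
      abort("wild-type CDS length must be divisible by 3")
    }
    prot <- translate_cds(cds)
    if (!attr(prot, "has_stop")) abort("wild-type CDS lacks an in-frame stop")
    # no second in-frame stop after the wild-type stop
    rest <- substr(cds, (nchar(prot) + 1L) * 3L + 1L, nchar(cds))
    if (nchar(rest) >= 3L && attr(translate_cds_quiet(rest), "stopped_early")) {
      abort("wild-type CDS must contain exactly one in-frame stop")
    }
  }
  ctx
}

#' Translate a coding sequence with the standard genetic code
#'
#' Translation starts at position 0 and stops at the first stop codon; the
#' protein is returned without the stop symbol. A trailing partial codon is
#' ignored.
#'
#' @param dna DNA string of length >= 3.
#' @return Protein string with attribute `has_stop` (`FALSE` when
#'   translation ran off the end without a stop codon).
#' @examples
#' translate_cds("ATGAAATAA")
#' @export
translate_cds <- function(dna) {
  dna <- check_dna(dna, "dna")
  if (nchar(dna) < 3L) abort("need at least one codon")
  n <- nchar(dna) %/% 3L
  codons <- substring(dna, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  stop_at <- which(aa == "*")[1]
  if (is.na(stop_at)) {
    structure(paste(aa, collapse = ""), has_stop = FALSE)
  } else {
    structure(paste(aa[seq_len(stop_at - 1L)], collapse = ""), has_stop = TRUE)
  }
}

# internal: like translate_cds but reports whether a stop occurred at all
translate_cds_quiet <- function(dna) {
  p <- translate_cds(dna)
  structure(p, stopped_early = attr(p, "has_stop"))
}

#' Packaged synthetic coding context for the StCDF1 fixture
#'
#' The true CDS and phase of the variable region are not published, so the
#' package ships a synthetic context engineered to realize the reported
#' outcomes: 7-nt insertions truncate the protein at a premature stop, the
#' 6-nt insertion adds exactly two residues in frame, and the 1-nt deletion
#' shifts the frame into a longer, altered C-terminus. Consequence calls
#' against this fixture characterize the alleles' indel arithmetic, not the
#' real gene.
#'
#' @return A [coding_context()].
#' @export
stcdf1_coding_context <- function() {
  coding_context(
    cds_upstream = paste0("ATG", strrep("GCA", 6), "GC"),
    frame_offset = 1L,
    cds_downstream = paste0(paste0(strrep("GCA", 10), "G"),
                            "TAA", "C", "TGA", "A", "TAA", "GCAGCAG"),
    locus = stcdf1_locus()
  )
}

#' Predict the protein consequence of an allele
#'
#' Assembles the allele CDS (upstream + edited variable region +
#' downstream), translates wild type and allele, and classifies:
#' `identical`; `in_frame_insertion` when the inserted length is a multiple
#' of 3 and the downstream protein is unchanged apart from the inserted
#' residues (one junction substitution is allowed when the insertion splits
#' a codon); `premature_stop` when the allele protein ends before the
#' wild-type stop; `frameshift_extension` when it ends after; `other`
#' otherwise.
#'
#' @param context A [coding_context()].
#' @param allele An [allele_def()] or allele name resolved in `catalog`.
#' @param locus,te,catalog As in [assemble_allele_sequence()].
#' @return One-row tibble: `allele`, `classification`, `extra_aa` (protein
#'   length change in residues; negative for truncations), `stop_shift`
#'   (codons relative to the wild-type stop), `protein_length`,
#'   `wt_protein_length`, `protein`.
#' @examples
#' predict_consequence(stcdf1_coding_context(), "StCDF1.7",
#'                     catalog = stcdf1_catalog())
#' @export
predict_consequence <- function(context, allele, locus = NULL, te = NULL,
                                catalog = NULL) {
  stopifnot(inherits(context, "coding_context"))
  if (!is.null(catalog)) {
    locus <- locus %||% catalog$locus
    te <- te %||% catalog$te
    if (is.character(allele)) allele <- catalog$alleles[[allele]] %||%
        abort(sprintf("unknown allele '%s'", allele))
  }
  region_wt <- locus$variable_region
  region_mut <- assemble_allele_sequence(allele, locus = locus, te = te)
  wt_cds <- paste0(context$cds_upstream, region_wt, context$cds_downstream)
  mut_cds <- paste0(context$cds_upstream, region_mut, context$cds_downstream)
  wt_prot <- translate_cds(wt_cds)
  mut_prot <- translate_cds(mut_cds)
  wl <- nchar(wt_prot); ml <- nchar(mut_prot)
  net <- nchar(region_mut) - nchar(region_wt)
  classification <- if (mut_prot == wt_prot) {
    "identical"
  } else if (net > 0L && net %% 3L == 0L && ml == wl + net %/% 3L &&
             in_frame_compatible(wt_prot, mut_prot, net %/% 3L)) {
    "in_frame_insertion"
  } else if (ml < wl) {
    "premature_stop"
  } else if (ml > wl) {
    "frameshift_extension"
  } else {
    "other"
  }
  tibble(
    allele = allele$name,
    classification = classification,
    extra_aa = ml - wl,
    stop_shift = ml - wl,
    protein_length = ml,
    wt_protein_length = wl,
    protein = as.character(mut_prot)
  )
}

# The mutant protein equals the wild type with k residues inserted, allowing
# at most one substitution at the insertion junction (codon split).
in_frame_compatible <- function(wt, mut, k) {
  wtc <- strsplit(wt, "")[[1]]
  mutc <- strsplit(mut, "")[[1]]
  npre <- 0L
  while (npre < length(wtc) && wtc[npre + 1L] == mutc[npre + 1L]) npre <- npre + 1L
  nsuf <- 0L
  while (nsuf < length(wtc) - npre &&
         wtc[length(wtc) - nsuf] == mutc[length(mutc) - nsuf]) nsuf <- nsuf + 1L
  npre + nsuf >= length(wtc) - 1L
}

#' Predict consequences for every allele of a catalog
#'
#' @param catalog An [allele_catalog()].
#' @param context A [coding_context()].
#' @return Tibble with one row per assemblable allele.
#' @export
predict_consequences <- function(catalog, context = stcdf1_coding_context()) {
  bind_rows(lapply(names(catalog$alleles), function(nm) {
    predict_consequence(context, nm, catalog = catalog)
  }))
}

#' Write per-allele protein FASTA
#'
#' @param consequences Output of [predict_consequences()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(consequences, path) {
  aa <- Biostrings::AAStringSet(setNames(consequences$protein,
                                         consequences$allele))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
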