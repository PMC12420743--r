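# Reference model of the StCDF1 variable region, the disrupting DNA
# transposon, and the catalog of named alleles with their diagnostic
# junction patterns.

#' Describe the targeted locus
#'
#' A locus model holds the wild-type sequence of the variable region that the
#' assays interrogate, plus the canonical transposon insertion site: the
#' position immediately 3' of the TSD-like motif at which every known
#' insertion allele arose.
#'
#' Coordinates are 0-based half-open internally; the genomic anchor is the
#' 1-based coordinate reported in outputs.
#'
#' @param locus_id Locus label.
#' @param chrom Chromosome label.
#' @param anchor_position 1-based genomic coordinate anchoring the probe
#'   region on the reference genome.
#' @param probe_region_length Length in nt of the short-read probe region.
#' @param variable_region Uppercase wild-type sequence of the variable region.
#' @param insertion_site 0-based offset into `variable_region` immediately
#'   after the TSD-like motif; all catalog insertions occur here.
#' @param tsd_motif Target-site-duplication-like motif directly 5' of the
#'   insertion site.
#' @return An object of class `locus_model`.
#' @seealso [stcdf1_locus()] for the packaged StCDF1 model.
#' @export
locus_model <- function(locus_id, chrom, anchor_position, variable_region,
                        insertion_site, probe_region_length = 150L,
                        tsd_motif = "ACACTAG") {
  variable_region <- check_dna(variable_region, "variable_region")
  tsd_motif <- check_dna(tsd_motif, "tsd_motif")
  insertion_site <- as.integer(insertion_site)
  if (insertion_site <= 0L || insertion_site >= nchar(variable_region)) {
    abort("insertion_site must lie strictly inside variable_region")
  }
  if (substr(variable_region, insertion_site - nchar(tsd_motif) + 1L,
             insertion_site) != tsd_motif) {
    abort("variable_region must end with tsd_motif immediately before insertion_site")
  }
  structure(
    list(
      locus_id = locus_id,
      chrom = chrom,
      anchor_position = as.integer(anchor_position),
      probe_region_length = as.integer(probe_region_length),
      variable_region = variable_region,
      insertion_site = insertion_site,
      tsd_motif = tsd_motif
    ),
    class = "locus_model"
  )
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("<locus_model> %s (%s:%d), variable region %d nt, insertion site %d after %s\n",
              x$locus_id, x$chrom, x$anchor_position, nchar(x$variable_region),
              x$insertion_site, x$tsd_motif))
  invisible(x)
}

#' Describe the disrupting DNA transposon
#'
#' Only the two junction-proximal fragments of the element are known from the
#' diagnostic patterns; the interior is synthetic filler bringing the element
#' to its full length. The 3' fragment ends with a copy of the TSD-like
#' motif, so splicing the assembled element at the insertion site reproduces
#' the target-site duplication flanking a Class II cut-and-paste insertion.
#'
#' @param five_prime_fragment First bases of the element (as printed in the
#'   left junction pattern).
#' @param three_prime_fragment Last bases of the element (as printed in the
#'   right junction pattern).
#' @param total_length Full element length in nt.
#' @param interior Optional interior sequence; when `NULL` a fixed synthetic
#'   filler is generated so that fragments plus interior have `total_length`.
#' @return An object of class `transposon_model`.
#' @seealso [stcdf1_transposon()]
#' @export
transposon_model <- function(five_prime_fragment, three_prime_fragment,
                             total_length = 865L, interior = NULL) {
  five_prime_fragment <- check_dna(five_prime_fragment, "five_prime_fragment")
  three_prime_fragment <- check_dna(three_prime_fragment, "three_prime_fragment")
  total_length <- as.integer(total_length)
  flen <- nchar(five_prime_fragment) + nchar(three_prime_fragment)
  if (total_length < flen) {
    abort("total_length must be at least the combined fragment length")
  }
  if (is.null(interior)) {
    need <- total_length - flen
    # Early stops in the reading frame entered at the canonical insertion
    # site, then a no-stop periodic filler; documented as non-biological.
    stopper <- "CCTAATAATAA"
    if (need <= nchar(stopper)) {
      interior <- substr(stopper, 1L, need)
    } else {
      filler <- strrep("CGA", ceiling((need - nchar(stopper)) / 3))
      interior <- paste0(stopper, substr(filler, 1L, need - nchar(stopper)))
    }
  } else {
    interior <- check_dna(interior, "interior", allow_empty = TRUE)
    if (nchar(interior) + flen != total_length) {
      abort("interior length inconsistent with total_length")
    }
  }
  structure(
    list(
      five_prime_fragment = five_prime_fragment,
      three_prime_fragment = three_prime_fragment,
      total_length = total_length,
      interior = interior
    ),
    class = "transposon_model"
  )
}

#' @export
print.transposon_model <- function(x, ...) {
  cat(sprintf("<transposon_model> %d nt, fragments %d/%d nt, synthetic interior %d nt\n",
              x$total_length, nchar(x$five_prime_fragment),
              nchar(x$three_prime_fragment), nchar(x$interior)))
  invisible(x)
}

#' Full sequence of the modeled transposon
#'
#' @param te A [transposon_model()].
#' @return A single DNA string of length `te$total_length`.
#' @export
te_sequence <- function(te) {
  stopifnot(inherits(te, "transposon_model"))
  paste0(te$five_prime_fragment, te$interior, te$three_prime_fragment)
}

#' Define one allele of the catalog
#'
#' @param name Allele name.
#' @param kind One of `wild_type`, `footprint_insertion`, `te_insertion`,
#'   `deletion`, `te_like_variant`, `user_defined`.
#' @param insertion_seq Inserted sequence for insertion kinds (empty
#'   otherwise).
#' @param deletion_len Deleted length in nt for `deletion` alleles.
#' @param note Free-text provenance note (e.g. "sequence unverified").
#' @return An object of class `allele_def`.
#' @export
allele_def <- function(name,
                       kind = c("wild_type", "footprint_insertion", "te_insertion",
                                "deletion", "te_like_variant", "user_defined"),
                       insertion_seq = "", deletion_len = 0L, note = "") {
  kind <- match.arg(kind)
  insertion_seq <- if (nzchar(insertion_seq)) check_dna(insertion_seq, "insertion_seq") else ""
  deletion_len <- as.integer(deletion_len)
  if (kind == "footprint_insertion" && (!nzchar(insertion_seq) || deletion_len != 0L)) {
    abort("footprint_insertion requires a non-empty insertion_seq and deletion_len = 0")
  }
  if (kind == "deletion" && (nzchar(insertion_seq) || deletion_len < 1L)) {
    abort("deletion requires an empty insertion_seq and deletion_len >= 1")
  }
  structure(
    list(name = name, kind = kind, insertion_seq = insertion_seq,
         deletion_len = deletion_len, note = note),
    class = "allele_def"
  )
}

#' Bundle alleles, locus and transposon into a catalog
#'
#' The catalog carries everything the typing and discovery stages need: the
#' allele definitions with their derived junction patterns, the locus model,
#' the transposon model and the assay ploidy.
#'
#' @param alleles List of [allele_def()] objects (unique names).
#' @param locus A [locus_model()].
#' @param te A [transposon_model()] (required when any allele is a
#'   `te_insertion`).
#' @param ploidy Assay ploidy; 4 for autotetraploid potato.
#' @param flank Integer vector of length 2: left and right flank lengths used
#'   by [derive_patterns()].
#' @return An object of class `allele_catalog`.
#' @seealso [stcdf1_catalog()]
#' @export
allele_catalog <- function(alleles, locus, te = NULL, ploidy = 4L,
                           flank = c(27L, 22L)) {
  nms <- vapply(alleles, `[[`, "", "name")
  if (anyDuplicated(nms)) abort("allele names must be unique")
  if (ploidy < 1L) abort("ploidy must be >= 1")
  names(alleles) <- nms
  patterns <- lapply(alleles, derive_patterns, locus = locus, te = te, flank = flank)
  structure(
    list(alleles = alleles, patterns = patterns, locus = locus, te = te,
         ploidy = as.integer(ploidy), flank = as.integer(flank)),
    class = "allele_catalog"
  )
}

#' @export
print.allele_catalog <- function(x, ...) {
  cat(sprintf("<allele_catalog> %d alleles at %s (ploidy %d)\n",
              length(x$alleles), x$locus$locus_id, x$ploidy))
  print(tidy(x))
  invisible(x)
}

#' @rdname allele_catalog
#' @param x An `allele_catalog`.
#' @param ... Unused.
#' @export
tidy.allele_catalog <- function(x, ...) {
  tibble(
    allele = names(x$alleles),
    kind = vapply(x$alleles, `[[`, "", "kind"),
    insertion_seq = vapply(x$alleles, `[[`, "", "insertion_seq"),
    deletion_len = vapply(x$alleles, `[[`, 0L, "deletion_len"),
    n_patterns = lengths(x$patterns),
    length = nchar(allele_sequences(x))
  )
}

#' Name of the transposon-insertion allele of a catalog
#'
#' @param catalog An [allele_catalog()].
#' @return Allele name, or `NA_character_` when the catalog has none.
#' @export
te_allele_name <- function(catalog) {
  kinds <- vapply(catalog$alleles, `[[`, "", "kind")
  nm <- names(kinds)[kinds == "te_insertion"]
  if (length(nm)) nm[[1]] else NA_character_
}

# Alleles that can arise as excision footprints (any non-TE indel allele).
footprint_allele_names <- function(catalog) {
  keep <- vapply(catalog$alleles, function(a) {
    a$kind %in% c("footprint_insertion", "deletion") ||
      (a$kind == "user_defined" && nzchar(a$insertion_seq))
  }, TRUE)
  names(catalog$alleles)[keep]
}

#' Assemble the full variable-region sequence of an allele
#'
#' Applies the allele's edit to the wild-type variable region at the
#' canonical insertion site. Wild type returns the region unchanged;
#' insertion alleles splice their insert (the full assembled transposon for
#' `te_insertion`); deletion alleles remove bases starting at the site.
#'
#' @param allele An [allele_def()] or the name of an allele in `catalog`.
#' @param locus A [locus_model()]; defaults to `catalog$locus`.
#' @param te A [transposon_model()]; defaults to `catalog$te`.
#' @param catalog Optional [allele_catalog()] supplying `locus`/`te` and
#'   resolving `allele` by name.
#' @return A single DNA string.
#' @examples
#' cat <- stcdf1_catalog()
#' nchar(assemble_allele_sequence("StCDF1.3", catalog = cat)) -
#'   nchar(assemble_allele_sequence("StCDF1.1", catalog = cat))
#' @export
assemble_allele_sequence <- function(allele, locus = NULL, te = NULL,
                                     catalog = NULL) {
  if (!is.null(catalog)) {
    locus <- locus %||% catalog$locus
    te <- te %||% catalog$te
    if (is.character(allele)) {
      if (!allele %in% names(catalog$alleles)) {
        abort(sprintf("unknown allele '%s'", allele))
      }
      allele <- catalog$alleles[[allele]]
    }
  }
  stopifnot(inherits(allele, "allele_def"), inherits(locus, "locus_model"))
  region <- locus$variable_region
  site <- locus$insertion_site
  switch(
    allele$kind,
    wild_type = region,
    te_insertion = {
      if (is.null(te)) abort("te_insertion allele requires a transposon_model")
      str_insert(region, site, te_sequence(te))
    },
    deletion = {
      if (site + allele$deletion_len > nchar(region)) {
        abort("deletion extends past the end of the variable region")
      }
      str_delete(region, site, allele$deletion_len)
    },
    te_like_variant = abort("te_like_variant alleles have no fully assembled sequence"),
    # footprint_insertion and user_defined with an insertion spec
    {
      if (!nzchar(allele$insertion_seq)) {
        abort("user_defined allele needs an insertion or deletion spec to be assembled")
      }
      str_insert(region, site, allele$insertion_seq)
    }
  )
}

#' Assembled sequences for every allele of a catalog
#'
#' @param catalog An [allele_catalog()].
#' @return Named character vector of sequences.
#' @export
allele_sequences <- function(catalog) {
  vapply(names(catalog$alleles), function(nm) {
    assemble_allele_sequence(nm, catalog = catalog)
  }, "", USE.NAMES = TRUE)
}

#' Derive the diagnostic junction pattern(s) of an allele
#'
#' Non-transposon alleles yield one exact-match pattern spanning the edit
#' with genomic flanks; the transposon allele yields two junction patterns
#' (left genomic flank + element start, element end + right genomic flank).
#' With the default flanks the packaged catalog reproduces the published
#' diagnostic strings byte for byte.
#'
#' @inheritParams assemble_allele_sequence
#' @param flank Integer vector `c(left, right)` of flank lengths around the
#'   edit.
#' @return Character vector of one (non-TE) or two (TE) patterns.
#' @export
derive_patterns <- function(allele, locus, te = NULL, flank = c(27L, 22L)) {
  stopifnot(inherits(allele, "allele_def"), inherits(locus, "locus_model"))
  region <- locus$variable_region
  site <- locus$insertion_site
  lf <- as.integer(flank[[1]]); rf <- as.integer(flank[[2]])
  if (lf > site) abort("left flank exceeds sequence available before the insertion site")
  left <- substr(region, site - lf + 1L, site)
  right_from <- function(pos0) { # rf bases of the region from 0-based pos0
    if (pos0 + rf > nchar(region)) {
      abort("right flank exceeds sequence available after the edit")
    }
    substr(region, pos0 + 1L, pos0 + rf)
  }
  switch(
    allele$kind,
    wild_type = paste0(left, right_from(site)),
    te_insertion = {
      if (is.null(te)) abort("te_insertion allele requires a transposon_model")
      c(paste0(left, te$five_prime_fragment),
        paste0(te$three_prime_fragment, right_from(site)))
    },
    deletion = paste0(left, right_from(site + allele$deletion_len)),
    te_like_variant = abort("te_like_variant alleles have no exact pattern"),
    {
      if (!nzchar(allele$insertion_seq)) {
        abort("user_defined allele needs an insertion spec to derive a pattern")
      }
      paste0(left, allele$insertion_seq, right_from(site))
    }
  )
}

#' Terminal-inverted-repeat overlap of the transposon fragments
#'
#' Length of the longest exact common substring between the element's 5'
#' fragment and the reverse complement of its 3' fragment. A Class II TIR
#' element shows a long overlap; unrelated fragments show a short one.
#'
#' @param te A [transposon_model()].
#' @return Integer overlap length `k`.
#' @export
tir_overlap <- function(te) {
  stopifnot(inherits(te, "transposon_model"))
  a <- strsplit(te$five_prime_fragment, "")[[1]]
  b <- strsplit(revcomp(te$three_prime_fragment), "")[[1]]
  # longest common substring by dynamic programming
  best <- 0L
  prev <- integer(length(b))
  for (i in seq_along(a)) {
    cur <- integer(length(b))
    hit <- which(b == a[[i]])
    if (length(hit)) {
      cur[hit] <- ifelse(hit == 1L, 1L, prev[pmax(hit - 1L, 1L)] + 1L)
    }
    best <- max(best, cur)
    prev <- cur
  }
  as.integer(best)
}

# ---- packaged StCDF1 model -------------------------------------------------

# The 49-nt wild-type core and the junction fragments are the published
# diagnostic strings; the padding that extends the core to the 150-nt probe
# region, and the transposon interior, are fixed synthetic sequences
# (T-free so they cannot harbor stop codons or spurious motif copies).
.stcdf1_core <- "CTAAAAGCTCTATATGGTCAACACTAGGTATCAGGAATGAGAAGATTGA"
.stcdf1_lpad <- substr(strrep("GAC", 17), 1, 50)
.stcdf1_rpad <- strrep("AGC", 17)

#' Packaged StCDF1 locus model
#'
#' The variable region is the published 49-nt wild-type core centered in a
#' 150-nt region; the flanking padding is fixed synthetic sequence (only the
#' core is biological). The canonical insertion site lies immediately after
#' the TSD-like motif `ACACTAG`.
#'
#' @return A [locus_model()].
#' @export
stcdf1_locus <- function() {
  locus_model(
    locus_id = "StCDF1",
    chrom = "chr05",
    anchor_position = 4487957L,
    variable_region = paste0(.stcdf1_lpad, .stcdf1_core, .stcdf1_rpad),
    insertion_site = 77L,
    probe_region_length = 150L,
    tsd_motif = "ACACTAG"
  )
}

#' Packaged StCDF1.3 transposon model
#'
#' Junction fragments are the published ones; the 865-nt total length is the
#' reported element size and the interior is synthetic filler.
#'
#' @param total_length Element length in nt.
#' @return A [transposon_model()].
#' @export
stcdf1_transposon <- function(total_length = 865L) {
  transposon_model(
    five_prime_fragment = "GTAAGGCTGGGCACCGGACCGGAATGG",
    three_prime_fragment = "ACCCGTTCCGGTGCCCAGCCTTAACACTAG",
    total_length = total_length
  )
}

#' Packaged StCDF1 allele catalog
#'
#' The named alleles of the variable region: wild type (StCDF1.1), the
#' excision footprints StCDF1.2a/2b (7-nt insertions) and StCDF1.7 (6-nt
#' in-frame insertion), the 865-nt transposon insertion StCDF1.3, plus
#' StCDF1.4 (a 7-nt insertion whose sequence is not published; a synthetic
#' TSD-like stand-in is used) and StCDF1.8 (1-nt deletion at the insertion
#' site; exact placement within the motif is not published, and the two
#' junction-equivalent placements are indistinguishable at sequence level).
#'
#' @param locus,te Optional overrides of the packaged models.
#' @param ploidy Assay ploidy (4).
#' @return An [allele_catalog()].
#' @examples
#' tidy(stcdf1_catalog())
#' @export
stcdf1_catalog <- function(locus = stcdf1_locus(), te = stcdf1_transposon(),
                           ploidy = 4L) {
  alleles <- list(
    allele_def("StCDF1.1", "wild_type"),
    allele_def("StCDF1.2a", "footprint_insertion", insertion_seq = "CCACTAG"),
    allele_def("StCDF1.2b", "footprint_insertion", insertion_seq = "TCACTAG"),
    allele_def("StCDF1.3", "te_insertion"),
    allele_def("StCDF1.4", "user_defined", insertion_seq = "GCACTAG",
               note = "sequence unverified; synthetic 7-nt stand-in"),
    allele_def("StCDF1.7", "footprint_insertion", insertion_seq = "CACTAG"),
    allele_def("StCDF1.8", "deletion", deletion_len = 1L,
               note = "sequence unverified; 1-nt deletion at the insertion site")
  )
  allele_catalog(alleles, locus = locus, te = te, ploidy = ploidy)
}

# ---- serialization ---------------------------------------------------------

#' Write / read an allele catalog as JSON
#'
#' The JSON file records allele definitions, derived patterns, the locus and
#' transposon models, the ploidy and the flank lengths, so a catalog round
#' trips losslessly.
#'
#' @param catalog An [allele_catalog()].
#' @param path File path.
#' @return `write_catalog_json()` returns `path` invisibly;
#'   `read_catalog_json()` returns an [allele_catalog()].
#' @export
write_catalog_json <- function(catalog, path) {
  obj <- list(
    ploidy = catalog$ploidy,
    flank = catalog$flank,
    locus = unclass(catalog$locus),
    te = if (!is.null(catalog$te)) unclass(catalog$te),
    alleles = lapply(catalog$alleles, unclass),
    patterns = catalog$patterns
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_catalog_json
#' @export
read_catalog_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  locus <- locus_model(
    locus_id = obj$locus$locus_id, chrom = obj$locus$chrom,
    anchor_position = obj$locus$anchor_position,
    variable_region = obj$locus$variable_region,
    insertion_site = obj$locus$insertion_site,
    probe_region_length = obj$locus$probe_region_length,
    tsd_motif = obj$locus$tsd_motif
  )
  te <- if (!is.null(obj$te)) {
    transposon_model(obj$te$five_prime_fragment, obj$te$three_prime_fragment,
                     obj$te$total_length, obj$te$interior)
  }
  alleles <- lapply(obj$alleles, function(a) {
    allele_def(a$name, a$kind, insertion_seq = a$insertion_seq,
               deletion_len = a$deletion_len, note = a$note %||% "")
  })
  allele_catalog(alleles, locus = locus, te = te, ploidy = obj$ploidy,
                 flank = obj$flank)
}

#' Export assembled allele sequences as FASTA
#'
#' One record per allele, ID = allele name.
#'
#' @param catalog An [allele_catalog()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_catalog_fasta <- function(catalog, path) {
  seqs <- Biostrings::DNAStringSet(allele_sequences(catalog))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
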