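# Footprint discovery: global alignment of reads to the wild-type variable
# region, grouping of indel/SNP haplotypes, detection of transposon-like
# near-miss junctions, and naming/classification of novel alleles.

# Fixed alignment scoring (not assay-derived): chosen so a 7-nt insertion is
# cheaper than 7 scattered mismatches. Gap of length k costs open + k*extend.
.align_scoring <- list(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2)

.align_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(
    match = .align_scoring$match, mismatch = .align_scoring$mismatch,
    baseOnly = TRUE)
}

# Extract non-match edits from one pair of gapped aligned strings
# (query, ref). Returns a tibble(kind, ref_position, length, sequence) with
# 0-based ref positions; insertions sit before ref_position.
edits_from_alignment <- function(qa, ra) {
  q <- strsplit(qa, "")[[1]]
  r <- strsplit(ra, "")[[1]]
  state <- ifelse(r == "-", "insertion",
                  ifelse(q == "-", "deletion",
                         ifelse(q == r, "match", "mismatch")))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  refpos <- cumsum(r != "-") # 1-based ref coordinate at each column
  out <- list()
  for (i in seq_along(runs$values)) {
    kind <- runs$values[[i]]
    if (kind == "match") next
    cols <- starts[i]:ends[i]
    if (kind == "insertion") {
      out[[length(out) + 1L]] <- tibble(
        kind = "insertion",
        ref_position = refpos[starts[i]], # 0-based position the insert precedes
        length = length(cols),
        sequence = paste(q[cols], collapse = ""))
    } else if (kind == "deletion") {
      out[[length(out) + 1L]] <- tibble(
        kind = "deletion",
        ref_position = refpos[starts[i]] - 1L,
        length = length(cols),
        sequence = paste(r[cols], collapse = ""))
    } else {
      out[[length(out) + 1L]] <- tibble(
        kind = "mismatch",
        ref_position = refpos[cols] - 1L,
        length = 1L,
        sequence = q[cols])
    }
  }
  if (!length(out)) {
    tibble(kind = character(), ref_position = integer(),
           length = integer(), sequence = character())
  } else {
    bind_rows(out)
  }
}

# Shift indels as far 3' as possible (right normalization). At this locus
# footprint insertions abut the right edge of the TSD motif, so the
# right-normalized breakpoint of a true footprint equals the canonical
# insertion site.
normalize_edits <- function(edits, ref) {
  if (!nrow(edits)) return(edits)
  n <- nchar(ref)
  for (i in seq_len(nrow(edits))) {
    kind <- edits$kind[i]
    p <- edits$ref_position[i]
    if (kind == "insertion") {
      s <- edits$sequence[i]
      while (p < n && substr(s, 1L, 1L) == substr(ref, p + 1L, p + 1L)) {
        s <- paste0(substr(s, 2L, nchar(s)), substr(s, 1L, 1L))
        p <- p + 1L
      }
      edits$sequence[i] <- s
      edits$ref_position[i] <- p
    } else if (kind == "deletion") {
      L <- edits$length[i]
      while (p + L < n &&
             substr(ref, p + 1L, p + 1L) == substr(ref, p + L + 1L, p + L + 1L)) {
        p <- p + 1L
      }
      edits$ref_position[i] <- p
      edits$sequence[i] <- substr(ref, p + 1L, p + L)
    }
  }
  edits[order(edits$ref_position, edits$kind), , drop = FALSE]
}

# Apply an edit table back onto the reference (inverse of extraction).
apply_edits <- function(ref, edits) {
  if (!nrow(edits)) return(ref)
  ed <- edits[order(-edits$ref_position), , drop = FALSE]
  out <- ref
  for (i in seq_len(nrow(ed))) {
    p <- ed$ref_position[i]
    out <- switch(ed$kind[i],
      insertion = str_insert(out, p, ed$sequence[i]),
      deletion = str_delete(out, p, ed$length[i]),
      mismatch = paste0(substr(out, 1L, p), ed$sequence[i],
                        substr(out, p + 2L, nchar(out)))
    )
  }
  out
}

profile_key <- function(edits) {
  if (!nrow(edits)) return("ref")
  paste(sprintf("%s@%d:%s", edits$kind, edits$ref_position, edits$sequence),
        collapse = ";")
}

#' Globally align a read to the wild-type variable region
#'
#' Needleman-Wunsch global alignment with fixed scoring (match +2, mismatch
#' -3, gap open -5, gap extend -2; a gap of length k costs open + k*extend).
#' The read and its reverse complement are both aligned and the higher
#' scoring orientation kept (forward on ties). Indels in the resulting edit
#' list are right-normalized.
#'
#' @param seq A single DNA string.
#' @param locus A [locus_model()].
#' @return A list of class `pairwise_alignment`: `strand`, `score`, `edits`
#'   (tibble of non-match edits with 0-based `ref_position`), `query`.
#' @export
align_to_wildtype <- function(seq, locus) {
  res <- align_reads(tibble(read_id = "q", sequence = seq), locus)
  structure(list(strand = res$strand[[1]], score = res$score[[1]],
                 edits = res$edits[[1]], query = seq),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> strand %s, score %g, %d edit(s)\n",
              x$strand, x$score, nrow(x$edits)))
  if (nrow(x$edits)) print(x$edits)
  invisible(x)
}

#' Align many reads to the wild-type variable region
#'
#' Vectorized version of [align_to_wildtype()].
#'
#' @param reads Data frame with `sequence` (and optionally `read_id`), or a
#'   character vector.
#' @param locus A [locus_model()].
#' @return Tibble with `read_id`, `strand`, `score`, `profile` (canonical
#'   edit-profile key, `"ref"` for an exact match) and `edits` (list
#'   column).
#' @export
align_reads <- function(reads, locus) {
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read%05d", seq_along(reads)),
                    sequence = unname(reads))
  }
  reads <- as_tibble(reads)
  seqs <- check_dna(reads$sequence, "read sequence")
  ref <- locus$variable_region
  subject <- Biostrings::DNAString(ref)
  submat <- .align_submat()
  aln_score <- function(x) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(x), subject, type = "global",
      substitutionMatrix = submat,
      gapOpening = .align_scoring$gap_open,
      gapExtension = .align_scoring$gap_extend, scoreOnly = FALSE)
  }
  uniq <- unique(seqs)
  umap <- match(seqs, uniq)
  fwd <- aln_score(uniq)
  rev <- aln_score(revcomp(uniq))
  use_rev <- Biostrings::score(rev) > Biostrings::score(fwd)
  pick <- function(acc) {
    out <- acc(fwd)
    out[use_rev] <- acc(rev)[use_rev]
    out
  }
  # pattern()/subject() give the gapped alignment of the aligned range only;
  # terminal overhangs are recovered from the range bounds below.
  qa <- pick(function(a) as.character(Biostrings::pattern(a)))
  ra <- pick(function(a) as.character(Biostrings::subject(a)))
  qs <- pick(function(a) Biostrings::start(Biostrings::pattern(a)))
  qe <- pick(function(a) Biostrings::end(Biostrings::pattern(a)))
  ss <- pick(function(a) Biostrings::start(Biostrings::subject(a)))
  se <- pick(function(a) Biostrings::end(Biostrings::subject(a)))
  sc <- pick(Biostrings::score)
  oriented <- ifelse(use_rev, revcomp(uniq), uniq)
  reflen <- nchar(ref)
  edits <- lapply(seq_along(uniq), function(i) {
    ed <- edits_from_alignment(qa[[i]], ra[[i]])
    ed$ref_position <- ed$ref_position + (ss[[i]] - 1L)
    extra <- list()
    if (qs[[i]] > 1L) { # leading query overhang = insertion at the ref start
      extra[[length(extra) + 1L]] <- tibble(
        kind = "insertion", ref_position = ss[[i]] - 1L,
        length = qs[[i]] - 1L,
        sequence = substr(oriented[[i]], 1L, qs[[i]] - 1L))
    }
    if (ss[[i]] > 1L) {
      extra[[length(extra) + 1L]] <- tibble(
        kind = "deletion", ref_position = 0L, length = ss[[i]] - 1L,
        sequence = substr(ref, 1L, ss[[i]] - 1L))
    }
    if (qe[[i]] < nchar(oriented[[i]])) {
      extra[[length(extra) + 1L]] <- tibble(
        kind = "insertion", ref_position = se[[i]],
        length = nchar(oriented[[i]]) - qe[[i]],
        sequence = substr(oriented[[i]], qe[[i]] + 1L, nchar(oriented[[i]])))
    }
    if (se[[i]] < reflen) {
      extra[[length(extra) + 1L]] <- tibble(
        kind = "deletion", ref_position = se[[i]], length = reflen - se[[i]],
        sequence = substr(ref, se[[i]] + 1L, reflen))
    }
    ed <- bind_rows(c(list(ed), extra))
    normalize_edits(ed, ref)
  })
  tibble(
    read_id = reads$read_id %||% sprintf("read%05d", seq_along(seqs)),
    strand = ifelse(use_rev, "-", "+")[umap],
    score = unname(sc)[umap],
    profile = vapply(edits, profile_key, "")[umap],
    edits = edits[umap]
  )
}

#' Group aligned reads into variant haplotypes
#'
#' Reads are grouped by identical canonical edit profile. Sequencing errors
#' scatter reads into rare singleton profiles, which are absorbed by the
#' support threshold: a profile is kept when its support is at least
#' `max(min_reads, min_frac * aligned reads)`.
#'
#' @inheritParams align_reads
#' @param min_frac Minimum variant frequency (default 0.05).
#' @param min_reads Absolute support floor (default 3).
#' @return Tibble of haplotypes sorted by support: `haplotype_id`,
#'   `profile`, `edits` (list), `support_count`, `frequency`, `read_ids`
#'   (list).
#' @export
call_haplotypes <- function(reads, locus, min_frac = 0.05, min_reads = 3L) {
  aligned <- align_reads(reads, locus)
  n <- nrow(aligned)
  if (n == 0L) {
    warn("no aligned reads")
    return(tibble(haplotype_id = character(), profile = character(),
                  edits = list(), support_count = integer(),
                  frequency = double(), read_ids = list()))
  }
  grp <- aligned |>
    group_by(.data$profile) |>
    summarise(support_count = n(),
              edits = list(.data$edits[[1]]),
              read_ids = list(.data$read_id), .groups = "drop") |>
    mutate(frequency = .data$support_count / n) |>
    arrange(dplyr::desc(.data$support_count), .data$profile)
  thr <- max(min_reads, min_frac * n)
  grp <- grp[grp$support_count >= thr, , drop = FALSE]
  grp |>
    mutate(haplotype_id = sprintf("hap%02d", dplyr::row_number())) |>
    select("haplotype_id", "profile", "edits", "support_count",
           "frequency", "read_ids")
}

#' Detect transposon-like variant haplotypes
#'
#' Reads that carry a near-miss transposon junction -- matching one of the
#' junction patterns with 1 to `max_mismatch` substitutions but no exact
#' match -- are grouped by their mismatch profile. Such haplotypes still
#' carry a transposon-like insert plus SNPs; they are reported with an
#' `incomplete` flag because the junction window cannot characterize the
#' full element.
#'
#' @inheritParams classify_reads
#' @param max_mismatch Maximum substitutions tolerated in a junction
#'   pattern.
#' @return Tibble: `haplotype_id`, `pattern_index`, `profile` (mismatch
#'   offsets and bases within the junction pattern), `support_count`,
#'   `read_ids`, `te_like` (all `TRUE`), `incomplete` (all `TRUE`).
#' @export
detect_te_like <- function(reads, catalog, max_mismatch = 3L) {
  te <- te_allele_name(catalog)
  if (is.na(te)) abort("catalog has no te_insertion allele")
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read%05d", seq_along(reads)),
                    sequence = unname(reads))
  }
  reads <- as_tibble(reads)
  if (!"read_id" %in% names(reads)) {
    reads$read_id <- sprintf("read%05d", seq_len(nrow(reads)))
  }
  seqs <- check_dna(reads$sequence, "read sequence")
  pats <- catalog$patterns[[te]]
  hits <- list()
  for (pi in seq_along(pats)) {
    pat <- pats[[pi]]
    for (i in seq_along(seqs)) {
      for (s in c("+", "-")) {
        subj <- if (s == "+") seqs[[i]] else revcomp(seqs[[i]])
        if (grepl(pat, subj, fixed = TRUE)) next # exact: classifies as the TE allele
        m <- Biostrings::matchPattern(pat, Biostrings::DNAString(subj),
                                      max.mismatch = max_mismatch,
                                      with.indels = FALSE)
        if (length(m) == 0L) next
        # best window = fewest mismatches, then leftmost
        mm <- vapply(seq_along(m), function(j) {
          sum(strsplit(as.character(m[[j]]), "")[[1]] != strsplit(pat, "")[[1]])
        }, 0L)
        j <- order(mm, Biostrings::start(m))[1]
        win <- strsplit(as.character(m[[j]]), "")[[1]]
        patc <- strsplit(pat, "")[[1]]
        off <- which(win != patc)
        if (length(off) == 0L) next
        hits[[length(hits) + 1L]] <- tibble(
          read_id = reads$read_id[[i]],
          pattern_index = pi,
          profile = paste(sprintf("p%d%s>%s", off, patc[off], win[off]),
                          collapse = ";"))
        break # one orientation is enough
      }
    }
  }
  if (!length(hits)) {
    return(tibble(haplotype_id = character(), pattern_index = integer(),
                  profile = character(), support_count = integer(),
                  read_ids = list(), te_like = logical(),
                  incomplete = logical()))
  }
  bind_rows(hits) |>
    group_by(.data$pattern_index, .data$profile) |>
    summarise(support_count = n(), read_ids = list(.data$read_id),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$support_count), .data$profile) |>
    mutate(haplotype_id = sprintf("telike%02d", dplyr::row_number()),
           te_like = TRUE, incomplete = TRUE) |>
    select("haplotype_id", "pattern_index", "profile", "support_count",
           "read_ids", "te_like", "incomplete")
}

#' Edit distance between a footprint insertion and the TSD motif
#'
#' Excision footprints resemble modified copies of the target-site
#' duplication; their Levenshtein distance from the TSD motif is a
#' compatibility score (the published footprints all sit at distance 1).
#'
#' @param insertion_seq,tsd_motif Non-empty DNA strings.
#' @return Integer Levenshtein distance.
#' @examples
#' tsd_similarity("CCACTAG", "ACACTAG")
#' @export
tsd_similarity <- function(insertion_seq, tsd_motif) {
  insertion_seq <- check_dna(insertion_seq, "insertion_seq")
  tsd_motif <- check_dna(tsd_motif, "tsd_motif")
  as.integer(adist(insertion_seq, tsd_motif))
}

#' Classify a variant haplotype as a known or novel allele
#'
#' Reconstructs the haplotype sequence from its edits; if it reproduces a
#' catalog allele's assembled sequence the haplotype is that allele
#' (`known_match`). Otherwise it receives the next unused integer-suffix
#' name in the allele series. A haplotype is `footprint_compatible` when it
#' is a single insertion whose (right-normalized) breakpoint is the
#' canonical insertion site, or a deletion overlapping the TSD motif.
#'
#' @param h One haplotype row from [call_haplotypes()] (or a list with an
#'   `edits` tibble).
#' @param catalog An [allele_catalog()].
#' @param locus A [locus_model()]; defaults to `catalog$locus`.
#' @param used_names Extra names already taken in the series (beyond the
#'   catalog), e.g. from previously named novel alleles.
#' @return One-row tibble: `assigned_name`, `known_match`,
#'   `footprint_compatible`, `tsd_edit_distance`, `te_like`, `n_edits`,
#'   `sequence`.
#' @export
classify_novel <- function(h, catalog, locus = NULL, used_names = NULL) {
  locus <- locus %||% catalog$locus
  edits <- if (is.data.frame(h)) h$edits[[1]] else h$edits
  if (is.null(edits)) abort("haplotype must carry an edits table")
  seqs <- allele_sequences(catalog)
  reconstructed <- apply_edits(locus$variable_region, edits)
  known <- names(seqs)[seqs == reconstructed]
  site <- locus$insertion_site
  tsd_len <- nchar(locus$tsd_motif)
  ins <- edits[edits$kind == "insertion", , drop = FALSE]
  del <- edits[edits$kind == "deletion", , drop = FALSE]
  region <- locus$variable_region
  # single insertion whose placement is equivalent to a breakpoint at the
  # canonical site (indel placement in repeat context is ambiguous, so the
  # reconstructed sequence is compared around the site rather than the
  # normalized coordinate alone)
  fp_ins <- nrow(ins) == 1L && nrow(edits) == 1L &&
    substr(reconstructed, 1L, site) == substr(region, 1L, site) &&
    substr(reconstructed, site + ins$length[1] + 1L, nchar(reconstructed)) ==
      substr(region, site + 1L, nchar(region))
  fp_del <- nrow(del) >= 1L &&
    any(del$ref_position < site + 1L & del$ref_position + del$length >= site - tsd_len)
  tsd_dist <- if (nrow(ins) == 1L) tsd_similarity(ins$sequence[1], locus$tsd_motif)
    else NA_integer_
  if (length(known)) {
    name <- known[[1]]
  } else {
    taken <- c(names(catalog$alleles), used_names)
    suffix <- suppressWarnings(as.integer(sub("^.*\\.([0-9]+)[a-z]?$", "\\1", taken)))
    nxt <- max(suffix, na.rm = TRUE) + 1L
    name <- sprintf("%s.%d", locus$locus_id, nxt)
    while (name %in% taken) {
      nxt <- nxt + 1L
      name <- sprintf("%s.%d", locus$locus_id, nxt)
    }
  }
  tibble(
    assigned_name = name,
    known_match = if (length(known)) known[[1]] else NA_character_,
    footprint_compatible = fp_ins || fp_del,
    tsd_edit_distance = tsd_dist,
    te_like = FALSE,
    n_edits = nrow(edits),
    sequence = reconstructed
  )
}

#' Classify every haplotype of a sample
#'
#' Runs [classify_novel()] over a haplotype table, assigning fresh series
#' names sequentially to unknown haplotypes.
#'
#' @param haplotypes Output of [call_haplotypes()].
#' @inheritParams classify_novel
#' @return Tibble with one row per haplotype: the haplotype columns plus the
#'   [classify_novel()] columns.
#' @export
discover_alleles <- function(haplotypes, catalog, locus = NULL) {
  locus <- locus %||% catalog$locus
  used <- character()
  out <- vector("list", nrow(haplotypes))
  for (i in seq_len(nrow(haplotypes))) {
    cls <- classify_novel(haplotypes[i, ], catalog, locus, used_names = used)
    if (is.na(cls$known_match)) used <- c(used, cls$assigned_name)
    out[[i]] <- dplyr::bind_cols(
      haplotypes[i, c("haplotype_id", "profile", "support_count", "frequency")],
      cls)
  }
  bind_rows(out)
}
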