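# Independent brute-force oracles used to validate the implementation.
# Each oracle is deliberately naive and shares no code with the package
# internals it checks.

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

rc_chr <- function(s) {
  chartr("ACGT", "TGCA", vapply(strsplit(s, ""), function(x)
    paste(rev(x), collapse = ""), ""))
}

# Longest common substring by enumeration of all start pairs.
oracle_lcs <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  best <- 0L
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      k <- 0L
      while (i + k <= na && j + k <= nb &&
             substr(a, i + k, i + k) == substr(b, j + k, j + k)) {
        k <- k + 1L
      }
      best <- max(best, k)
    }
  }
  best
}

# Levenshtein distance by the textbook DP recursion.
oracle_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(x) + 1L, length(y) + 1L)
  d[, 1] <- 0:length(x); d[1, ] <- 0:length(y)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[length(x) + 1L, length(y) + 1L]
}

# Naive classifier: exact substring search of every pattern against the read
# and its reverse complement; unique allele or nothing.
oracle_classify <- function(seqs, catalog) {
  vapply(seqs, function(s) {
    rs <- rc_chr(s)
    hit <- vapply(names(catalog$alleles), function(a) {
      any(vapply(catalog$patterns[[a]], function(p) {
        grepl(p, s, fixed = TRUE) || grepl(p, rs, fixed = TRUE)
      }, TRUE))
    }, TRUE)
    if (sum(hit) == 1L) names(hit)[hit] else NA_character_
  }, "", USE.NAMES = FALSE)
}

# Global affine-gap alignment score (match +2, mismatch -3, gap of length k
# costs 5 + 2k), quadratic DP with three state matrices.
oracle_align_score <- function(q, r, match = 2, mismatch = -3,
                               gap_open = 5, gap_extend = 2) {
  x <- strsplit(q, "")[[1]]; y <- strsplit(r, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -gap_open - gap_extend * i
  for (j in seq_len(m)) Iy[1, j + 1] <- -gap_open - gap_extend * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                              Ix[i, j + 1] - gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                              Iy[i + 1, j] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Multiset symmetric difference size via explicit counting.
oracle_symdiff <- function(a, b) {
  all_tok <- union(a, b)
  as.integer(sum(vapply(all_tok, function(t) abs(sum(a == t) - sum(b == t)), 0)))
}

# Pairwise mismatch distances straight from a wide call table.
oracle_mismatch_matrix <- function(calls) {
  acols <- grep("^allele_", names(calls), value = TRUE)
  samples <- unique(calls$sample)
  d <- matrix(0L, length(samples), length(samples),
              dimnames = list(samples, samples))
  for (i in seq_along(samples)) {
    for (j in seq_along(samples)) {
      if (i >= j) next
      tot <- 0L
      for (loc in unique(calls$locus)) {
        a <- unlist(calls[calls$sample == samples[i] & calls$locus == loc, acols])
        b <- unlist(calls[calls$sample == samples[j] & calls$locus == loc, acols])
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (!length(a) || !length(b)) next
        tot <- tot + oracle_symdiff(a, b)
      }
      d[i, j] <- d[j, i] <- tot
    }
  }
  d
}

# Naive agglomerative complete linkage: returns sorted merge heights.
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); besth <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < besth) { besth <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, besth)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Partition of samples obtained by cutting complete-linkage merges at h:
# transitive closure of "complete-linkage mergeable at height <= h".
partition_at <- function(hc, h) {
  stats::cutree(hc, h = h)
}

# The frozen diagnostic strings of the packaged catalog (one per allele;
# two junction patterns for the transposon allele).
table1_patterns <- list(
  StCDF1.1 = "CTAAAAGCTCTATATGGTCAACACTAGGTATCAGGAATGAGAAGATTGA",
  StCDF1.2a = "CTAAAAGCTCTATATGGTCAACACTAGCCACTAGGTATCAGGAATGAGAAGATTGA",
  StCDF1.2b = "CTAAAAGCTCTATATGGTCAACACTAGTCACTAGGTATCAGGAATGAGAAGATTGA",
  StCDF1.7 = "CTAAAAGCTCTATATGGTCAACACTAGCACTAGGTATCAGGAATGAGAAGATTGA",
  StCDF1.3 = c("CTAAAAGCTCTATATGGTCAACACTAGGTAAGGCTGGGCACCGGACCGGAATGG",
               "ACCCGTTCCGGTGCCCAGCCTTAACACTAGGTATCAGGAATGAGAAGATTGA")
)
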