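# Independent brute-force oracles. These share no code with the package
# internals: IUPAC matching, pattern scanning, off-target distance and
# alignment scoring are all re-derived from first principles here.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(x) {
  chartr_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(chartr_map[strsplit(x, "")[[1]]])), collapse = "")
}

# does seq (chars) match IUPAC pattern (chars) position by position?
oracle_pattern_match <- function(seq_chars, pat_chars) {
  if (length(seq_chars) != length(pat_chars)) return(FALSE)
  for (k in seq_along(pat_chars)) {
    if (!(seq_chars[k] %in% ORACLE_IUPAC[[pat_chars[k]]])) return(FALSE)
  }
  TRUE
}

# brute-force scan of one forward-strand sequence for the overlap
# pattern TTTV + N{s9} + NGG on both strands; returns forward-axis loci
oracle_scan_overlaps <- function(seq, cas12a_pam = "TTTV",
                                 cas9_pam = "NGG", s9 = 20L) {
  slen <- nchar(cas12a_pam) + s9 + nchar(cas9_pam)
  pat <- strsplit(paste0(cas12a_pam, strrep("N", s9), cas9_pam), "")[[1]]
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    chars <- strsplit(s, "")[[1]]
    for (i in 0:(n - slen)) {
      if (oracle_pattern_match(chars[(i + 1):(i + slen)], pat)) {
        start <- if (strand == "+") i else n - i - slen
        out[[length(out) + 1L]] <-
          data.frame(start = start, end = start + slen, strand = strand,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  o <- do.call(rbind, out)
  o[order(o$start, o$strand), , drop = FALSE]
}

# minimal mismatch count of spacer vs window over all single-gap
# placements (or none); returns list(n_mm, bulge) or NULL if > max_mm
oracle_distance <- function(spacer, window, max_mm) {
  a <- strsplit(spacer, "")[[1]]
  b <- strsplit(window, "")[[1]]
  neq <- function(x, y) x != y | x == "N" | y == "N"
  d <- length(b) - length(a)
  if (d == 0L) {
    mm <- sum(neq(a, b))
    if (mm > max_mm) return(NULL)
    return(list(n_mm = mm, bulge = "none"))
  }
  if (d == -1L) { long <- a; short <- b; type <- "rna" }
  else if (d == 1L) { long <- b; short <- a; type <- "dna" }
  else stop("bad window length")
  best <- Inf
  for (j in seq_along(long)) {
    mm <- sum(neq(long[-j], short))
    if (mm < best) best <- mm
  }
  if (best > max_mm) return(NULL)
  list(n_mm = best, bulge = type)
}

# exhaustive window scan: every PAM-adjacent window of each admissible
# length on both strands; returns (start, end, strand, n_mm, bulge)
oracle_offtargets <- function(genome, spacer, pam, pam_side, max_mm,
                              max_bulge) {
  L <- nchar(spacer)
  plen <- nchar(pam)
  pat <- strsplit(pam, "")[[1]]
  lens <- if (max_bulge >= 1L) c(L - 1L, L, L + 1L) else L
  out <- list()
  for (chrom in names(genome)) {
    n <- nchar(genome[[chrom]])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") genome[[chrom]] else
        oracle_revcomp(genome[[chrom]])
      chars <- strsplit(s, "")[[1]]
      for (p in 0:(n - plen)) {
        if (!oracle_pattern_match(chars[(p + 1):(p + plen)], pat)) next
        for (l in lens) {
          if (pam_side == "3prime") { a <- p - l; b <- p }
          else { a <- p + plen; b <- p + plen + l }
          if (a < 0L || b > n) next
          dd <- oracle_distance(spacer,
                                paste(chars[(a + 1):b], collapse = ""),
                                max_mm)
          if (is.null(dd)) next
          fwd <- if (strand == "+") c(a, b) else c(n - b, n - a)
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = fwd[1], end = fwd[2],
            strand = strand, n_mismatches = dd$n_mm, bulge = dd$bulge,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_mismatches = integer(), bulge = character(),
                      stringsAsFactors = FALSE))
  o <- do.call(rbind, out)
  o <- o[order(o$chrom, o$start, o$end, o$strand, o$bulge), ,
         drop = FALSE]
  rownames(o) <- NULL
  o
}

# plain-R global affine-gap DP, score only; gap length k costs
# open + (k-1) * extend
oracle_align_score <- function(read, ref, match = 2, mismatch = -4,
                               gap_open = -6, gap_extend = -1) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e15
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in read row (ref consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in ref row (read consumed)
  M[1, 1] <- 0
  for (j in 2:(m + 1)) X[1, j] <- gap_open + (j - 2) * gap_extend
  for (i in 2:(n + 1)) Y[i, 1] <- gap_open + (i - 2) * gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i, j - 1] + gap_open, X[i, j - 1] + gap_extend,
                     Y[i, j - 1] + gap_open)
      Y[i, j] <- max(M[i - 1, j] + gap_open, Y[i - 1, j] + gap_extend,
                     X[i - 1, j] + gap_open)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# default off-target configurations used by planted-genome fixtures
default_ot_configs <- function() {
  list(
    list(site = 1L, nuclease = "cas12a", n_mismatches = 2L,
         mismatch_positions = c(18L, 23L), bulge = "none"),
    list(site = 1L, nuclease = "cas9", n_mismatches = 1L,
         mismatch_positions = 5L, bulge = "none"),
    list(site = 2L, nuclease = "cas12a", n_mismatches = 0L,
         mismatch_positions = integer(0), bulge = "dna",
         bulge_position = 10L),
    list(site = 2L, nuclease = "cas9", n_mismatches = 1L,
         mismatch_positions = 8L, bulge = "rna", bulge_position = 15L)
  )
}
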