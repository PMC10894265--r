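# Cas-OFFinder-style enumeration of candidate off-target sites: every
# PAM-matching window whose protospacer-like sequence is within a bounded
# number of mismatches of the spacer, allowing at most one one-nucleotide
# DNA bulge (extra genomic base) or RNA bulge (extra guide base).
# Mismatch counting excludes the PAM; the PAM must match its IUPAC
# pattern exactly. Positions are numbered 1 at the PAM-proximal end of
# the spacer for both nucleases.

#' Query spacer for off-target search
#'
#' @param nuclease `"cas9"` or `"cas12a"`.
#' @param spacer Protospacer sequence, 5' to 3' (20 nt for Cas9, 23 nt
#'   for Cas12a).
#' @param id Query identifier carried into hit tables.
#' @param pam IUPAC PAM pattern; defaults to `NGG` (Cas9) or `TTTV`
#'   (Cas12a).
#' @return A list of class `query_spacer` with fields `nuclease`,
#'   `spacer`, `pam`, `pam_side`, `id`.
#' @export
query_spacer <- function(nuclease = c("cas9", "cas12a"), spacer,
                         id = "query", pam = NULL) {
  nuclease <- match.arg(nuclease)
  spacer <- toupper(spacer)
  expected_len <- if (nuclease == "cas9") 20L else 23L
  if (nchar(spacer) != expected_len)
    stop(nuclease, " spacer must be ", expected_len, " nt")
  if (grepl("[^ACGT]", spacer)) stop("spacer must be over {A,C,G,T}")
  if (is.null(pam)) pam <- if (nuclease == "cas9") "NGG" else "TTTV"
  pam_side <- if (nuclease == "cas9") "3prime" else "5prime"
  structure(list(nuclease = nuclease, spacer = spacer, pam = pam,
                 pam_side = pam_side, id = id),
            class = "query_spacer")
}

# vectorized base inequality; N matches nothing, including N
.base_neq <- function(a, b) a != b | a == "N" | b == "N"

# PAM-proximal position number of spacer index i (1-based along 5'->3')
.pp_pos <- function(i, spacer_len, pam_side) {
  if (pam_side == "5prime") i else spacer_len - i + 1L
}

#' Mismatch/bulge distance between a spacer and a candidate site
#'
#' Equal lengths are compared positionally. A length difference of one
#' is resolved by the single best gap placement: the placement with the
#' fewest mismatches, ties broken by the most PAM-proximal gap. An extra
#' genomic base is a DNA bulge; a skipped (unpaired) guide base is an
#' RNA bulge. Mismatch and bulge positions are numbered with 1 at the
#' PAM-proximal end of the spacer.
#'
#' @param spacer Spacer sequence (no PAM).
#' @param site_seq Candidate genomic sequence, same orientation, of
#'   length `|spacer| - 1`, `|spacer|`, or `|spacer| + 1`.
#' @param pam_side `"5prime"` or `"3prime"` (PAM location relative to
#'   the protospacer).
#' @param max_mm Maximum number of mismatches; more returns `NULL`.
#' @return `NULL` (no match) or a list with `n_mismatches`,
#'   `mismatch_positions` (sorted integer vector), `bulge` (`"none"`,
#'   `"dna"`, `"rna"`), `bulge_position` (`NA` when no bulge).
#' @export
hit_distance <- function(spacer, site_seq, pam_side = c("3prime", "5prime"),
                         max_mm = 3L) {
  pam_side <- match.arg(pam_side)
  L <- nchar(spacer)
  d <- nchar(site_seq) - L
  if (abs(d) > 1L) stop("site length must be within 1 of spacer length")
  a <- strsplit(spacer, "")[[1]]
  b <- strsplit(site_seq, "")[[1]]

  if (d == 0L) {
    mm_idx <- which(.base_neq(a, b))
    if (length(mm_idx) > max_mm) return(NULL)
    return(list(n_mismatches = length(mm_idx),
                mismatch_positions =
                  sort(.pp_pos(mm_idx, L, pam_side)),
                bulge = "none", bulge_position = NA_integer_))
  }

  if (d == -1L) {
    # RNA bulge: one spacer base unpaired; gap placed at spacer index j
    long <- a; short <- b; bulge <- "rna"
  } else {
    # DNA bulge: one extra site base; gap placed at site index j
    long <- b; short <- a; bulge <- "dna"
  }
  nl <- length(long)
  # mm(j) = mismatches when long[j] is skipped:
  #   prefix: long[i] vs short[i] for i < j; suffix: long[i] vs short[i-1]
  pre <- c(0L, cumsum(.base_neq(long[seq_len(nl - 1L)], short)))
  suf_terms <- .base_neq(long[2L:nl], short)
  suf <- c(rev(cumsum(rev(suf_terms))), 0L)
  mm <- pre + suf  # length nl, entry j = gap at long index j
  best_mm <- min(mm)
  if (best_mm > max_mm) return(NULL)
  cand <- which(mm == best_mm)
  # bulge slot in spacer coordinates: the gap interrupts the spacer
  # before/at index min(j, L); tie-break = most PAM-proximal slot
  slot <- pmin(cand, L)
  ppos <- .pp_pos(slot, L, pam_side)
  j <- cand[which.min(ppos)]
  bulge_position <- .pp_pos(min(j, L), L, pam_side)
  # mismatch indices in spacer coordinates for the chosen placement
  if (d == -1L) {
    # long = spacer; spacer index i pairs short[i] (i<j) or short[i-1]
    idx <- setdiff(seq_len(nl), j)
    partner <- ifelse(idx < j, idx, idx - 1L)
    mm_spacer_idx <- idx[.base_neq(a[idx], b[partner])]
  } else {
    # long = site; spacer index i pairs site[i] (i<j) or site[i+1]
    idx <- seq_len(L)
    partner <- ifelse(idx < j, idx, idx + 1L)
    mm_spacer_idx <- idx[.base_neq(a[idx], b[partner])]
  }
  list(n_mismatches = best_mm,
       mismatch_positions = sort(.pp_pos(mm_spacer_idx, L, pam_side)),
       bulge = bulge, bulge_position = as.integer(bulge_position))
}

empty_hits <- function() {
  data.frame(query_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             site_seq = character(), pam_seq = character(),
             n_mismatches = integer(), mismatch_positions = character(),
             bulge = character(), bulge_position = integer(),
             stringsAsFactors = FALSE)
}

#' Enumerate candidate off-target sites genome-wide
#'
#' Scans both strands of every chromosome. A candidate is any window
#' adjacent (on the correct side) to an exact IUPAC PAM match, of length
#' `|spacer|` or, when `max_bulge >= 1`, `|spacer| - 1` or
#' `|spacer| + 1`. The on-target locus itself appears as a 0-mismatch
#' hit. Coordinates (`start`, `end`) span the protospacer-like window on
#' the forward axis; the PAM is reported separately.
#'
#' @param genome Named character vector from [read_fasta()].
#' @param query A [query_spacer()].
#' @param max_mm Maximum mismatches (PAM excluded), default 3.
#' @param max_bulge Maximum bulge size in nt, 0 or 1.
#' @return Hit `data.frame` (see [empty_hits()] columns), with
#'   `mismatch_positions` comma-joined, sorted by `(n_mismatches,
#'   bulge != "none", chrom, start)`.
#' @export
enumerate_offtargets <- function(genome, query, max_mm = 3L,
                                 max_bulge = 1L) {
  stopifnot(inherits(query, "query_spacer"), max_bulge %in% c(0L, 1L))
  L <- nchar(query$spacer)
  plen <- nchar(query$pam)
  lens <- if (max_bulge >= 1L) c(L - 1L, L, L + 1L) else L
  pam_re <- paste0("(?=", iupac_regex(query$pam), ")")
  rows <- list()
  for (chrom in names(genome)) {
    n <- nchar(genome[[chrom]])
    for (strand in c("+", "-")) {
      S <- if (strand == "+") genome[[chrom]] else revcomp(genome[[chrom]])
      m <- gregexpr(pam_re, S, perl = TRUE)[[1]]
      pam_pos <- as.integer(m)
      if (length(pam_pos) == 1L && pam_pos == -1L) next
      pam_pos <- pam_pos - 1L  # 0-based
      pam_pos <- pam_pos[pam_pos + plen <= n]
      for (p in pam_pos) {
        pam_seq <- substr(S, p + 1L, p + plen)
        for (l in lens) {
          if (query$pam_side == "3prime") {
            a <- p - l; b <- p
          } else {
            a <- p + plen; b <- p + plen + l
          }
          if (a < 0L || b > n) next
          site_seq <- substr(S, a + 1L, b)
          hd <- hit_distance(query$spacer, site_seq, query$pam_side,
                             max_mm = max_mm)
          if (is.null(hd)) next
          fwd <- if (strand == "+") c(a, b) else c(n - b, n - a)
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = query$id, chrom = chrom,
            start = fwd[1], end = fwd[2], strand = strand,
            site_seq = site_seq, pam_seq = pam_seq,
            n_mismatches = hd$n_mismatches,
            mismatch_positions = paste(hd$mismatch_positions,
                                       collapse = ","),
            bulge = hd$bulge, bulge_position = hd$bulge_position,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(empty_hits())
  hits <- do.call(rbind, rows)
  ord <- order(hits$n_mismatches, hits$bulge != "none", hits$chrom,
               hits$start, hits$strand)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

parse_mm_positions <- function(x) {
  lapply(strsplit(x, ","), function(v) as.integer(v[nzchar(v)]))
}

#' Histogram of mismatch positions along the spacer
#'
#' @param hits Hit table from [enumerate_offtargets()] (one nuclease).
#' @param spacer_len Spacer length (number of bins).
#' @return Integer vector of counts named `1..spacer_len` (position 1 =
#'   PAM-proximal); sums to the total mismatch count.
#' @export
mismatch_position_histogram <- function(hits, spacer_len) {
  counts <- integer(spacer_len)
  names(counts) <- as.character(seq_len(spacer_len))
  pos <- unlist(parse_mm_positions(hits$mismatch_positions))
  if (length(pos)) {
    if (any(pos < 1L | pos > spacer_len))
      stop("mismatch position outside 1..spacer_len")
    t <- table(pos)
    counts[names(t)] <- as.integer(t)
  }
  counts
}

#' Select a balanced panel of off-target sites
#'
#' Greedy maximum-coverage selection of up to `k` hits spreading
#' mismatches as evenly as possible over the spacer: each step picks the
#' hit covering the most previously uncovered mismatch positions, ties
#' broken by fewer mismatches, then genomic order (`chrom`, `start`,
#' `strand`). Deterministic.
#'
#' @param hits Hit table from [enumerate_offtargets()].
#' @param k Maximum number of hits to select.
#' @param drop_on_target Drop 0-mismatch, bulge-free hits (the on-target
#'   locus) before selecting. Default `TRUE`.
#' @return Subset of `hits`, in selection order.
#' @export
select_balanced_offtargets <- function(hits, k = 4L,
                                       drop_on_target = TRUE) {
  if (drop_on_target)
    hits <- hits[hits$n_mismatches > 0L | hits$bulge != "none", ,
                 drop = FALSE]
  if (nrow(hits) <= k) {
    rownames(hits) <- NULL
    return(hits)
  }
  pos_sets <- parse_mm_positions(hits$mismatch_positions)
  covered <- integer(0)
  chosen <- integer(0)
  remaining <- seq_len(nrow(hits))
  while (length(chosen) < k && length(remaining)) {
    gain <- vapply(remaining, function(i)
      length(setdiff(pos_sets[[i]], covered)), integer(1))
    best_gain <- max(gain)
    cand <- remaining[gain == best_gain]
    cand <- cand[order(hits$n_mismatches[cand], hits$chrom[cand],
                       hits$start[cand], hits$strand[cand])]
    pick <- cand[1]
    chosen <- c(chosen, pick)
    covered <- union(covered, pos_sets[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  out <- hits[chosen, , drop = FALSE]
  rownames(out) <- NULL
  out
}
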