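# Amplicon-sequencing indel caller: merge read pairs, align each merged
# read globally to the reference amplicon (affine gaps, left-aligned
# indels), call a read edited when an indel overlaps the expected cut
# window, and mask events also present in a mock-transfected control.
# Substitutions never mark a read edited: isolated base changes are
# attributed to PCR/sequencing error.

DEFAULT_ALN_SCORES <- list(match = 2, mismatch = -4,
                           gap_open = -6, gap_extend = -1)

#' Amplicon specification
#'
#' @param amplicon_id Identifier.
#' @param ref_seq Reference amplicon sequence.
#' @param guide_start,guide_end 0-based half-open span of the
#'   protospacer within `ref_seq`.
#' @param nuclease `"cas9"` or `"cas12a"`.
#' @param strand_of_guide Strand of the protospacer on the amplicon.
#' @return A list of class `amplicon_spec`.
#' @export
amplicon_spec <- function(amplicon_id, ref_seq, guide_start, guide_end,
                          nuclease = c("cas9", "cas12a"),
                          strand_of_guide = "+") {
  nuclease <- match.arg(nuclease)
  ref_seq <- toupper(ref_seq)
  guide_start <- as.integer(guide_start); guide_end <- as.integer(guide_end)
  if (guide_start < 0L || guide_end > nchar(ref_seq) ||
      guide_start >= guide_end)
    stop("guide interval outside amplicon")
  glen <- guide_end - guide_start
  expected <- if (nuclease == "cas9") 20L else 23L
  if (glen != expected)
    stop("guide length ", glen, " does not match ", nuclease,
         " spacer length ", expected)
  if (!strand_of_guide %in% c("+", "-")) stop("invalid strand")
  structure(list(amplicon_id = amplicon_id, ref_seq = ref_seq,
                 guide_start = guide_start, guide_end = guide_end,
                 nuclease = nuclease, strand_of_guide = strand_of_guide),
            class = "amplicon_spec")
}

#' Read an amplicon specification table (TSV)
#'
#' Columns: `amplicon_id`, `ref_seq`, `guide_start`, `guide_end`,
#' `strand`, `nuclease`.
#'
#' @param path Path to the TSV file.
#' @return List of [amplicon_spec()] objects, named by id.
#' @export
read_amplicon_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(tab)), function(i)
    amplicon_spec(tab$amplicon_id[i], tab$ref_seq[i], tab$guide_start[i],
                  tab$guide_end[i], tab$nuclease[i], tab$strand[i]))
  names(specs) <- tab$amplicon_id
  specs
}

#' Merge one paired-end read
#'
#' `r2` is given in sequencing orientation and reverse-complemented
#' internally. Among candidate overlaps of at least `min_overlap` nt
#' whose mismatch fraction is within `max_overlap_mismatch_frac`, the
#' one with the lowest mismatch fraction (ties: longest) is used.
#' Disagreeing overlap bases are resolved toward the higher base
#' quality; ties go to `r1`.
#'
#' @param r1,r2 Read sequences.
#' @param q1,q2 Optional phred+33 quality strings (same lengths).
#' @param min_overlap Minimum overlap in nt.
#' @param max_overlap_mismatch_frac Maximum allowed mismatch fraction in
#'   the overlap.
#' @return `list(seq=, qual=)` or `NULL` when no acceptable overlap
#'   exists (the pair is discarded).
#' @export
merge_read_pair <- function(r1, r2, q1 = NULL, q2 = NULL,
                            min_overlap = 20L,
                            max_overlap_mismatch_frac = 0.1) {
  b <- revcomp(r2)
  qb <- if (!is.null(q2)) paste(rev(strsplit(q2, "")[[1]]), collapse = "")
        else NULL
  cand <- cpp_overlap_scan(r1, b, as.integer(min_overlap))
  if (nrow(cand) == 0L) return(NULL)
  frac <- cand[, 2] / cand[, 1]
  ok <- frac <= max_overlap_mismatch_frac
  if (!any(ok)) return(NULL)
  cand <- cand[ok, , drop = FALSE]; frac <- frac[ok]
  best <- which(frac == min(frac))
  best <- best[which.max(cand[best, 1])]
  L <- cand[best, 1]
  n1 <- nchar(r1); n2 <- nchar(b)
  v1 <- strsplit(r1, "")[[1]]; v2 <- strsplit(b, "")[[1]]
  o1 <- v1[(n1 - L + 1L):n1]; o2 <- v2[seq_len(L)]
  if (is.null(q1)) p1 <- rep(30L, n1) else
    p1 <- utf8ToInt(q1) - 33L
  if (is.null(qb)) p2 <- rep(30L, n2) else
    p2 <- utf8ToInt(qb) - 33L
  oq1 <- p1[(n1 - L + 1L):n1]; oq2 <- p2[seq_len(L)]
  cons <- ifelse(o1 == o2, o1, ifelse(oq2 > oq1, o2, o1))
  consq <- pmax(oq1, oq2)
  seq <- paste0(substr(r1, 1L, n1 - L),
                paste(cons, collapse = ""),
                substr(b, L + 1L, n2))
  tailq <- if (L < n2) p2[(L + 1L):n2] else integer(0)
  qual <- intToUtf8(c(p1[seq_len(n1 - L)], consq, tailq) + 33L)
  list(seq = seq, qual = qual)
}

#' Merge a set of read pairs
#'
#' @param r1,r2 Character vectors of read sequences (paired by index).
#' @param q1,q2 Optional character vectors of quality strings.
#' @inheritParams merge_read_pair
#' @return `list(seqs=, quals=, n_failed=)`; failed pairs are dropped
#'   and counted.
#' @export
merge_read_pairs <- function(r1, r2, q1 = NULL, q2 = NULL,
                             min_overlap = 20L,
                             max_overlap_mismatch_frac = 0.1) {
  stopifnot(length(r1) == length(r2))
  seqs <- character(0); quals <- character(0); n_failed <- 0L
  for (i in seq_along(r1)) {
    m <- merge_read_pair(r1[i], r2[i],
                         if (is.null(q1)) NULL else q1[i],
                         if (is.null(q2)) NULL else q2[i],
                         min_overlap, max_overlap_mismatch_frac)
    if (is.null(m)) n_failed <- n_failed + 1L
    else { seqs <- c(seqs, m$seq); quals <- c(quals, m$qual) }
  }
  list(seqs = seqs, quals = quals, n_failed = n_failed)
}

#' Global affine-gap alignment of a read to the reference amplicon
#'
#' Needleman-Wunsch with affine gaps (a gap of length k scores
#' `gap_open + (k-1) * gap_extend`). Traceback is deterministic:
#' diagonal preferred, then gap in the reference row, then gap in the
#' read row. Indel events extracted downstream are left-aligned on the
#' reference.
#'
#' @param read_seq,ref_seq DNA strings.
#' @param scores Named list with `match`, `mismatch`, `gap_open`,
#'   `gap_extend`.
#' @return `list(score=, read_aln=, ref_aln=)` (aligned strings with
#'   `-` gaps).
#' @export
align_to_amplicon <- function(read_seq, ref_seq,
                              scores = DEFAULT_ALN_SCORES) {
  if (!nchar(read_seq) || !nchar(ref_seq))
    stop("empty sequence in alignment")
  cpp_affine_align(read_seq, ref_seq, scores$match, scores$mismatch,
                   scores$gap_open, scores$gap_extend)
}

# Left-align one event against the reference (VCF-style normalization).
left_align_event <- function(kind, position, size, inserted_seq, ref) {
  rv <- strsplit(ref, "")[[1]]
  if (kind == "deletion") {
    s <- position
    while (s > 0L && rv[s] == rv[s + size]) s <- s - 1L
    list(position = s, inserted_seq = "")
  } else {
    p <- position
    t <- strsplit(inserted_seq, "")[[1]]
    k <- length(t)
    while (p > 0L && t[k] == rv[p]) {
      t <- c(t[k], t[seq_len(k - 1L)])
      p <- p - 1L
    }
    list(position = p, inserted_seq = paste(t, collapse = ""))
  }
}

# Extract left-aligned indel events and per-column stats from one
# alignment. Returns list(events=data.frame, n_match, n_aln_cols,
# ref_cols = per-ref-position read base or NA).
alignment_events <- function(alignment, ref_seq) {
  rd <- strsplit(alignment$read_aln, "")[[1]]
  rf <- strsplit(alignment$ref_aln, "")[[1]]
  ref_consumed <- cumsum(rf != "-")      # ref chars consumed through col
  both <- rd != "-" & rf != "-"
  n_match <- sum(both & rd == rf)
  n_both <- sum(both)
  events <- list()
  # deletions: runs of '-' in the read row
  r <- rle(rd == "-")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    pos <- ref_consumed[starts[i]] - 1L  # 0-based ref start of deletion
    size <- r$lengths[i]
    la <- left_align_event("deletion", pos, size, "", ref_seq)
    events[[length(events) + 1L]] <- data.frame(
      kind = "deletion", size = size, position = la$position,
      inserted_seq = "", stringsAsFactors = FALSE)
  }
  # insertions: runs of '-' in the ref row
  r <- rle(rf == "-")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    pos <- ref_consumed[starts[i]]       # 0-based anchor (ref bases before)
    ins <- paste(rd[starts[i]:ends[i]], collapse = "")
    la <- left_align_event("insertion", pos, r$lengths[i], ins, ref_seq)
    events[[length(events) + 1L]] <- data.frame(
      kind = "insertion", size = r$lengths[i], position = la$position,
      inserted_seq = la$inserted_seq, stringsAsFactors = FALSE)
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(), size = integer(), position = integer(),
               inserted_seq = character(), stringsAsFactors = FALSE)
  # read base per reference position (NA under deletions)
  keep <- rf != "-"
  ref_cols <- ifelse(rd[keep] == "-", NA_character_, rd[keep])
  list(events = ev, n_match = n_match, n_both = n_both,
       ref_cols = ref_cols)
}

#' Cut window for an amplicon
#'
#' Cas9 cleaves bluntly between protospacer positions 17 and 18 (3 nt
#' PAM-proximal of the 3' NGG); Cas12a cuts in a staggered fashion
#' across protospacer positions 18-23, distal from its 5' PAM. The core
#' window (position 18 for Cas9; positions 18-23 for Cas12a) is expanded
#' by `flank` on both sides and clipped to the amplicon.
#'
#' @param spec An [amplicon_spec()].
#' @param flank Flank in nt added to each side of the core window.
#' @return `list(start=, end=)`, 0-based half-open in `ref_seq`
#'   coordinates.
#' @export
cut_window_for <- function(spec, flank = 5L) {
  gs <- spec$guide_start; ge <- spec$guide_end
  core <- if (spec$nuclease == "cas9") c(18L, 18L) else c(18L, 23L)
  if (spec$strand_of_guide == "+") {
    w <- c(gs + core[1] - 1L, gs + core[2])
  } else {
    w <- c(ge - core[2], ge - core[1] + 1L)
  }
  w <- c(w[1] - flank, w[2] + flank)
  w[1] <- max(0L, w[1]); w[2] <- min(nchar(spec$ref_seq), w[2])
  list(start = as.integer(w[1]), end = as.integer(w[2]))
}

#' Call editing status of one aligned read
#'
#' A read is `edited` iff at least one indel event overlaps the cut
#' window: a deletion overlaps when its reference span intersects the
#' window, an insertion when its anchor position lies in the window.
#' Substitutions never mark a read edited. Reads whose alignment
#' identity (matching columns over all alignment columns, gap columns
#' included) is below `min_identity` are `discarded`.
#' `net_indel` sums in-window events (+insertion, -deletion sizes).
#'
#' @param alignment Result of [align_to_amplicon()].
#' @param cut_window Result of [cut_window_for()].
#' @param ref_seq Reference amplicon sequence.
#' @param min_identity Minimum match fraction over alignment columns.
#' @return `list(status=, events=, net_indel=, ref_cols=)`; `events`
#'   gains a logical `in_window` column.
#' @export
call_read <- function(alignment, cut_window, ref_seq,
                      min_identity = 0.6) {
  ae <- alignment_events(alignment, ref_seq)
  ev <- ae$events
  if (nrow(ev)) {
    ev$in_window <- ifelse(
      ev$kind == "deletion",
      ev$position < cut_window$end & ev$position + ev$size > cut_window$start,
      ev$position >= cut_window$start & ev$position < cut_window$end)
  } else {
    ev$in_window <- logical(0)
  }
  n_cols <- nchar(alignment$read_aln)
  identity <- if (n_cols > 0L) ae$n_match / n_cols else 0
  status <- if (identity < min_identity) "discarded"
            else if (any(ev$in_window)) "edited" else "unedited"
  net <- sum(ifelse(ev$kind[ev$in_window] == "insertion",
                    ev$size[ev$in_window], -ev$size[ev$in_window]))
  ref_chars <- strsplit(ref_seq, "")[[1]]
  win <- seq.int(cut_window$start + 1L, cut_window$end)
  subst_window <- sum(!is.na(ae$ref_cols[win]) &
                        ae$ref_cols[win] != ref_chars[win])
  list(status = status, events = ev, net_indel = as.integer(net),
       n_subst_window = as.integer(subst_window), ref_cols = ae$ref_cols)
}

# outcome class of an edited read from its in-window events
read_outcome_class <- function(events) {
  inw <- events[events$in_window, , drop = FALSE]
  if (nrow(inw) == 0L) return(NA_character_)
  has_ins <- any(inw$kind == "insertion")
  has_del <- any(inw$kind == "deletion")
  if (has_ins && has_del) "mixed" else if (has_ins) "insertion"
  else "deletion"
}

#' Quantify editing over merged reads of one amplicon
#'
#' Aligns every merged read to the reference, calls per-read editing
#' status against the nuclease cut window, and aggregates. Discarded
#' reads are excluded from the denominator: `mutation_frequency = 100 *
#' n_edited / (n_edited + n_unedited)`.
#'
#' @param spec An [amplicon_spec()].
#' @param merged_reads Character vector of merged read sequences.
#' @param flank Cut-window flank (see [cut_window_for()]).
#' @param min_identity Identity threshold below which reads are
#'   discarded.
#' @param scores Alignment scores (see [align_to_amplicon()]).
#' @return An object of class `amplicon_callset`: list with
#'   `amplicon_id`, `n_total`, `n_edited`, `n_unedited`, `n_discarded`,
#'   `mutation_frequency` (percent, `NA` and `unreliable` flag when no
#'   usable reads), `reads` (per-read status/class/net_indel table),
#'   `read_events` (per-read in-window event table), `events`
#'   (aggregated event table with counts and percent frequencies), and
#'   `consensus` (majority base per reference position).
#' @export
quantify <- function(spec, merged_reads, flank = 5L, min_identity = 0.6,
                     scores = DEFAULT_ALN_SCORES) {
  cw <- cut_window_for(spec, flank)
  L <- nchar(spec$ref_seq)
  n <- length(merged_reads)
  status <- character(n); net <- integer(n); cls <- character(n)
  nsub <- integer(n)
  rev_list <- vector("list", n)
  counts <- matrix(0L, nrow = 5L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  ids <- names(merged_reads)
  if (is.null(ids)) ids <- sprintf("read_%d", seq_len(n))
  for (i in seq_len(n)) {
    aln <- align_to_amplicon(merged_reads[i], spec$ref_seq, scores)
    cr <- call_read(aln, cw, spec$ref_seq, min_identity)
    status[i] <- cr$status; net[i] <- cr$net_indel
    nsub[i] <- cr$n_subst_window
    cls[i] <- read_outcome_class(cr$events)
    ev <- cr$events[cr$events$in_window, , drop = FALSE]
    if (nrow(ev)) { ev$read_idx <- i; rev_list[[i]] <- ev }
    if (cr$status != "discarded") {
      ok <- !is.na(cr$ref_cols) & cr$ref_cols %in% rownames(counts)
      if (any(ok)) {
        idx <- cbind(match(cr$ref_cols[ok], rownames(counts)), which(ok))
        counts[idx] <- counts[idx] + 1L
      }
    }
  }
  reads <- data.frame(read_id = ids, status = status, class = cls,
                      net_indel = net, n_subst_window = nsub,
                      stringsAsFactors = FALSE)
  read_events <- if (length(rev <- Filter(Negate(is.null), rev_list)))
    do.call(rbind, rev) else
    data.frame(kind = character(), size = integer(), position = integer(),
               inserted_seq = character(), in_window = logical(),
               read_idx = integer(), stringsAsFactors = FALSE)
  build_callset(spec, reads, read_events, counts, n_merge_failed = 0L)
}

# Assemble an amplicon_callset from per-read calls (also used after
# control masking re-evaluation).
build_callset <- function(spec, reads, read_events, counts,
                          n_merge_failed = 0L) {
  usable <- reads$status != "discarded"
  n_edited <- sum(reads$status == "edited")
  n_unedited <- sum(reads$status == "unedited")
  n_usable <- n_edited + n_unedited
  freq <- if (n_usable > 0L) 100 * n_edited / n_usable else NA_real_
  ev_use <- read_events[read_events$read_idx %in% which(usable), ,
                        drop = FALSE]
  if (nrow(ev_use)) {
    key <- paste(ev_use$kind, ev_use$size, ev_use$position,
                 ev_use$inserted_seq, sep = "|")
    agg <- ev_use[!duplicated(key), c("kind", "size", "position",
                                      "inserted_seq"), drop = FALSE]
    agg$count <- as.integer(table(key)[unique(key)])
    agg$frequency <- 100 * agg$count / n_usable
    agg <- agg[order(-agg$count, agg$position, agg$kind, agg$size), ,
               drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(kind = character(), size = integer(),
                      position = integer(), inserted_seq = character(),
                      count = integer(), frequency = numeric(),
                      stringsAsFactors = FALSE)
  }
  cons <- if (ncol(counts) && any(counts > 0L)) {
    ref_chars <- strsplit(spec$ref_seq, "")[[1]]
    vapply(seq_len(ncol(counts)), function(j) {
      col <- counts[, j]
      if (all(col == 0L)) return(ref_chars[j])  # no coverage: keep ref
      top <- which(col == max(col))
      # ties resolved toward the reference base when it is among them
      if (match(ref_chars[j], rownames(counts)) %in% top) ref_chars[j]
      else rownames(counts)[top[1]]
    }, character(1))
  } else strsplit(spec$ref_seq, "")[[1]]
  structure(list(amplicon_id = spec$amplicon_id, spec = spec,
                 n_total = nrow(reads), n_merge_failed = n_merge_failed,
                 n_edited = n_edited, n_unedited = n_unedited,
                 n_discarded = sum(reads$status == "discarded"),
                 mutation_frequency = freq,
                 unreliable = n_usable == 0L,
                 reads = reads, read_events = read_events,
                 events = agg, base_counts = counts,
                 consensus = paste(cons, collapse = ""),
                 control_reliable = NA),
            class = "amplicon_callset")
}

#' @export
print.amplicon_callset <- function(x, ...) {
  cat("Amplicon call set:", x$amplicon_id, "\n")
  cat(sprintf("  reads: %d total, %d edited, %d unedited, %d discarded\n",
              x$n_total, x$n_edited, x$n_unedited, x$n_discarded))
  cat(sprintf("  mutation frequency: %s%%\n",
              format(round(x$mutation_frequency, 2))))
  if (!is.na(x$control_reliable))
    cat("  control reliable:", x$control_reliable, "\n")
  invisible(x)
}

#' Normalize a treated call set against a mock-transfected control
#'
#' Any event whose frequency in the control reaches
#' `control_mask_threshold` (percent) is masked: removed from the
#' treated event table and ignored when deciding per-read edited status.
#' A control with fewer than `min_control_reads` usable reads, or whose
#' majority consensus disagrees with the reference, marks the amplicon
#' as having no reliable control (`control_reliable = FALSE`);
#' downstream adjudication must disregard such amplicons.
#'
#' @param treated,control `amplicon_callset` objects for the same
#'   amplicon.
#' @param control_mask_threshold Masking threshold in percent of
#'   control reads.
#' @param min_control_reads Minimum usable control reads.
#' @return The treated `amplicon_callset`, re-evaluated, with
#'   `control_reliable` set and a `masked_events` table attached.
#' @export
normalize_with_control <- function(treated, control,
                                   control_mask_threshold = 0.5,
                                   min_control_reads = 50L) {
  if (!identical(treated$amplicon_id, control$amplicon_id))
    stop("amplicon id mismatch: ", treated$amplicon_id, " vs ",
         control$amplicon_id)
  n_usable_ctrl <- control$n_edited + control$n_unedited
  reliable <- n_usable_ctrl >= min_control_reads &&
    identical(control$consensus, control$spec$ref_seq)
  mask <- control$events[control$events$frequency >=
                           control_mask_threshold, , drop = FALSE]
  ev <- treated$read_events
  if (nrow(mask) && nrow(ev)) {
    mkey <- paste(mask$kind, mask$size, mask$position, mask$inserted_seq,
                  sep = "|")
    ekey <- paste(ev$kind, ev$size, ev$position, ev$inserted_seq,
                  sep = "|")
    ev <- ev[!ekey %in% mkey, , drop = FALSE]
  }
  reads <- treated$reads
  # re-evaluate status/class/net from surviving in-window events
  for (i in seq_len(nrow(reads))) {
    if (reads$status[i] == "discarded") next
    evi <- ev[ev$read_idx == i, , drop = FALSE]
    reads$status[i] <- if (nrow(evi)) "edited" else "unedited"
    reads$class[i] <- read_outcome_class(evi)
    reads$net_indel[i] <- as.integer(
      sum(ifelse(evi$kind == "insertion", evi$size, -evi$size)))
  }
  out <- build_callset(treated$spec, reads, ev, treated$base_counts,
                       treated$n_merge_failed)
  out$control_reliable <- reliable
  out$masked_events <- mask
  out
}

#' Run the full caller on one amplicon's paired reads
#'
#' Convenience pipeline: merge pairs, then [quantify()]. Merge failures
#' are counted in `n_merge_failed` and excluded from all denominators.
#'
#' @param spec An [amplicon_spec()].
#' @param r1,r2 Character vectors of paired read sequences.
#' @param q1,q2 Optional quality strings.
#' @inheritParams merge_read_pair
#' @inheritParams quantify
#' @return An `amplicon_callset`.
#' @export
call_amplicon <- function(spec, r1, r2, q1 = NULL, q2 = NULL,
                          min_overlap = 20L,
                          max_overlap_mismatch_frac = 0.1,
                          flank = 5L, min_identity = 0.6,
                          scores = DEFAULT_ALN_SCORES) {
  m <- merge_read_pairs(r1, r2, q1, q2, min_overlap,
                        max_overlap_mismatch_frac)
  cs <- quantify(spec, m$seqs, flank, min_identity, scores)
  cs$n_merge_failed <- m$n_failed
  cs
}
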