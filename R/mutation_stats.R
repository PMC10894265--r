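# Downstream editing statistics: per-read net-indel size spectra,
# frameshift fractions, off-target adjudication against a frequency
# threshold, and relative off-target frequencies.

as_callset_list <- function(callsets) {
  if (inherits(callsets, "amplicon_callset")) list(callsets) else callsets
}

mutated_reads <- function(callsets) {
  do.call(rbind, lapply(as_callset_list(callsets), function(cs)
    cs$reads[cs$reads$status == "edited", , drop = FALSE]))
}

#' Indel size spectrum of mutated reads
#'
#' Each mutated read contributes once, via its net indel size (sum of
#' in-window event sizes, +insertion/-deletion). Sizes beyond the
#' bounds are pooled into the boundary bins.
#'
#' @param callsets An `amplicon_callset` or a list of them (same
#'   nuclease).
#' @param max_del,max_ins Pooling bounds: deletions larger than
#'   `max_del` count in the `-max_del` bin, insertions larger than
#'   `max_ins` in the `+max_ins` bin.
#' @return `data.frame` with columns `net_indel` and `fraction`
#'   (fractions of mutated reads; sum to 1), sorted by size.
#' @export
size_spectrum <- function(callsets, max_del = 30L, max_ins = 10L) {
  mut <- mutated_reads(callsets)
  if (is.null(mut) || nrow(mut) == 0L)
    stop("no mutated reads; size spectrum undefined")
  net <- pmax(pmin(mut$net_indel, max_ins), -max_del)
  t <- table(net)
  data.frame(net_indel = as.integer(names(t)),
             fraction = as.numeric(t) / nrow(mut))
}

#' Frameshift summary of mutated reads
#'
#' `frameshift_fraction` is the fraction of mutated reads whose net
#' indel is not a multiple of 3. `from_1bp_insertion` is the fraction of
#' mutated reads that are frameshift with net +1 arising from a single
#' 1-nt insertion (exactly one in-window event, an insertion of size 1).
#'
#' @param callsets An `amplicon_callset` or a list of them.
#' @return `list(frameshift_fraction=, from_1bp_insertion=,
#'   n_mutated=)`.
#' @export
frameshift_summary <- function(callsets) {
  callsets <- as_callset_list(callsets)
  mut <- mutated_reads(callsets)
  if (is.null(mut) || nrow(mut) == 0L)
    stop("no mutated reads; frameshift summary undefined")
  fs <- mut$net_indel %% 3L != 0L
  # identify single-1bp-insertion reads across call sets
  one_bp <- 0L
  for (cs in callsets) {
    ev <- cs$read_events[cs$read_events$in_window, , drop = FALSE]
    if (!nrow(ev)) next
    edited_idx <- which(cs$reads$status == "edited")
    for (i in edited_idx) {
      evi <- ev[ev$read_idx == i, , drop = FALSE]
      if (nrow(evi) == 1L && evi$kind == "insertion" && evi$size == 1L)
        one_bp <- one_bp + 1L
    }
  }
  list(frameshift_fraction = mean(fs),
       from_1bp_insertion = one_bp / nrow(mut),
       n_mutated = nrow(mut))
}

#' Relative off-target frequency
#'
#' Off-target mutation frequency divided by the matched on-target
#' frequency: a measure of how likely an off- and an on-target mutation
#' co-occur in one genome.
#'
#' @param off_pct,on_pct Mutation frequencies in percent.
#' @return The ratio; `NA` (undefined) when `on_pct` is 0.
#' @export
relative_offtarget_frequency <- function(off_pct, on_pct) {
  if (any(c(off_pct, on_pct) < 0)) stop("frequencies must be >= 0")
  if (on_pct == 0) return(NA_real_)
  off_pct / on_pct
}

#' Adjudicate a candidate off-target site
#'
#' A site carries genuine nuclease-induced off-target mutations iff all
#' three hold: its mutation frequency is at least `threshold` percent of
#' usable reads, a reliable wild-type control was obtained, and the
#' variant pattern is indel-dominated (among usable reads carrying any
#' variant in the cut window, at least `indel_dominance_min` carry an
#' indel) rather than substitution-dominated sequencing/PCR noise.
#'
#' @param off_callset Control-normalized `amplicon_callset` of the
#'   off-target amplicon.
#' @param on_callset Control-normalized `amplicon_callset` of the
#'   matched on-target amplicon.
#' @param control_reliable Overrides the off-target call set's
#'   `control_reliable` flag when given.
#' @param threshold Frequency threshold in percent (default 0.1).
#' @param indel_dominance_min Minimum indel fraction among
#'   variant-carrying reads.
#' @return One-row `data.frame`: `site_id`, `off_frequency`,
#'   `on_frequency`, `relative_frequency`, `passes_threshold`,
#'   `control_reliable`, `indel_dominated`, `genuine`.
#' @export
adjudicate_offtarget <- function(off_callset, on_callset,
                                 control_reliable = NULL,
                                 threshold = 0.1,
                                 indel_dominance_min = 0.5) {
  off_f <- off_callset$mutation_frequency
  on_f <- on_callset$mutation_frequency
  if (is.null(control_reliable))
    control_reliable <- isTRUE(off_callset$control_reliable)
  passes <- !is.na(off_f) && off_f >= threshold - 1e-9
  rd <- off_callset$reads
  usable <- rd$status != "discarded"
  has_indel <- rd$status == "edited"
  has_var <- usable & (has_indel | rd$n_subst_window > 0L)
  indel_dom <- if (sum(has_var) == 0L) TRUE else
    sum(has_indel[usable]) / sum(has_var) >= indel_dominance_min
  genuine <- passes && control_reliable && indel_dom
  data.frame(site_id = off_callset$amplicon_id,
             off_frequency = off_f, on_frequency = on_f,
             relative_frequency =
               if (is.na(on_f) || on_f == 0) NA_real_ else off_f / on_f,
             passes_threshold = passes,
             control_reliable = control_reliable,
             indel_dominated = indel_dom, genuine = genuine,
             stringsAsFactors = FALSE)
}

#' Per-target comparison of the two nucleases
#'
#' Summarizes replicate mutation frequencies per shared target:
#' mean, standard deviation (absent for a single replicate) and
#' replicate count for each nuclease, plus the difference of means
#' (Cas12a minus Cas9). No hypothesis testing is performed; the summary
#' carries what any standard test needs.
#'
#' @param cas9_results,cas12a_results `data.frame`s with columns
#'   `target_id` and `frequency` (one row per replicate).
#' @return `data.frame` with per-target summary columns.
#' @export
per_target_comparison <- function(cas9_results, cas12a_results) {
  shared <- intersect(unique(cas9_results$target_id),
                      unique(cas12a_results$target_id))
  if (length(shared) == 0L) stop("no shared target ids")
  summarize <- function(res, id) {
    f <- res$frequency[res$target_id == id]
    c(mean = mean(f), sd = if (length(f) > 1L) stats::sd(f) else NA_real_,
      n = length(f))
  }
  rows <- lapply(shared, function(id) {
    s9 <- summarize(cas9_results, id)
    s12 <- summarize(cas12a_results, id)
    data.frame(target_id = id,
               cas9_mean = s9["mean"], cas9_sd = s9["sd"],
               cas9_n = as.integer(s9["n"]),
               cas12a_mean = s12["mean"], cas12a_sd = s12["sd"],
               cas12a_n = as.integer(s12["n"]),
               diff_mean = s12["mean"] - s9["mean"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Outcome-class shares among mutated reads
#'
#' Classifies every mutated read by its in-window events: `insertion`
#' (insertions only), `deletion` (deletions only) or `mixed` (both),
#' and returns each class's percentage of mutated reads.
#'
#' @param callsets An `amplicon_callset` or a list of them.
#' @return `list(insertion=, deletion=, mixed=, n_mutated=)`,
#'   percentages of mutated reads.
#' @export
outcome_class_shares <- function(callsets) {
  mut <- mutated_reads(callsets)
  if (is.null(mut) || nrow(mut) == 0L)
    stop("no mutated reads; class shares undefined")
  n <- nrow(mut)
  list(insertion = 100 * sum(mut$class == "insertion") / n,
       deletion = 100 * sum(mut$class == "deletion") / n,
       mixed = 100 * sum(mut$class == "mixed") / n,
       n_mutated = n)
}
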