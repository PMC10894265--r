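mk_spec <- function(nuclease = "cas9", len = 240L, seed = 7L) {
  synthetic_amplicon(paste0("amp_", nuclease), nuclease, length = len,
                     seed = seed)
}

reads_from_fragment <- function(frag, read_len = 60L) {
  list(r1 = substr(frag, 1, read_len),
       r2 = oracle_revcomp(substr(frag, nchar(frag) - read_len + 1,
                                  nchar(frag))))
}

test_that("error-free pairs merge back to the exact fragment", {
  set.seed(401)
  frag <- random_seq(100)
  rp <- reads_from_fragment(frag, 60L)
  m <- merge_read_pair(rp$r1, rp$r2)
  expect_identical(m$seq, frag)
})

test_that("overlaps below the minimum are rejected", {
  set.seed(402)
  frag <- random_seq(110)  # 60 + 60 tile -> overlap 10 < 20
  rp <- reads_from_fragment(frag, 60L)
  expect_null(merge_read_pair(rp$r1, rp$r2, min_overlap = 20L))
  expect_false(is.null(merge_read_pair(rp$r1, rp$r2, min_overlap = 10L)))
})

test_that("overlap disagreements resolve toward the higher base quality", {
  set.seed(403)
  frag <- random_seq(100)
  rp <- reads_from_fragment(frag, 60L)
  # introduce one mismatch in r1 inside the overlap (positions 41..60
  # of r1 overlap the fragment)
  r1_bad <- rp$r1
  truth_base <- substr(frag, 50, 50)
  wrong <- setdiff(c("A", "C", "G", "T"), truth_base)[1]
  substr(r1_bad, 50, 50) <- wrong
  q_hi <- strrep("I", 60); q_lo <- strrep("5", 60)
  # r2 higher quality -> r2 base (the true one) wins
  m <- merge_read_pair(r1_bad, rp$r2, q1 = q_lo, q2 = q_hi)
  expect_identical(substr(m$seq, 50, 50), truth_base)
  # tie -> r1 wins
  m2 <- merge_read_pair(r1_bad, rp$r2, q1 = q_hi, q2 = q_hi)
  expect_identical(substr(m2$seq, 50, 50), wrong)
})

test_that("alignment scores equal the independent DP oracle", {
  set.seed(404)
  for (rep in 1:40) {
    ref <- random_seq(sample(50:120, 1))
    # mutate a copy: substitutions plus one optional indel
    read <- ref
    for (i in sample(nchar(ref), sample(0:3, 1)))
      substr(read, i, i) <- sample(c("A", "C", "G", "T"), 1)
    if (runif(1) < 0.7) {
      k <- sample(1:6, 1)
      p <- sample(10:(nchar(read) - 10), 1)
      read <- if (runif(1) < 0.5)
        paste0(substr(read, 1, p), substr(read, p + k + 1, nchar(read)))
      else paste0(substr(read, 1, p), random_seq(k),
                  substr(read, p + 1, nchar(read)))
    }
    aln <- align_to_amplicon(read, ref)
    expect_equal(aln$score, oracle_align_score(read, ref))
    # aligned strings reproduce the inputs
    expect_identical(gsub("-", "", aln$read_aln), read)
    expect_identical(gsub("-", "", aln$ref_aln), ref)
  }
})

test_that("a read identical to the reference aligns gaplessly at 2*len", {
  set.seed(405)
  ref <- random_seq(80)
  aln <- align_to_amplicon(ref, ref)
  expect_equal(aln$score, 2 * 80)
  expect_false(grepl("-", aln$read_aln))
})

test_that("indels in homopolymers are reported left-aligned", {
  ref <- paste0("ACGTG", "AAAA", "CTGTC")
  # delete one A of the run (rightmost)
  read <- paste0("ACGTG", "AAA", "CTGTC")
  aln <- align_to_amplicon(read, ref)
  ev <- casTandem:::alignment_events(aln, ref)$events
  expect_equal(nrow(ev), 1L)
  expect_identical(ev$kind, "deletion")
  expect_equal(ev$position, 5L)  # leftmost position of the A run
  # insertion of an extra A
  read2 <- paste0("ACGTG", "AAAAA", "CTGTC")
  ev2 <- casTandem:::alignment_events(align_to_amplicon(read2, ref),
                                      ref)$events
  expect_identical(ev2$kind, "insertion")
  expect_equal(ev2$position, 5L)
})

test_that("cut windows follow nuclease geometry and clip to bounds", {
  ref <- random_seq(200)
  s9 <- amplicon_spec("a", ref, 50L, 70L, "cas9")
  expect_equal(cut_window_for(s9, flank = 5L), list(start = 62L, end = 73L))
  ref12 <- random_seq(200)
  s12 <- amplicon_spec("b", ref12, 50L, 73L, "cas12a")
  expect_equal(cut_window_for(s12, flank = 0L), list(start = 67L, end = 73L))
  # minus-strand guide mirrors the window inside the guide span
  s9m <- amplicon_spec("c", ref, 50L, 70L, "cas9", strand_of_guide = "-")
  expect_equal(cut_window_for(s9m, flank = 0L), list(start = 52L, end = 53L))
  # clipping at the amplicon edge
  s_edge <- amplicon_spec("d", substr(ref, 1, 40), 10L, 30L, "cas9")
  w <- cut_window_for(s_edge, flank = 20L)
  expect_gte(w$start, 0L)
  expect_lte(w$end, 40L)
})

test_that("call_read applies the window rule to insertions and deletions", {
  spec <- mk_spec("cas9")
  ref <- spec$ref_seq
  cw <- cut_window_for(spec, 5L)
  cut <- spec$guide_start + 17L
  # 1-nt insertion at the cut -> edited, net +1
  read_ins <- paste0(substr(ref, 1, cut),
                     setdiff(c("A", "C", "G", "T"),
                             substr(ref, cut, cut))[1],
                     substr(ref, cut + 1, nchar(ref)))
  cr <- call_read(align_to_amplicon(read_ins, ref), cw, ref)
  expect_identical(cr$status, "edited")
  expect_equal(cr$net_indel, 1L)
  # 4-nt deletion far outside the window -> unedited
  read_del_out <- paste0(substr(ref, 1, 20), substr(ref, 25, nchar(ref)))
  cr2 <- call_read(align_to_amplicon(read_del_out, ref), cw, ref)
  expect_identical(cr2$status, "unedited")
  expect_equal(nrow(cr2$events), 1L)
  # deletion + insertion both in window -> edited, net = ins - del
  read_mix <- paste0(substr(ref, 1, cut - 4),
                     setdiff(c("A", "C", "G", "T"),
                             substr(ref, cut - 4, cut - 4))[1],
                     substr(ref, cut - 3, cut),
                     substr(ref, cut + 3, nchar(ref)))
  cr3 <- call_read(align_to_amplicon(read_mix, ref), cw, ref)
  expect_identical(cr3$status, "edited")
  expect_equal(sum(cr3$events$in_window), 2L)
  expect_equal(cr3$net_indel, 1L - 2L)
  # substitutions never mark a read edited
  read_sub <- ref
  substr(read_sub, cut, cut) <- setdiff(c("A", "C", "G", "T"),
                                        substr(ref, cut, cut))[1]
  expect_identical(call_read(align_to_amplicon(read_sub, ref), cw,
                             ref)$status, "unedited")
})

test_that("garbled reads are discarded by the identity filter", {
  spec <- mk_spec("cas9")
  junk <- random_seq(nchar(spec$ref_seq))
  cs <- quantify(spec, junk)
  expect_equal(cs$n_discarded, 1L)
  expect_true(cs$unreliable)
  expect_true(is.na(cs$mutation_frequency))
})

test_that("quantify returns the exact programmed frequency on clean reads", {
  spec <- mk_spec("cas9")
  ref <- spec$ref_seq
  cut <- spec$guide_start + 17L
  del2 <- paste0(substr(ref, 1, cut - 1), substr(ref, cut + 2, nchar(ref)))
  reads <- c(rep(del2, 25), rep(ref, 75))
  cs <- quantify(spec, reads)
  expect_equal(cs$mutation_frequency, 25.0)
  expect_equal(quantify(spec, rep(ref, 50))$mutation_frequency, 0.0)
  # reads carrying only substitutions stay at 0%
  sub_read <- ref
  substr(sub_read, cut, cut) <- setdiff(c("A", "C", "G", "T"),
                                        substr(ref, cut, cut))[1]
  expect_equal(quantify(spec, rep(sub_read, 30))$mutation_frequency, 0.0)
})

test_that("aggregated event counts cover every edited read", {
  spec <- mk_spec("cas12a")
  pf <- preset_profiles()$cas12a_like
  rd <- simulate_reads(spec, pf, n_reads = 200L, error_rate = 0,
                       seed = 31L)
  cs <- call_amplicon(spec, rd$r1, rd$r2, rd$q1, rd$q2)
  expect_gte(sum(cs$events$count), cs$n_edited)
})

test_that("control masking removes shared events and re-evaluates reads", {
  spec <- mk_spec("cas9")
  ref <- spec$ref_seq
  cut <- spec$guide_start + 17L
  del3 <- paste0(substr(ref, 1, cut - 2), substr(ref, cut + 2, nchar(ref)))
  ins1 <- paste0(substr(ref, 1, cut),
                 setdiff(c("A", "C", "G", "T"),
                         substr(ref, cut, cut))[1],
                 substr(ref, cut + 1, nchar(ref)))
  treated <- quantify(spec, c(rep(del3, 10), rep(ins1, 5), rep(ref, 85)))
  # control carries the del3 event at 2% (>= 0.5% threshold) but is
  # otherwise wild type
  control <- quantify(spec, c(rep(del3, 2), rep(ref, 98)))
  out <- normalize_with_control(treated, control)
  expect_true(out$control_reliable)
  expect_equal(out$n_edited, 5L)            # only the insertion remains
  expect_equal(out$mutation_frequency, 5.0)
  expect_false(any(out$events$kind == "deletion"))

  # event present in treated but absent from control is retained
  control_clean <- quantify(spec, rep(ref, 100))
  out2 <- normalize_with_control(treated, control_clean)
  expect_equal(out2$n_edited, 15L)

  # small control -> unreliable
  small <- quantify(spec, rep(ref, 30))
  expect_false(normalize_with_control(treated, small)$control_reliable)

  # control consensus differing from the reference -> unreliable
  mut_ref <- ref
  for (i in (spec$guide_start + c(2L, 8L, 14L))) {
    substr(mut_ref, i, i) <- setdiff(c("A", "C", "G", "T"),
                                     substr(mut_ref, i, i))[1]
  }
  bad_ctrl <- quantify(spec, rep(mut_ref, 60))
  expect_false(normalize_with_control(treated, bad_ctrl)$control_reliable)

  expect_error(normalize_with_control(
    treated, quantify(amplicon_spec("other", ref, spec$guide_start,
                                    spec$guide_end, "cas9"),
                      rep(ref, 60))),
    "mismatch")
})
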