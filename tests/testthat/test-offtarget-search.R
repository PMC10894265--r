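test_that("hit_distance: identity, numbering, and no-match bound", {
  sp9 <- "ACGTACGTACGTACGTACGT"
  expect_equal(hit_distance(sp9, sp9, "3prime"),
               list(n_mismatches = 0L, mismatch_positions = integer(0),
                    bulge = "none", bulge_position = NA_integer_))

  # PAM-distal substitution of a 23-nt Cas12a spacer -> position 23
  sp12 <- "ACGTACGTACGTACGTACGTACG"
  site <- sp12
  substr(site, 23, 23) <- "T"
  hd <- hit_distance(sp12, site, "5prime")
  expect_equal(hd$n_mismatches, 1L)
  expect_equal(hd$mismatch_positions, 23L)

  # for Cas9 (3' PAM) the same string position is PAM-proximal
  site9 <- sp9
  substr(site9, 20, 20) <- "A"
  expect_equal(hit_distance(sp9, site9, "3prime")$mismatch_positions, 1L)

  # four substitutions exceed the bound
  s4 <- sp9
  for (i in c(2, 5, 9, 13)) {
    substr(s4, i, i) <- setdiff(c("A", "C", "G", "T"),
                                substr(sp9, i, i))[1]
  }
  expect_null(hit_distance(sp9, s4, "3prime"))
  expect_error(hit_distance(sp9, substr(sp9, 1, 17), "3prime"),
               "within 1")
})

test_that("bulge placement minimizes mismatches like the gap-enumeration oracle", {
  set.seed(301)
  for (rep in 1:40) {
    sp <- random_seq(23)
    kind <- sample(c("rna", "dna"), 1)
    if (kind == "rna") {
      j <- sample(2:22, 1)
      site <- paste0(substr(sp, 1, j - 1), substr(sp, j + 1, 23))
    } else {
      j <- sample(2:22, 1)
      site <- paste0(substr(sp, 1, j), random_seq(1), substr(sp, j + 1, 23))
    }
    hd <- hit_distance(sp, site, "5prime", max_mm = 3L)
    orc <- oracle_distance(sp, site, max_mm = 3L)
    if (is.null(orc)) {
      expect_null(hd)
    } else {
      expect_equal(hd$n_mismatches, orc$n_mm)
      expect_equal(hd$bulge, orc$bulge)
    }
  }
})

plant_window <- function(genome_seq, pos, window) {
  substr(genome_seq, pos + 1L, pos + nchar(window)) <- window
  genome_seq
}

test_that("enumerate_offtargets equals the exhaustive oracle across settings", {
  set.seed(302)
  genome_seq <- random_seq(2500, gc = 0.45)
  sp9 <- random_seq(20)
  # plant: exact site, 2-mm site, 3-mm site, dna-bulge site
  mk <- function(sp, subs = integer(0), ins_at = NA) {
    s <- sp
    for (i in subs)
      substr(s, i, i) <- setdiff(c("A", "C", "G", "T"),
                                 substr(s, i, i))[1]
    if (!is.na(ins_at))
      s <- paste0(substr(s, 1, ins_at), "A", substr(s, ins_at + 1, nchar(s)))
    paste0(s, "AGG")
  }
  genome_seq <- plant_window(genome_seq, 100L, mk(sp9))
  genome_seq <- plant_window(genome_seq, 300L, mk(sp9, c(3, 11)))
  genome_seq <- plant_window(genome_seq, 500L, mk(sp9, c(2, 9, 17)))
  genome_seq <- plant_window(genome_seq, 700L, mk(sp9, ins_at = 6))
  genome <- c(c1 = genome_seq)
  q <- query_spacer("cas9", sp9, id = "q1")
  for (max_mm in 0:3) {
    for (max_bulge in 0:1) {
      hits <- enumerate_offtargets(genome, q, max_mm = max_mm,
                                   max_bulge = max_bulge)
      orc <- oracle_offtargets(genome, sp9, "NGG", "3prime",
                               max_mm, max_bulge)
      h <- hits[order(hits$chrom, hits$start, hits$end, hits$strand,
                      hits$bulge),
                c("chrom", "start", "end", "strand", "n_mismatches",
                  "bulge")]
      rownames(h) <- NULL
      expect_identical(h, orc,
                       label = sprintf("mm=%d bulge=%d", max_mm, max_bulge))
    }
  }
  # with the full settings the planted loci are all recovered
  hits <- enumerate_offtargets(genome, q)
  expect_true(all(c(100L, 300L, 500L, 700L) %in% hits$start))
})

test_that("a 4-mismatch site is absent; Cas12a oracle agreement on both strands", {
  set.seed(303)
  genome_seq <- random_seq(2000, gc = 0.45)
  sp12 <- random_seq(23)
  s4 <- sp12
  for (i in c(2, 8, 14, 20))
    substr(s4, i, i) <- setdiff(c("A", "C", "G", "T"),
                                substr(s4, i, i))[1]
  genome_seq <- plant_window(genome_seq, 200L, paste0("TTTC", sp12))
  genome_seq <- plant_window(genome_seq, 500L, paste0("TTTC", s4))
  genome_seq <- plant_window(genome_seq, 900L,
                             oracle_revcomp(paste0("TTTA", sp12)))
  genome <- c(c1 = genome_seq)
  q <- query_spacer("cas12a", sp12, id = "q1")
  hits <- enumerate_offtargets(genome, q)
  expect_false(504L %in% hits$start[hits$bulge == "none"])
  expect_true(204L %in% hits$start)
  expect_true(any(hits$strand == "-"))
  orc <- oracle_offtargets(genome, sp12, "TTTV", "5prime", 3L, 1L)
  h <- hits[order(hits$chrom, hits$start, hits$end, hits$strand,
                  hits$bulge),
            c("chrom", "start", "end", "strand", "n_mismatches", "bulge")]
  rownames(h) <- NULL
  expect_identical(h, orc)
})

test_that("reverse-complementing the genome mirrors the hit set", {
  set.seed(304)
  genome_seq <- random_seq(1500, gc = 0.45)
  sp9 <- random_seq(20)
  genome_seq <- plant_window(genome_seq, 400L, paste0(sp9, "TGG"))
  n <- nchar(genome_seq)
  q <- query_spacer("cas9", sp9, id = "q")
  h1 <- enumerate_offtargets(c(c1 = genome_seq), q)
  h2 <- enumerate_offtargets(c(c1 = oracle_revcomp(genome_seq)), q)
  expect_equal(nrow(h1), nrow(h2))
  mirrored <- data.frame(start = n - h2$end, end = n - h2$start,
                         strand = ifelse(h2$strand == "+", "-", "+"),
                         stringsAsFactors = FALSE)
  key <- function(d) sort(paste(d$start, d$end, d$strand))
  expect_identical(key(h1[, c("start", "end", "strand")]), key(mirrored))
})

test_that("longer Cas12a spacers yield no more hits than Cas9 in expectation", {
  set.seed(305)
  n9 <- 0; n12 <- 0
  for (rep in 1:20) {
    genome <- c(c1 = random_seq(1200, gc = 0.5))
    sp9 <- random_seq(20); sp12 <- random_seq(23)
    n9 <- n9 + nrow(enumerate_offtargets(genome,
                                         query_spacer("cas9", sp9)))
    n12 <- n12 + nrow(enumerate_offtargets(genome,
                                           query_spacer("cas12a", sp12)))
  }
  expect_lte(n12, n9)
})

test_that("mismatch position histogram counts and conserves totals", {
  hits <- data.frame(mismatch_positions = c("5,20", "", "5", "1,2,3"),
                     n_mismatches = c(2L, 0L, 1L, 3L))
  h <- mismatch_position_histogram(hits, 20L)
  expect_equal(unname(h[c("5", "20")]), c(2L, 1L))
  expect_equal(sum(h), sum(hits$n_mismatches))
  expect_equal(sum(mismatch_position_histogram(hits[0, ], 20L)), 0L)
})

test_that("balanced selection maximizes covered mismatch positions", {
  mk_hits <- function(pos_list, starts = seq_along(pos_list)) {
    data.frame(query_id = "q", chrom = "c1", start = starts,
               end = starts + 20L, strand = "+", site_seq = "x",
               pam_seq = "x",
               n_mismatches = lengths(pos_list),
               mismatch_positions = vapply(pos_list, paste,
                                           character(1), collapse = ","),
               bulge = "none", bulge_position = NA_integer_,
               stringsAsFactors = FALSE)
  }
  # fewer candidates than k -> all returned
  h3 <- mk_hits(list(1, 5, 9))
  expect_equal(nrow(select_balanced_offtargets(h3, k = 4)), 3L)

  # coverage maximization picks {1} and {9}, not the duplicate {1}
  h <- mk_hits(list(1, 1, 9))
  sel <- select_balanced_offtargets(h, k = 2)
  expect_setequal(unlist(lapply(sel$mismatch_positions, identity)),
                  c("1", "9"))

  # greedy coverage equals the exhaustive 4-subset optimum here
  set.seed(306)
  pos_list <- replicate(12, sort(sample(1:20, sample(1:3, 1))),
                        simplify = FALSE)
  h12 <- mk_hits(pos_list)
  sel <- select_balanced_offtargets(h12, k = 4)
  sel_cov <- length(unique(unlist(
    lapply(strsplit(sel$mismatch_positions, ","), as.integer))))
  best <- 0L
  combos <- utils::combn(12, 4)
  for (c_i in seq_len(ncol(combos))) {
    cov <- length(unique(unlist(pos_list[combos[, c_i]])))
    best <- max(best, cov)
  }
  expect_equal(sel_cov, best)

  # the 0-mismatch on-target hit is dropped by default
  on <- mk_hits(list(integer(0), 3), starts = c(50L, 60L))
  on$n_mismatches <- c(0L, 1L)
  sel2 <- select_balanced_offtargets(on, k = 4)
  expect_equal(nrow(sel2), 1L)
  expect_equal(sel2$n_mismatches, 1L)
})
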