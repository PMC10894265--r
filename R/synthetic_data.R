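# Synthetic-data generator: genomes with planted overlapping target
# sites and configured off-target sites (ground truth exhaustive by
# construction, with background screening), and paired-end amplicon
# read pools with programmed editing outcomes.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Editing-outcome profile for the read simulator
#'
#' Describes the distribution of repair outcomes among mutated reads:
#' the probability a read is edited at all (`edit_fraction`), the class
#' probabilities among edited reads (`p_insertion`, `p_deletion`, and
#' `p_mixed` for reads carrying one deletion plus a 1-nt insertion),
#' the size distributions within each class, and the maximum offset of
#' an event from the canonical cut site (`position_jitter`).
#'
#' @param edit_fraction Probability a read is edited.
#' @param p_insertion,p_deletion,p_mixed Outcome-class probabilities
#'   among edited reads; must sum to 1.
#' @param insertion_size_dist Named numeric vector, size -> probability.
#' @param deletion_size_dist Named numeric vector, size -> probability.
#' @param position_jitter Maximum offset (nt) of an event from the
#'   canonical cut position.
#' @return A list of class `editing_profile`.
#' @export
editing_profile <- function(edit_fraction, p_insertion, p_deletion,
                            p_mixed = 0, insertion_size_dist,
                            deletion_size_dist, position_jitter = 2L) {
  stopifnot(edit_fraction >= 0, edit_fraction <= 1)
  if (abs(p_insertion + p_deletion + p_mixed - 1) > 1e-9)
    stop("class probabilities must sum to 1")
  if (abs(sum(insertion_size_dist) - 1) > 1e-9 ||
      abs(sum(deletion_size_dist) - 1) > 1e-9)
    stop("size distributions must sum to 1")
  structure(list(edit_fraction = edit_fraction,
                 p_insertion = p_insertion, p_deletion = p_deletion,
                 p_mixed = p_mixed,
                 insertion_size_dist = insertion_size_dist,
                 deletion_size_dist = deletion_size_dist,
                 position_jitter = as.integer(position_jitter)),
            class = "editing_profile")
}

#' Preset Cas9-like and Cas12a-like editing profiles
#'
#' Class shares follow the two enzymes' published on-target repair
#' spectra: the Cas9-like profile has a 17.4% insertion share with 89%
#' of insertions being 1 bp and deletions concentrated at 1-5 bp
#' (truncated geometric); the Cas12a-like profile has a 1.8% insertion
#' share and deletions concentrated at 5-10 bp (discrete triangular).
#' The residual probability in each profile is a mixed outcome (one
#' deletion plus a 1-nt insertion in the same read), so the insertion
#' and deletion class shares are realized simultaneously. Size
#' distribution shapes beyond the 1-bp insertion share are this
#' module's choices.
#'
#' @return `list(cas9_like=, cas12a_like=)` of [editing_profile()]s.
#' @export
preset_profiles <- function() {
  geo <- 0.5 ^ (0:4); geo <- geo / sum(geo)
  tri <- c(1, 2, 3, 3, 2, 1); tri <- tri / sum(tri)
  list(
    cas9_like = editing_profile(
      edit_fraction = 0.5,
      p_insertion = 0.174, p_deletion = 0.805, p_mixed = 0.021,
      insertion_size_dist = stats::setNames(c(0.89, 0.08, 0.03), 1:3),
      deletion_size_dist = stats::setNames(geo, 1:5),
      position_jitter = 2L),
    cas12a_like = editing_profile(
      edit_fraction = 0.5,
      p_insertion = 0.018, p_deletion = 0.941, p_mixed = 0.041,
      insertion_size_dist = stats::setNames(c(0.6, 0.3, 0.1), 1:3),
      deletion_size_dist = stats::setNames(tri, 5:10),
      position_jitter = 2L)
  )
}

#' Analytic frameshift expectation of a profile
#'
#' Probability that an edited read's net indel is not a multiple of 3,
#' computed from the profile's class and size distributions (mixed
#' reads have net `1 - deletion size`).
#'
#' @param profile An [editing_profile()].
#' @return Numeric scalar in `[0, 1]`.
#' @export
profile_frameshift_expectation <- function(profile) {
  ins <- profile$insertion_size_dist
  del <- profile$deletion_size_dist
  fs_ins <- sum(ins[as.integer(names(ins)) %% 3L != 0L])
  fs_del <- sum(del[as.integer(names(del)) %% 3L != 0L])
  fs_mix <- sum(del[(1L - as.integer(names(del))) %% 3L != 0L])
  profile$p_insertion * fs_ins + profile$p_deletion * fs_del +
    profile$p_mixed * fs_mix
}

#' Planting specification for the genome simulator
#'
#' @param n_overlap_sites Number of overlapping target sites (one per
#'   generated gene).
#' @param offtarget_configs List of configurations, each a list with
#'   fields `site` (index of the planted site the spacer comes from),
#'   `nuclease` (`"cas9"`/`"cas12a"`), `n_mismatches` (0-3),
#'   `mismatch_positions` (PAM-proximal, length `n_mismatches`),
#'   `bulge` (`"none"`, `"dna"`, `"rna"`), `bulge_position` (when
#'   bulged).
#' @param genome_length Background genome length in nt.
#' @param gc_content Background GC fraction.
#' @param seed Mandatory RNG seed.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(n_overlap_sites = 3L, offtarget_configs = list(),
                       genome_length = 15000L, gc_content = 0.38,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  for (cfg in offtarget_configs) {
    stopifnot(cfg$nuclease %in% c("cas9", "cas12a"),
              cfg$n_mismatches >= 0L, cfg$n_mismatches <= 3L,
              cfg$bulge %in% c("none", "dna", "rna"),
              length(cfg$mismatch_positions) == cfg$n_mismatches)
  }
  footprint <- n_overlap_sites * 400L + length(offtarget_configs) * 60L
  if (genome_length < footprint)
    stop("genome_length too small for the requested plants (need >= ",
         footprint, ")")
  structure(list(n_overlap_sites = as.integer(n_overlap_sites),
                 offtarget_configs = offtarget_configs,
                 genome_length = as.integer(genome_length),
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "plant_spec")
}

# draw a random overlap-site sequence TTTV + N20 + NGG
.draw_site_seq <- function() {
  paste0("TTT", sample(c("A", "C", "G"), 1L),
         paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
               collapse = ""),
         sample(c("A", "C", "G", "T"), 1L), "GG")
}

# spacer index (5'->3') of a PAM-proximal position
.idx_from_pp <- function(pos, spacer_len, pam_side) {
  if (pam_side == "5prime") pos else spacer_len - pos + 1L
}

# realize one off-target config: mutate a copy of the spacer and attach
# a concrete PAM; returns list(site_with_pam, window_offset, window_len)
# where window_offset is the 0-based offset of the protospacer-like
# window within the returned sequence
.realize_offtarget <- function(cfg, spacer) {
  L <- nchar(spacer)
  pam_side <- if (cfg$nuclease == "cas9") "3prime" else "5prime"
  chars <- strsplit(spacer, "")[[1]]
  for (pos in cfg$mismatch_positions) {
    i <- .idx_from_pp(pos, L, pam_side)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  if (cfg$bulge == "rna") {
    i <- .idx_from_pp(cfg$bulge_position, L, pam_side)
    # unambiguous placement requires the skipped base to differ from
    # its neighbours
    if ((i > 1L && chars[i] == chars[i - 1L]) ||
        (i < L && chars[i] == chars[i + 1L])) return(NULL)
    chars <- chars[-i]
  } else if (cfg$bulge == "dna") {
    i <- .idx_from_pp(cfg$bulge_position, L, pam_side)
    forbid <- unique(c(chars[i], if (i > 1L) chars[i - 1L]))
    ins <- sample(setdiff(c("A", "C", "G", "T"), forbid), 1L)
    chars <- append(chars, ins, after = i - 1L)
  }
  window <- paste(chars, collapse = "")
  if (cfg$nuclease == "cas9") {
    pam <- paste0(sample(c("A", "C", "G", "T"), 1L), "GG")
    list(seq = paste0(window, pam), window_offset = 0L,
         window_len = nchar(window))
  } else {
    pam <- paste0("TTT", sample(c("A", "C", "G"), 1L))
    list(seq = paste0(pam, window), window_offset = 4L,
         window_len = nchar(window))
  }
}

splice_in <- function(seq, pos, insert) {
  # overwrite seq[pos+1 .. pos+nchar(insert)] (0-based pos)
  paste0(substr(seq, 1L, pos), insert,
         substr(seq, pos + nchar(insert) + 1L, nchar(seq)))
}

#' Simulate a genome with planted target and off-target sites
#'
#' Generates a single-chromosome background at the requested GC
#' content, lays out one gene (with one or two CDS intervals) per
#' overlap site, plants each overlap site wholly inside a CDS on a
#' random strand, and realizes every off-target configuration by
#' mutating a copy of the corresponding planted spacer and placing it
#' intergenically with a valid PAM. Background windows that would spawn
#' accidental overlap-pattern matches inside the scanned CDS, or
#' accidental off-target hits of any planted spacer, are regenerated so
#' the ground-truth tables are exhaustive. Deterministic given the
#' seed.
#'
#' @param spec A [plant_spec()].
#' @param max_iter Maximum screening iterations before giving up.
#' @return List with `genome` (named character vector), `gene_models`
#'   (CDS table as from [read_gff3()]), `families` (gene_id -> family),
#'   `sites` (ground-truth overlap-site table), `offtargets`
#'   (ground-truth off-target table with configured mismatch/bulge
#'   annotation).
#' @export
simulate_genome <- function(spec, max_iter = 30L) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(spec$seed, {
    G <- spec$genome_length
    chrom <- "chr1"
    n <- spec$n_overlap_sites
    n_ot <- length(spec$offtarget_configs)
    # layout: genes evenly spaced in the left 60%, off-targets in the
    # right 30%
    gene_span <- 300L
    gene_starts <- as.integer(seq(from = 200L,
                                  to = max(300L, floor(G * 0.6)),
                                  length.out = max(n, 1L)))
    genome <- random_dna(G, spec$gc_content)

    genes <- list(); sites <- list()
    occupied <- list()  # list of c(start, end) footprints
    for (i in seq_len(n)) {
      gid <- sprintf("gene%02d", i)
      cds_start <- gene_starts[i]
      cds_end <- cds_start + gene_span
      if (cds_end > G) stop("infeasible packing: genome too short")
      strand <- sample(c("+", "-"), 1L)
      # draw a site whose spacer admits every bulge config planted
      # from it without placement ambiguity
      repeat {
        site_seq <- .draw_site_seq()
        spacer23 <- substr(site_seq, 5L, 27L)
        ok <- TRUE
        # the same span must not also match on the opposite strand
        if (nrow(scan_sequence(site_seq, strand = "-")) > 0L) ok <- FALSE
        for (cfg in spec$offtarget_configs) {
          if (cfg$site != i || cfg$bulge == "none") next
          sp <- if (cfg$nuclease == "cas9") substr(spacer23, 1L, 20L)
                else spacer23
          if (is.null(.realize_offtarget(cfg, sp))) ok <- FALSE
        }
        if (ok) break
      }
      pos <- cds_start + sample.int(gene_span - 27L, 1L)
      insert <- if (strand == "+") site_seq else revcomp(site_seq)
      genome <- splice_in(genome, pos, insert)
      genes[[i]] <- data.frame(
        gene_id = gid, chrom = chrom, start = cds_start, end = cds_end,
        strand = "+", stringsAsFactors = FALSE)
      sites[[i]] <- data.frame(
        chrom = chrom, start = pos, end = pos + 27L, strand = strand,
        gene_id = gid,
        cas9_spacer = substr(site_seq, 5L, 24L),
        cas9_pam = substr(site_seq, 25L, 27L),
        cas12a_spacer = substr(site_seq, 5L, 27L),
        cas12a_pam = substr(site_seq, 1L, 4L),
        stringsAsFactors = FALSE)
      occupied[[length(occupied) + 1L]] <- c(pos, pos + 27L)
    }
    gene_models <- do.call(rbind, genes)
    sites <- do.call(rbind, sites)

    # place off-targets in the right part of the genome, spaced apart
    ot_rows <- list()
    ot_slot <- as.integer(floor(G * 0.7))
    for (k in seq_len(n_ot)) {
      cfg <- spec$offtarget_configs[[k]]
      st <- sites[cfg$site, ]
      sp <- if (cfg$nuclease == "cas9") st$cas9_spacer else
        st$cas12a_spacer
      real <- .realize_offtarget(cfg, sp)
      if (is.null(real)) stop("bulge config ambiguous for planted spacer")
      strand <- sample(c("+", "-"), 1L)
      pos <- ot_slot
      ot_slot <- ot_slot + nchar(real$seq) + 60L
      if (pos + nchar(real$seq) > G) stop("infeasible packing")
      insert <- if (strand == "+") real$seq else revcomp(real$seq)
      genome <- splice_in(genome, pos, insert)
      win_start <- if (strand == "+") pos + real$window_offset else
        pos + nchar(real$seq) - real$window_offset - real$window_len
      ot_rows[[k]] <- data.frame(
        config = k, site = cfg$site, nuclease = cfg$nuclease,
        chrom = chrom, start = win_start,
        end = win_start + real$window_len, strand = strand,
        n_mismatches = cfg$n_mismatches,
        mismatch_positions = paste(sort(cfg$mismatch_positions),
                                   collapse = ","),
        bulge = cfg$bulge,
        bulge_position = if (cfg$bulge == "none") NA_integer_ else
          as.integer(cfg$bulge_position),
        stringsAsFactors = FALSE)
      occupied[[length(occupied) + 1L]] <-
        c(pos, pos + nchar(real$seq))
    }
    offtargets <- if (n_ot) do.call(rbind, ot_rows) else
      data.frame(config = integer(), site = integer(),
                 nuclease = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character(),
                 n_mismatches = integer(),
                 mismatch_positions = character(), bulge = character(),
                 bulge_position = integer(), stringsAsFactors = FALSE)

    overlaps_truth <- function(a, b) {
      any(vapply(occupied, function(f) a < f[2] && b > f[1], logical(1)))
    }
    # positions (0-based) in [a, b) not covered by any truth footprint
    uncovered_positions <- function(a, b) {
      pos <- a:(b - 1L)
      for (f in occupied) pos <- pos[pos < f[1] | pos >= f[2]]
      pos
    }
    # true iff (start, strand) is a planted overlap-site locus
    is_planted_site <- function(s, strand) {
      any(sites$start == s & sites$strand == strand)
    }

    # screening: regenerate background that spawns accidental matches
    queries <- list()
    for (i in seq_len(nrow(sites))) {
      queries[[length(queries) + 1L]] <-
        query_spacer("cas9", sites$cas9_spacer[i], id = "screen")
      queries[[length(queries) + 1L]] <-
        query_spacer("cas12a", sites$cas12a_spacer[i], id = "screen")
    }
    for (iter in seq_len(max_iter)) {
      dirty <- FALSE
      # accidental overlap-pattern matches inside scanned CDS
      found <- find_overlapping_sites(setNames(genome, chrom),
                                      gene_models, gene_models$gene_id)
      for (j in seq_len(nrow(found))) {
        if (is_planted_site(found$start[j], found$strand[j])) next
        # accidental match: regenerate only bases outside planted
        # footprints (a match overlapping a planted site keeps the
        # planted bases intact and loses its own flanking support)
        pos <- uncovered_positions(found$start[j], found$end[j])
        if (!length(pos))
          stop("infeasible packing: accidental site inside a footprint")
        for (p in pos)
          genome <- splice_in(genome, p, random_dna(1L, spec$gc_content))
        dirty <- TRUE
      }
      # accidental off-target hits of any planted spacer
      for (q in queries) {
        hits <- enumerate_offtargets(setNames(genome, chrom), q)
        for (j in seq_len(nrow(hits))) {
          if (!overlaps_truth(hits$start[j], hits$end[j])) {
            genome <- splice_in(genome, hits$start[j],
                                random_dna(hits$end[j] - hits$start[j],
                                           spec$gc_content))
            dirty <- TRUE
          }
        }
      }
      if (!dirty) break
      if (iter == max_iter)
        stop("infeasible packing: background screening did not converge")
    }

    fam <- setNames(rep(c("bHLH", "MYB"), length.out = nrow(gene_models)),
                    gene_models$gene_id)
    list(genome = setNames(genome, chrom), gene_models = gene_models,
         families = fam, sites = sites, offtargets = offtargets)
  })
}

#' Write a simulated genome bundle to disk
#'
#' Writes FASTA, GFF3 (gene/mRNA/CDS rows per gene), a BED6 of planted
#' site loci and TSV ground-truth tables. Byte-identical for identical
#' spec and seed.
#'
#' @param sim Result of [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_genome_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gff3 = file.path(dir, "models.gff3"),
             bed = file.path(dir, "sites.bed"),
             sites = file.path(dir, "sites_truth.tsv"),
             offtargets = file.path(dir, "offtargets_truth.tsv"))
  write_fasta(sim$genome, paths["fasta"])
  gm <- sim$gene_models
  lines <- c("##gff-version 3")
  for (gid in unique(gm$gene_id)) {
    rows <- gm[gm$gene_id == gid, , drop = FALSE]
    gs <- min(rows$start); ge <- max(rows$end)
    strand <- rows$strand[1]; chrom <- rows$chrom[1]
    lines <- c(lines,
      sprintf("%s\tcasTandem\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              chrom, gs + 1L, ge, strand, gid),
      sprintf("%s\tcasTandem\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
              chrom, gs + 1L, ge, strand, gid, gid),
      sprintf(paste0("%s\tcasTandem\tCDS\t%d\t%d\t.\t%s\t0\t",
                     "ID=%s.1.cds;Parent=%s.1;gene_id=%s"),
              rows$chrom, rows$start + 1L, rows$end, rows$strand,
              gid, gid, gid))
  }
  writeLines(lines, paths["gff3"])
  bed <- sim$sites
  bed$name <- site_id(bed)
  write_bed(bed, paths["bed"])
  write_tsv(sim$sites, paths["sites"])
  write_tsv(sim$offtargets, paths["offtargets"])
  invisible(paths)
}

#' Simulate paired-end amplicon reads with programmed editing
#'
#' Exactly `floor(edit_fraction * n_reads)` reads carry a sampled edit
#' (class, sizes and position jitter drawn from the profile) applied at
#' the nuclease's canonical cut site; the rest are wild type. Uniform
#' substitution errors are then applied per base. Read 1 is the first
#' `read_len` bases of the (edited) fragment; read 2 is the reverse
#' complement of the last `read_len` bases, i.e. sequencing
#' orientation. Qualities are a constant high value, optionally lowered
#' at simulated error positions.
#'
#' @param spec An [amplicon_spec()]; the amplicon must be at least
#'   `read_len` long after the largest programmed deletion.
#' @param profile An [editing_profile()].
#' @param n_reads Number of read pairs.
#' @param error_rate Per-base substitution error probability.
#' @param read_len Read length (150 by default).
#' @param seed Mandatory RNG seed.
#' @param base_quality Phred quality for all bases (default 37).
#' @param error_quality Optional lower phred value written at simulated
#'   error positions.
#' @return List with `r1`, `r2`, `q1`, `q2` (character vectors) and
#'   `truth` (`data.frame`: `read_id`, `edited`, `class`, `ins_size`,
#'   `del_size`, `net_indel`).
#' @export
simulate_reads <- function(spec, profile, n_reads, error_rate = 0,
                           read_len = 150L, seed, base_quality = 37L,
                           error_quality = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(spec, "amplicon_spec"),
            inherits(profile, "editing_profile"))
  ref <- spec$ref_seq
  L <- nchar(ref)
  max_del <- max(as.integer(names(profile$deletion_size_dist)))
  if (L < read_len)
    stop("amplicon shorter than read length")
  if (L - max_del < read_len)
    stop("largest programmed deletion would shrink the fragment below ",
         "the read length")
  core <- cut_window_for(spec, flank = 0L)
  center <- core$start + (core$end - core$start) %/% 2L
  with_seed(seed, {
    n_edit <- floor(profile$edit_fraction * n_reads)
    edited <- rep(FALSE, n_reads)
    edited[sample.int(n_reads, n_edit)] <- TRUE
    r1 <- character(n_reads); r2 <- character(n_reads)
    q1 <- character(n_reads); q2 <- character(n_reads)
    cls <- rep(NA_character_, n_reads)
    ins_size <- rep(NA_integer_, n_reads)
    del_size <- rep(NA_integer_, n_reads)
    classes <- c("insertion", "deletion", "mixed")
    probs <- c(profile$p_insertion, profile$p_deletion, profile$p_mixed)
    jit_max <- profile$position_jitter
    for (i in seq_len(n_reads)) {
      frag <- ref
      if (edited[i]) {
        cls[i] <- sample(classes, 1L, prob = probs)
        jit <- if (jit_max > 0L) sample(-jit_max:jit_max, 1L) else 0L
        if (cls[i] %in% c("deletion", "mixed")) {
          ds <- as.integer(sample(names(profile$deletion_size_dist), 1L,
                                  prob = profile$deletion_size_dist))
          del_size[i] <- ds
          # mixed reads carry the deletion right of the cut and a 1-nt
          # insertion left of it, separated by matching bases, so both
          # events are recoverable from one alignment
          dstart <- if (cls[i] == "mixed") center + 2L + jit else
            max(0L, center - ds %/% 2L + jit)
          frag <- paste0(substr(frag, 1L, dstart),
                         substr(frag, dstart + ds + 1L, nchar(frag)))
          if (cls[i] == "mixed") {
            ins_size[i] <- 1L
            anchor <- center - 2L + jit
            # a base differing from its left neighbour cannot left-shift
            prev <- substr(frag, anchor, anchor)
            insb <- sample(setdiff(c("A", "C", "G", "T"), prev), 1L)
            frag <- paste0(substr(frag, 1L, anchor), insb,
                           substr(frag, anchor + 1L, nchar(frag)))
          }
        } else {
          is_ <- as.integer(sample(names(profile$insertion_size_dist), 1L,
                                   prob = profile$insertion_size_dist))
          ins_size[i] <- is_
          anchor <- center + jit
          insb <- paste(sample(c("A", "C", "G", "T"), is_,
                               replace = TRUE), collapse = "")
          frag <- paste0(substr(frag, 1L, anchor), insb,
                         substr(frag, anchor + 1L, nchar(frag)))
        }
      }
      fl <- nchar(frag)
      s1 <- substr(frag, 1L, read_len)
      s2 <- revcomp(substr(frag, fl - read_len + 1L, fl))
      qs1 <- rep(base_quality, read_len)
      qs2 <- rep(base_quality, read_len)
      if (error_rate > 0) {
        add_err <- function(s, qs) {
          v <- strsplit(s, "")[[1]]
          hit <- which(runif(length(v)) < error_rate)
          for (h in hit)
            v[h] <- sample(setdiff(c("A", "C", "G", "T"), v[h]), 1L)
          if (!is.null(error_quality)) qs[hit] <- error_quality
          list(seq = paste(v, collapse = ""), qs = qs)
        }
        e1 <- add_err(s1, qs1); s1 <- e1$seq; qs1 <- e1$qs
        e2 <- add_err(s2, qs2); s2 <- e2$seq; qs2 <- e2$qs
      }
      r1[i] <- s1; r2[i] <- s2
      q1[i] <- intToUtf8(qs1 + 33L); q2[i] <- intToUtf8(qs2 + 33L)
    }
    net <- ifelse(edited,
                  ifelse(is.na(ins_size), 0L, ins_size) -
                    ifelse(is.na(del_size), 0L, del_size),
                  NA_integer_)
    truth <- data.frame(
      read_id = sprintf("%s_read_%05d", spec$amplicon_id,
                        seq_len(n_reads)),
      edited = edited, class = cls, ins_size = ins_size,
      del_size = del_size, net_indel = as.integer(net),
      stringsAsFactors = FALSE)
    list(r1 = r1, r2 = r2, q1 = q1, q2 = q2, truth = truth)
  })
}

#' Draw a synthetic amplicon reference with an embedded target site
#'
#' Generates a random amplicon containing a valid protospacer + PAM for
#' the nuclease, with the guide near the center. Candidates are
#' rejected unless (a) every programmed deletion placement (all sizes
#' up to `max_del`, all jitters) still overlaps the default cut window
#' after left-alignment, and (b) the sequence around the cut contains
#' no homopolymer run of 3+, nor period-2 or period-3 repeats, which
#' could let a left-aligned insertion migrate out of the window. This
#' makes the caller's programmed-frequency recovery exact on error-free
#' reads.
#'
#' @param amplicon_id Identifier.
#' @param nuclease `"cas9"` or `"cas12a"`.
#' @param length Amplicon length in nt.
#' @param seed Mandatory RNG seed.
#' @param max_del Largest deletion the screen must accommodate.
#' @param jitter Largest event jitter the screen must accommodate.
#' @param flank Cut-window flank assumed by the screen.
#' @return An [amplicon_spec()].
#' @export
synthetic_amplicon <- function(amplicon_id, nuclease = c("cas9", "cas12a"),
                               length = 240L, seed, max_del = 10L,
                               jitter = 2L, flank = 5L) {
  if (missing(seed)) stop("seed is mandatory")
  nuclease <- match.arg(nuclease)
  glen <- if (nuclease == "cas9") 20L else 23L
  gs <- (length - glen) %/% 2L
  with_seed(seed, {
    repeat {
      ref <- random_dna(length, gc = 0.4)
      # embed a concrete PAM so the locus is a real target site
      if (nuclease == "cas9") {
        ref <- splice_in(ref, gs + glen,
                         paste0(sample(c("A", "C", "G", "T"), 1L), "GG"))
      } else {
        ref <- splice_in(ref, gs - 4L,
                         paste0("TTT", sample(c("A", "C", "G"), 1L)))
      }
      spec <- amplicon_spec(amplicon_id, ref, gs, gs + glen, nuclease)
      cw <- cut_window_for(spec, flank)
      core <- cut_window_for(spec, 0L)
      center <- core$start + (core$end - core$start) %/% 2L
      ok <- TRUE
      for (s in seq_len(max_del)) {
        for (j in -jitter:jitter) {
          # centered placement (pure deletions) and right-of-cut
          # placement (mixed reads) must both stay in the window after
          # left-alignment
          for (dstart in c(center - s %/% 2L + j, center + 2L + j)) {
            la <- left_align_event("deletion", dstart, s, "", ref)
            if (!(la$position < cw$end && la$position + s > cw$start)) {
              ok <- FALSE; break
            }
          }
          if (!ok) break
        }
        if (!ok) break
      }
      region <- substr(ref, center - 11L, center + 7L)
      if (grepl("(.)\\1\\1", region) ||
          grepl("(..)\\1", region) ||
          grepl("(...)\\1", region)) ok <- FALSE
      if (ok) return(spec)
    }
  })
}

#' Write paired reads as FASTQ
#'
#' @param reads Result of [simulate_reads()].
#' @param prefix Output path prefix; writes `<prefix>_R1.fastq[.gz]`
#'   and `<prefix>_R2.fastq[.gz]`.
#' @param gzip Compress output.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pair <- function(reads, prefix, gzip = FALSE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_R1", "_R2"), ext)
  wr <- function(seqs, quals, path) {
    s <- Biostrings::DNAStringSet(seqs)
    names(s) <- reads$truth$read_id
    x <- Biostrings::QualityScaledDNAStringSet(
      s, Biostrings::PhredQuality(quals))
    Biostrings::writeQualityScaledXStringSet(x, path, compress = gzip)
  }
  wr(reads$r1, reads$q1, paths[1])
  wr(reads$r2, reads$q2, paths[2])
  invisible(paths)
}

#' Read a FASTQ file (gzip-transparent)
#'
#' @param path Path to a FASTQ file.
#' @return `list(ids=, seqs=, quals=)`.
#' @export
read_fastq <- function(path) {
  # the reader's benign note about dropped metadata columns is silenced
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  list(ids = names(x), seqs = unname(as.character(x)),
       quals = unname(as.character(Biostrings::quality(x))))
}
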