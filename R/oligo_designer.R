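# Golden-Gate spacer cloning: forward/reverse oligo pairs whose annealed
# duplex carries 4-nt 5' single-stranded ends matching the overhangs the
# type-IIS enzyme leaves in the backbone, plus an in-silico
# restriction-ligation check of the assembled junction.

GG_ENZYMES <- list(
  BsaI = list(site = "GGTCTC", spacing = 1L, overhang = 4L),
  BsmBI = list(site = "CGTCTC", spacing = 1L, overhang = 4L)
)

#' Cassette specification for spacer cloning
#'
#' Overhang and direct-repeat sequences are construct-specific and
#' must be supplied from the user's cassette catalog; the defaults here
#' are clearly labelled placeholders for testing only.
#'
#' @param cassette_id Identifier.
#' @param nuclease One of `cas9`, `as_cas12a`, `fn_cas12a`, `lb_cas12a`.
#' @param crRNA_form `"sgRNA"` (Cas9), `"mature"` or `"pre"` (Cas12a).
#' @param fwd_overhang,rev_overhang 4-nt 5' overhangs of the forward
#'   and reverse oligo.
#' @param enzyme `"BsaI"` or `"BsmBI"`.
#' @param direct_repeat Direct-repeat sequence (required for crRNA
#'   forms).
#' @return A list of class `cassette_spec`.
#' @export
cassette_spec <- function(cassette_id, nuclease, crRNA_form,
                          fwd_overhang = "ATTG", rev_overhang = "AAAC",
                          enzyme = c("BsaI", "BsmBI"),
                          direct_repeat = "") {
  enzyme <- match.arg(enzyme)
  nuclease <- match.arg(nuclease,
                        c("cas9", "as_cas12a", "fn_cas12a", "lb_cas12a"))
  crRNA_form <- match.arg(crRNA_form, c("sgRNA", "mature", "pre"))
  if (nchar(fwd_overhang) != 4L || nchar(rev_overhang) != 4L)
    stop("overhangs must be 4 nt")
  if (crRNA_form %in% c("mature", "pre") && !nzchar(direct_repeat))
    stop("crRNA cassettes require a direct_repeat sequence")
  structure(list(cassette_id = cassette_id, nuclease = nuclease,
                 crRNA_form = crRNA_form,
                 fwd_overhang = toupper(fwd_overhang),
                 rev_overhang = toupper(rev_overhang),
                 enzyme = enzyme, direct_repeat = toupper(direct_repeat)),
            class = "cassette_spec")
}

spacer_len_for_nuclease <- function(nuclease) {
  if (nuclease == "cas9") 20L else 23L
}

#' Validate a spacer for Golden-Gate cloning
#'
#' Checks: correct length for the nuclease (error), internal
#' recognition site of the cassette enzyme on either strand (error,
#' since it would be re-cut after ligation), and a T-homopolymer run of
#' 4 or more (warning: behaves as a PolIII terminator and can abort
#' guide transcription).
#'
#' @param spacer Spacer sequence over `{A,C,G,T}`.
#' @param nuclease Nuclease the spacer is for (see [cassette_spec()]).
#' @param enzyme Cloning enzyme whose site must be absent.
#' @return `data.frame` of findings with columns `level`
#'   (`error`/`warning`) and `message`; zero rows when clean.
#' @export
validate_spacer <- function(spacer, nuclease = "cas9", enzyme = "BsaI") {
  spacer <- toupper(spacer)
  if (grepl("[^ACGT]", spacer))
    stop("spacer contains non-ACGT characters")
  findings <- data.frame(level = character(), message = character(),
                         stringsAsFactors = FALSE)
  add <- function(level, msg) rbind(findings, data.frame(
    level = level, message = msg, stringsAsFactors = FALSE))
  want <- spacer_len_for_nuclease(nuclease)
  if (nchar(spacer) != want)
    findings <- add("error", sprintf(
      "spacer length %d differs from the %d nt expected for %s",
      nchar(spacer), want, nuclease))
  enz <- GG_ENZYMES[[enzyme]]
  if (grepl(enz$site, spacer, fixed = TRUE) ||
      grepl(revcomp(enz$site), spacer, fixed = TRUE))
    findings <- add("error", sprintf(
      "internal %s recognition site (%s)", enzyme, enz$site))
  if (grepl("TTTT", spacer, fixed = TRUE))
    findings <- add("warning",
                    "T homopolymer run >= 4 (possible PolIII terminator)")
  findings
}

#' Design a spacer oligo pair
#'
#' The forward oligo is `fwd_overhang + spacer`; the reverse oligo is
#' `rev_overhang + revcomp(spacer)`. Annealing the two leaves 4-nt 5'
#' single-stranded ends equal to the overhangs, ready for ligation into
#' the enzyme-digested backbone.
#'
#' @param spacer Spacer sequence (must pass [validate_spacer()] without
#'   errors; warnings are attached to the result).
#' @param cassette A [cassette_spec()].
#' @return A list of class `oligo_pair` with fields `fwd`, `rev`,
#'   `spacer`, and attribute `warnings`.
#' @export
design_oligos <- function(spacer, cassette) {
  spacer <- toupper(spacer)
  findings <- validate_spacer(spacer, cassette$nuclease, cassette$enzyme)
  errs <- findings$message[findings$level == "error"]
  if (length(errs)) stop("invalid spacer: ", paste(errs, collapse = "; "))
  structure(list(fwd = paste0(cassette$fwd_overhang, spacer),
                 rev = paste0(cassette$rev_overhang, revcomp(spacer)),
                 spacer = spacer),
            warnings = findings$message[findings$level == "warning"],
            class = "oligo_pair")
}

# 0-based recognition-site scan on both strands; returns data.frame
# (pos, orient) with orient "+" (cuts downstream) or "-" (cuts upstream)
find_enzyme_sites <- function(seq, enzyme) {
  enz <- GG_ENZYMES[[enzyme]]
  scan1 <- function(pat) {
    m <- gregexpr(pat, seq, fixed = TRUE)[[1]]
    p <- as.integer(m)
    if (length(p) == 1L && p == -1L) integer(0) else p - 1L
  }
  fwd <- scan1(enz$site)
  rev <- scan1(revcomp(enz$site))
  out <- data.frame(pos = c(fwd, rev),
                    orient = rep(c("+", "-"), c(length(fwd), length(rev))),
                    stringsAsFactors = FALSE)
  out[order(out$pos), , drop = FALSE]
}

#' Simulate Golden-Gate restriction-ligation of a spacer duplex
#'
#' The backbone must contain exactly two recognition sites of the
#' cassette enzyme, pointing outward from the stuffer so that digestion
#' excises the stuffer together with both recognition sites, leaving
#' 4-nt 5' overhangs on the vector ends. The spacer duplex is ligated
#' in when its overhangs match the vector's uniquely; the assembly
#' therefore carries no residual recognition site.
#'
#' @param oligo_pair An [design_oligos()] result.
#' @param backbone_seq Backbone (top strand, linear representation).
#' @param cassette The [cassette_spec()] the oligos were designed for.
#' @return Assembled top-strand sequence.
#' @export
simulate_ligation <- function(oligo_pair, backbone_seq, cassette) {
  backbone_seq <- toupper(backbone_seq)
  enz <- GG_ENZYMES[[cassette$enzyme]]
  sites <- find_enzyme_sites(backbone_seq, cassette$enzyme)
  if (nrow(sites) != 2L)
    stop("backbone must contain exactly 2 ", cassette$enzyme,
         " sites, found ", nrow(sites))
  if (!identical(sites$orient, c("-", "+")))
    stop("recognition sites must point outward from the stuffer")
  r1 <- sites$pos[1]; r2 <- sites$pos[2]
  # reverse site cuts upstream of itself, forward site downstream
  cut_left <- r1 - enz$spacing - enz$overhang   # top-strand cut, left
  cut_right <- r2 + nchar(enz$site) + enz$spacing  # top-strand cut, right
  if (cut_left < 0L || cut_right + enz$overhang > nchar(backbone_seq))
    stop("recognition sites cut outside the backbone")
  oh_left <- substr(backbone_seq, cut_left + 1L, cut_left + enz$overhang)
  oh_right <- substr(backbone_seq, cut_right + 1L,
                     cut_right + enz$overhang)
  fwd_oh <- substr(oligo_pair$fwd, 1L, enz$overhang)
  rev_oh <- substr(oligo_pair$rev, 1L, enz$overhang)
  if (oh_left == oh_right)
    stop("vector overhangs are identical: insert orientation ambiguous")
  if (oh_left != fwd_oh || oh_right != revcomp(rev_oh))
    stop("oligo overhangs do not complement the vector overhangs")
  paste0(substr(backbone_seq, 1L, cut_left),
         oligo_pair$fwd,  # fwd_overhang + spacer
         substr(backbone_seq, cut_right + 1L, nchar(backbone_seq)))
}

#' Build a toy Golden-Gate backbone around a stuffer
#'
#' Constructs a linear backbone `left | fwd_overhang | N |
#' revcomp(site) | stuffer | site | N | revcomp(rev_overhang) | right`
#' compatible with [simulate_ligation()] for the given cassette (the
#' two recognition sites point outward and are excised with the
#' stuffer). Intended for tests and synthetic fixtures.
#'
#' @param cassette A [cassette_spec()].
#' @param stuffer Stuffer sequence between the recognition sites.
#' @param left,right Flanking vector sequence.
#' @return Backbone top-strand string.
#' @export
make_test_backbone <- function(cassette, stuffer = "ATGCGTACGTTAGC",
                               left = "TGCACCTGCA", right = "GGATCCTAGG") {
  enz <- GG_ENZYMES[[cassette$enzyme]]
  paste0(left, cassette$fwd_overhang, "A", revcomp(enz$site), stuffer,
         enz$site, "A", revcomp(cassette$rev_overhang), right)
}
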