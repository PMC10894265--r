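# Discovery of loci carrying both a Cas12a and a Cas9 target site in the
# same-strand nested geometry 5'-TTTV . N20 . NGG-3' (27 nt): the Cas12a
# protospacer is the 23 nt downstream of the TTTV PAM, so its last three
# bases coincide with the Cas9 NGG PAM and its first 20 with the Cas9
# protospacer.

#' Overlap pattern specification
#'
#' Describes the dual-nuclease target geometry. The only built-in
#' geometry is `same_strand_nested`, in which the Cas9 PAM supplies
#' Cas12a spacer positions 21-23 and the combined site is
#' `nchar(cas12a_pam) + cas12a_spacer_len` nucleotides (27 by default).
#'
#' @param cas12a_pam IUPAC PAM 5' of the Cas12a protospacer.
#' @param cas9_pam IUPAC PAM 3' of the Cas9 protospacer.
#' @param cas12a_spacer_len Cas12a spacer length in nt.
#' @param cas9_spacer_len Cas9 spacer length in nt.
#' @param geometry Overlap geometry; only `"same_strand_nested"`.
#' @return A list of class `overlap_pattern_spec`.
#' @export
overlap_pattern_spec <- function(cas12a_pam = "TTTV", cas9_pam = "NGG",
                                 cas12a_spacer_len = 23L,
                                 cas9_spacer_len = 20L,
                                 geometry = "same_strand_nested") {
  geometry <- match.arg(geometry)
  cas12a_spacer_len <- as.integer(cas12a_spacer_len)
  cas9_spacer_len <- as.integer(cas9_spacer_len)
  if (cas12a_spacer_len <= 0L || cas9_spacer_len <= 0L)
    stop("spacer lengths must be positive")
  if (cas12a_spacer_len != cas9_spacer_len + nchar(cas9_pam))
    stop("nested geometry requires cas12a_spacer_len == ",
         "cas9_spacer_len + nchar(cas9_pam)")
  structure(list(cas12a_pam = cas12a_pam, cas9_pam = cas9_pam,
                 cas12a_spacer_len = cas12a_spacer_len,
                 cas9_spacer_len = cas9_spacer_len,
                 geometry = geometry),
            class = "overlap_pattern_spec")
}

site_length <- function(spec) {
  nchar(spec$cas12a_pam) + spec$cas12a_spacer_len
}

overlap_regex <- function(spec) {
  paste0(iupac_regex(spec$cas12a_pam),
         "([ACGT]{", spec$cas9_spacer_len, "})",
         iupac_regex(spec$cas9_pam))
}

empty_sites <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), gene_id = character(),
             cas9_spacer = character(), cas9_pam = character(),
             cas12a_spacer = character(), cas12a_pam = character(),
             stringsAsFactors = FALSE)
}

#' Scan one sequence for overlapping Cas9/Cas12a target sites
#'
#' All matches are reported, including mutually overlapping ones (the
#' scan advances one position at a time). `N` never matches any pattern
#' position, including the `N` slots of a PAM.
#'
#' @param seq Forward-strand DNA string of the scanned region.
#' @param offset 0-based forward-axis position of `seq[1]` in the
#'   genome; reported coordinates are on the forward axis.
#' @param strand Strand to scan: `"+"` scans `seq`, `"-"` scans its
#'   reverse complement (coordinates still forward-axis).
#' @param spec An [overlap_pattern_spec()].
#' @return Site `data.frame` (no `chrom`/`gene_id` columns) with the
#'   locus, strand and the Cas9/Cas12a protospacer and PAM sequences.
#' @export
scan_sequence <- function(seq, offset = 0L, strand = "+",
                          spec = overlap_pattern_spec()) {
  stopifnot(strand %in% c("+", "-"))
  slen <- site_length(spec)
  n <- nchar(seq)
  target <- if (strand == "-") revcomp(seq) else seq
  m <- gregexpr(paste0("(?=", overlap_regex(spec), ")"), target,
                perl = TRUE)[[1]]
  pos <- as.integer(m)
  if (length(pos) == 1L && pos == -1L) pos <- integer(0)
  pos <- pos - 1L  # 0-based offsets into `target`
  pos <- pos[pos + slen <= n]
  if (length(pos) == 0L) {
    out <- empty_sites()
    return(out[, setdiff(names(out), c("chrom", "gene_id"))])
  }
  sites <- substring(target, pos + 1L, pos + slen)
  p4 <- nchar(spec$cas12a_pam)
  s9 <- spec$cas9_spacer_len
  start <- if (strand == "+") offset + pos else offset + n - pos - slen
  data.frame(
    start = as.integer(start), end = as.integer(start + slen),
    strand = strand,
    cas9_spacer = substring(sites, p4 + 1L, p4 + s9),
    cas9_pam = substring(sites, p4 + s9 + 1L, slen),
    cas12a_spacer = substring(sites, p4 + 1L, slen),
    cas12a_pam = substring(sites, 1L, p4),
    stringsAsFactors = FALSE
  )
}

#' Identifier for an overlap site locus
#'
#' @param sites Site `data.frame` with `chrom`, `start`, `strand`.
#' @return Character vector `chrom:start:strand`.
#' @export
site_id <- function(sites) {
  paste(sites$chrom, sites$start, sites$strand, sep = ":")
}

#' Find overlapping target sites in the CDS of listed genes
#'
#' Scans both strands of every CDS interval of every listed gene. A site
#' is reported only when its full locus lies within a single CDS
#' interval. Duplicate loci (same position and strand, e.g. from
#' duplicated CDS rows) are reported once.
#'
#' @param genome Named character vector from [read_fasta()].
#' @param gene_models CDS interval table from [read_gff3()].
#' @param gene_ids Character vector of gene identifiers to scan; unknown
#'   identifiers produce a warning and are skipped.
#' @param spec An [overlap_pattern_spec()].
#' @return Site `data.frame` with columns `chrom`, `start`, `end`,
#'   `strand`, `gene_id`, `cas9_spacer`, `cas9_pam`, `cas12a_spacer`,
#'   `cas12a_pam`, sorted by locus.
#' @export
find_overlapping_sites <- function(genome, gene_models, gene_ids,
                                   spec = overlap_pattern_spec()) {
  missing <- setdiff(gene_ids, gene_models$gene_id)
  if (length(missing))
    warning("unknown gene id(s) skipped: ", paste(missing, collapse = ", "))
  gene_ids <- setdiff(gene_ids, missing)
  out <- list()
  for (gid in gene_ids) {
    cds <- gene_models[gene_models$gene_id == gid, , drop = FALSE]
    for (i in seq_len(nrow(cds))) {
      seq <- fetch_sequence(genome, list(chrom = cds$chrom[i],
                                         start = cds$start[i],
                                         end = cds$end[i], strand = "+"))
      for (strand in c("+", "-")) {
        hits <- scan_sequence(seq, offset = cds$start[i], strand = strand,
                              spec = spec)
        if (nrow(hits)) {
          hits$chrom <- cds$chrom[i]
          hits$gene_id <- gid
          out[[length(out) + 1L]] <- hits
        }
      }
    }
  }
  if (!length(out)) return(empty_sites())
  sites <- do.call(rbind, out)
  sites <- sites[, names(empty_sites())]
  sites <- sites[!duplicated(sites[, c("chrom", "start", "strand")]), ,
                 drop = FALSE]
  sites <- sites[order(sites$chrom, sites$start, sites$strand), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Count overlap sites per gene family
#'
#' Optionally also counts, per family, the sites that have at least one
#' predicted off-target site (excluding the on-target locus itself) for
#' both nucleases.
#'
#' @param sites Site table from [find_overlapping_sites()].
#' @param family_map Named character vector mapping gene id to family,
#'   or a `data.frame` with columns `gene_id` and `family`.
#' @param cas9_hits,cas12a_hits Optional off-target hit tables from
#'   [enumerate_offtargets()] whose `query_id` equals [site_id()] of the
#'   corresponding site.
#' @return `data.frame` with columns `family`, `n_sites`, and (when both
#'   hit tables are supplied) `n_with_offtargets_both`.
#' @export
count_sites_per_family <- function(sites, family_map,
                                   cas9_hits = NULL, cas12a_hits = NULL) {
  if (is.data.frame(family_map))
    family_map <- setNames(family_map$family, family_map$gene_id)
  if (nrow(sites) == 0L) {
    out <- data.frame(family = character(), n_sites = integer(),
                      stringsAsFactors = FALSE)
    if (!is.null(cas9_hits) && !is.null(cas12a_hits))
      out$n_with_offtargets_both <- integer()
    return(out)
  }
  fam <- unname(family_map[sites$gene_id])
  if (anyNA(fam)) stop("gene id(s) absent from family_map: ",
                       paste(unique(sites$gene_id[is.na(fam)]),
                             collapse = ", "))
  tab <- as.data.frame(table(family = fam), stringsAsFactors = FALSE)
  names(tab)[2] <- "n_sites"
  if (!is.null(cas9_hits) && !is.null(cas12a_hits)) {
    has_ot <- function(hits) {
      real <- hits[hits$n_mismatches > 0L | hits$bulge != "none", ,
                   drop = FALSE]
      unique(real$query_id)
    }
    both <- intersect(has_ot(cas9_hits), has_ot(cas12a_hits))
    with_both <- site_id(sites) %in% both
    tab$n_with_offtargets_both <-
      vapply(tab$family, function(f) sum(with_both[fam == f]), integer(1))
  }
  tab
}
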