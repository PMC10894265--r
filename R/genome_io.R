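#' @useDynLib casTandem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom utils read.table write.table
#' @importFrom stats setNames runif
NULL

# Internal coordinate convention: 0-based half-open on the forward genome
# axis, everywhere. GFF3 (1-based inclusive) is converted on read; BED6 is
# written natively.

IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Construct a genomic interval table
#'
#' Intervals are 0-based half-open on the forward axis; `strand` is
#' `"+"` or `"-"`.
#'
#' @param chrom Sequence identifiers.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions.
#' @param strand Strand, `"+"` or `"-"` (recycled).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(end <= start))
    stop("invalid interval: need 0 <= start < end")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and any character outside `{A,C,G,T,N}`
#' (including IUPAC ambiguity codes) is collapsed to `N`. `N` never
#' matches a PAM or spacer base downstream, so ambiguous sequence can
#' never spawn a target or off-target call.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase DNA string per record.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  seqs <- gsub("[^ACGTN]", "N", seqs)
  if (any(nchar(seqs) == 0L)) stop("empty sequence record in FASTA")
  setNames(seqs, ids)
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of DNA strings.
#' @param path Output path.
#' @param width Line width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read gene models (CDS intervals) from GFF3
#'
#' Keeps only rows whose feature type is `CDS`, converts the 1-based
#' inclusive GFF3 coordinates to the internal 0-based half-open
#' convention, and resolves each CDS to a gene identifier: the `gene_id`
#' or `gene` attribute when present, otherwise the first `Parent` with
#' any `mRNA:`/`transcript:`/`gene:` prefix stripped. Duplicate identical
#' intervals are removed; overlapping CDS intervals are kept unmerged.
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` of CDS intervals with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, in file order within gene.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(gr) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  mc <- S4Vectors::mcols(gr)
  gid <- rep(NA_character_, length(gr))
  for (field in c("gene_id", "gene")) {
    if (field %in% names(mc)) {
      v <- as.character(mc[[field]])
      gid[is.na(gid) & !is.na(v)] <- v[is.na(gid) & !is.na(v)]
    }
  }
  if ("Parent" %in% names(mc)) {
    par <- vapply(mc$Parent, function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1))
    par <- sub("^(mRNA|transcript|gene):", "", par)
    gid[is.na(gid)] <- par[is.na(gid)]
  }
  if (anyNA(gid))
    stop("CDS feature without resolvable gene identifier in ", path)
  out <- data.frame(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # GFF3 1-based -> 0-based
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (!all(out$strand %in% c("+", "-")))
    stop("CDS feature with missing strand in ", path)
  out[!duplicated(out), , drop = FALSE]
}

#' Read a plain-text gene-identifier list
#'
#' @param path Path to a text file, one gene identifier per line.
#' @return Character vector of identifiers (blank lines dropped).
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

#' Fetch a strand-aware subsequence
#'
#' @param genome Named character vector from [read_fasta()].
#' @param interval One-row interval `data.frame` (see
#'   [genomic_interval()]) or a list with fields `chrom`, `start`,
#'   `end`, `strand`.
#' @return DNA string of length `end - start`; reverse-complemented for
#'   strand `-`.
#' @export
fetch_sequence <- function(genome, interval) {
  chrom <- as.character(interval$chrom[1])
  start <- as.integer(interval$start[1])
  end <- as.integer(interval$end[1])
  strand <- as.character(interval$strand[1])
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- nchar(genome[[chrom]])
  if (start < 0L || end > len || start >= end)
    stop("interval [", start, ",", end, ") outside chromosome ", chrom,
         " of length ", len)
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

#' Write intervals as BED6
#'
#' Columns: chrom, start, end, name, score, strand; 0-based half-open.
#'
#' @param intervals Interval `data.frame`; an optional `name` column is
#'   used for column 4, otherwise ".".
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(intervals)) intervals$name else "."
  bed <- data.frame(intervals$chrom, intervals$start, intervals$end,
                    name, ".", intervals$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file into an interval table
#'
#' @param path Path to a BED file written by [write_bed()].
#' @return Interval `data.frame` with columns `chrom`, `start`, `end`,
#'   `strand`, `name`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      name = character(), stringsAsFactors = FALSE))
  b <- read.table(path, sep = "\t", header = FALSE,
                  colClasses = c("character", "integer", "integer",
                                 "character", "character", "character"))
  data.frame(chrom = b[[1]], start = b[[2]], end = b[[3]],
             strand = b[[6]], name = b[[4]], stringsAsFactors = FALSE)
}

#' Write a table as TSV
#'
#' @param x A `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# IUPAC code -> regex character class (N deliberately excluded from every
# class so masked genome sequence never matches).
iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_MAP))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ""))
  paste0(vapply(chars, function(ch) {
    opts <- IUPAC_MAP[[ch]]
    if (nchar(opts) == 1L) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
}

# Does `seq` match IUPAC `pattern` exactly (same length)? N never matches.
iupac_match <- function(seq, pattern) {
  if (nchar(seq) != nchar(pattern)) return(FALSE)
  grepl(paste0("^", iupac_regex(pattern), "$"), seq)
}
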