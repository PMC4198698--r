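# Pileup extraction. Two alignment-source kinds are supported:
#
#  * the plain-text pileup dialect used for fixtures: a header-bearing TSV
#    with columns chrom, pos, ref, bases, quals — `bases` a string of base
#    characters and `quals` comma-separated phred integers, one per base;
#  * indexed BAM, read through Rsamtools/GenomicAlignments (Suggests).
#
# All public coordinates are 1-based inclusive (VCF convention).

#' Open an alignment source
#'
#' @param path path to a pileup TSV (`.tsv`/`.pileup`/`.txt`) or an indexed
#'   BAM (`.bam`).
#' @return an object of class `fv_pileup_source` or `fv_bam_source`.
#' @export
alignment_source <- function(path) {
  if (!file.exists(path)) fv_stop("fv_io", sprintf("no such alignment source: '%s'", path))
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      fv_stop("fv_dependency", "BAM support needs Rsamtools/GenomicAlignments")
    return(structure(list(path = path), class = "fv_bam_source"))
  }
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character", pos = "integer",
                                   ref = "character", bases = "character",
                                   quals = "character"))
  need <- c("chrom", "pos", "ref", "bases", "quals")
  if (!all(need %in% names(tab)))
    fv_stop("fv_io", sprintf("pileup fixture '%s' lacks columns: %s", path,
                             paste(setdiff(need, names(tab)), collapse = ", ")))
  structure(list(path = path, table = tab), class = "fv_pileup_source")
}

#' Extract the pileup column over one position
#'
#' Returns every aligned, mapped, non-duplicate base overlapping the position
#' with base quality at or above `min_base_qual`; deletions and reference
#' skips are excluded. By default no quality filtering is applied
#' (`min_base_qual = 0`).
#'
#' @param src an alignment source from [alignment_source()].
#' @param chrom contig name.
#' @param pos 1-based position.
#' @param min_base_qual minimum phred base quality (default 0: keep all).
#' @return list of class `fv_pileup_column` with fields `chrom`, `pos`,
#'   `ref_base`, `bases` (character vector), `quals` (integer vector), and
#'   `flag` (`""`, or `"contig_missing"` when the contig is absent).
#' @export
pileup_at <- function(src, chrom, pos, min_base_qual = 0) {
  UseMethod("pileup_at")
}

new_pileup_column <- function(chrom, pos, ref_base, bases, quals, flag = "") {
  stopifnot(length(bases) == length(quals), all(quals >= 0))
  structure(list(chrom = chrom, pos = as.integer(pos), ref_base = ref_base,
                 bases = bases, quals = as.integer(quals), flag = flag),
            class = "fv_pileup_column")
}

#' @export
pileup_at.fv_pileup_source <- function(src, chrom, pos, min_base_qual = 0) {
  tab <- src$table
  if (!chrom %in% tab$chrom)
    return(new_pileup_column(chrom, pos, "N", character(), integer(), "contig_missing"))
  hit <- tab[tab$chrom == chrom & tab$pos == pos, , drop = FALSE]
  if (nrow(hit) == 0L)
    return(new_pileup_column(chrom, pos, "N", character(), integer()))
  bases <- strsplit(hit$bases[1L], "")[[1L]]
  quals <- if (nzchar(hit$quals[1L])) as.integer(strsplit(hit$quals[1L], ",")[[1L]]) else integer()
  if (length(bases) != length(quals))
    fv_stop("fv_io", sprintf("pileup row %s:%d has %d bases but %d quals",
                             chrom, pos, length(bases), length(quals)))
  keep <- quals >= min_base_qual
  new_pileup_column(chrom, pos, hit$ref[1L], bases[keep], quals[keep])
}

#' @export
pileup_at.fv_bam_source <- function(src, chrom, pos, min_base_qual = 0) {
  bf <- Rsamtools::BamFile(src$path)
  contigs <- names(Rsamtools::scanBamHeader(bf)$targets)
  if (!chrom %in% contigs)
    return(new_pileup_column(chrom, pos, "N", character(), integer(), "contig_missing"))
  region <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isDuplicate = FALSE),
    which = region)
  seqs <- GenomicAlignments::stackStringsFromBam(
    bf, param = param, what = "seq", D.letter = "-", N.letter = "-")
  qs <- GenomicAlignments::stackStringsFromBam(
    bf, param = param, what = "qual", D.letter = " ", N.letter = " ")
  if (length(seqs) == 0L)
    return(new_pileup_column(chrom, pos, "N", character(), integer()))
  bases <- substring(as.character(seqs), 1L, 1L)
  quals <- as.integer(charToRaw(paste(substring(as.character(qs), 1L, 1L), collapse = ""))) - 33L
  keep <- bases %in% c("A", "C", "G", "T", "N") & quals >= min_base_qual
  new_pileup_column(chrom, pos, "N", bases[keep], quals[keep])
}

#' @export
print.fv_pileup_column <- function(x, ...) {
  cat(sprintf("<pileup %s:%d ref=%s depth=%d%s>\n", x$chrom, x$pos, x$ref_base,
              length(x$bases), if (nzchar(x$flag)) paste0(" ", x$flag) else ""))
  invisible(x)
}

#' Read a reference lookup table
#'
#' Fixtures carry reference bases as a TSV (`chrom`, `pos`, `ref`) rather
#' than a full genome FASTA. For real deployments [reference_from_fasta()]
#' builds the same table from a FASTA over a set of positions.
#'
#' @param path TSV path.
#' @return data.frame with columns chrom, pos, ref.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path))
    fv_stop("fv_io", sprintf("no such reference table: '%s'", path))
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character", pos = "integer", ref = "character"))
  if (!all(c("chrom", "pos", "ref") %in% names(tab)))
    fv_stop("fv_io", "reference table needs columns chrom, pos, ref")
  tab
}

#' @rdname read_reference_table
#' @param fasta_path FASTA file.
#' @param positions data.frame with chrom, pos (1-based).
#' @export
reference_from_fasta <- function(fasta_path, positions) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    fv_stop("fv_dependency", "FASTA support needs Biostrings")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ref <- vapply(seq_len(nrow(positions)), function(i) {
    as.character(Biostrings::subseq(seqs[[positions$chrom[i]]],
                                    positions$pos[i], positions$pos[i]))
  }, character(1))
  data.frame(chrom = positions$chrom, pos = positions$pos, ref = ref,
             stringsAsFactors = FALSE)
}

ref_base_at <- function(ref_table, chrom, pos) {
  hit <- ref_table$ref[ref_table$chrom == chrom & ref_table$pos == pos]
  if (length(hit) == 0L) "N" else hit[1L]
}
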