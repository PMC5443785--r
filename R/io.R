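# Readers and writers for the standard formats.
#
# Internal coordinates are 0-based half-open; conversion happens at the
# I/O boundary (BED/bedGraph stay 0-based half-open, GFF3 is 1-based
# inclusive). Writers emit sorted, deterministic output.

#' Read a FASTA file
#' @param path FASTA file (plain or gzipped).
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write sequences to FASTA
#' @param seqs Named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a GFF3 gene annotation
#' @param path GFF3 file.
#' @return A `GRanges` suitable for [region_model()].
#' @export
read_gff3 <- function(path) rtracklayer::import(path, format = "gff3")

#' Write GFF3-style features
#' @param gr `GRanges` with `type`, `ID`, `Parent` metadata columns (as
#'   produced by [simulate_genome()]).
#' @param path Output path.
#' @export
write_gff3 <- function(gr, path) {
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a BED file of intervals
#' @param path BED file (3+ columns).
#' @return Data.frame `chrom`, `start`, `end` (0-based half-open), plus
#'   `name`, `score`, `strand` when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = BiocGenerics::start(gr) - 1L,
                    end = BiocGenerics::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' Write an SSR catalogue as BED6+1
#'
#' Columns: chrom, start, end, name (canonical motif), score (repeat
#' count), strand (`+`), period.
#'
#' @param catalogue Catalogue data.frame.
#' @param path Output path.
#' @export
write_catalogue_bed <- function(catalogue, path) {
  df <- catalogue[order(catalogue$chrom, catalogue$start,
                        method = "radix"), , drop = FALSE]
  data.table::fwrite(
    data.frame(df$chrom, df$start, df$end, df$motif, df$repeat_count,
               "+", df$period),
    path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED6+1 SSR catalogue written by [write_catalogue_bed()]
#' @param path BED file.
#' @return Catalogue data.frame with `locus` ids.
#' @export
read_catalogue_bed <- function(path) {
  df <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "motif",
                                        "repeat_count", "strand",
                                        "period"),
                          data.table = FALSE)
  out <- data.frame(chrom = df$chrom, start = as.integer(df$start),
                    end = as.integer(df$end), motif = df$motif,
                    period = as.integer(df$period),
                    repeat_count = as.integer(df$repeat_count),
                    ref_len = as.integer(df$end - df$start),
                    stringsAsFactors = FALSE)
  out$locus <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out
}

#' Read a genotype table
#'
#' Expects a tab-separated file with header columns `sample`, `locus`,
#' `allele_a`, `allele_b`, `q`, `reads`. With `offsets = TRUE` the
#' allele columns hold length offsets from the reference tract (the
#' lobSTR convention) and are converted to absolute bp lengths using the
#' catalogue's `ref_len`.
#'
#' @param path TSV file.
#' @param offsets Are allele columns offsets from the reference?
#' @param catalogue Catalogue data.frame, required when `offsets = TRUE`.
#' @return Genotype data.frame (see [locus_stats()]).
#' @export
read_genotypes <- function(path, offsets = FALSE, catalogue = NULL) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  need <- c("sample", "locus", "allele_a", "allele_b", "q", "reads")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("genotype file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (offsets) {
    if (is.null(catalogue))
      stop("offsets mode needs the catalogue for reference lengths")
    ref <- catalogue$ref_len[match(df$locus, catalogue$locus)]
    if (anyNA(ref)) stop("genotyped locus absent from catalogue")
    df$allele_a <- ref + df$allele_a
    df$allele_b <- ref + df$allele_b
  }
  .check_calls(df[, need])
}

#' Write a genotype table
#' @param calls Genotype data.frame.
#' @param path Output path.
#' @export
write_genotypes <- function(calls, path) {
  calls <- calls[order(calls$sample, calls$locus), , drop = FALSE]
  data.table::fwrite(calls, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a bedGraph score track
#' @param path bedGraph file.
#' @return Data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             value = gr$score, stringsAsFactors = FALSE)
}

#' Write a bedGraph score track
#' @param track Data.frame `chrom`, `start`, `end`, `value` (0-based
#'   half-open).
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  track <- track[order(track$chrom, track$start), , drop = FALSE]
  data.table::fwrite(track[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract indel intervals from a VCF
#'
#' Keeps records where any alternate allele differs in length from the
#' reference allele; the interval spans the reference allele footprint.
#'
#' @param path VCF file (plain or bgzipped).
#' @return Data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
read_vcf_indels <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (length(ln) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  f <- data.table::tstrsplit(ln, "\t", fixed = TRUE)
  chrom <- f[[1L]]; pos <- as.integer(f[[2L]])
  ref <- f[[4L]]; alt <- f[[5L]]
  is_indel <- mapply(function(r, a) {
    any(nchar(strsplit(a, ",", fixed = TRUE)[[1L]]) != nchar(r))
  }, ref, alt, USE.NAMES = FALSE)
  out <- data.frame(chrom = chrom[is_indel],
                    start = pos[is_indel] - 1L,
                    end = pos[is_indel] - 1L + nchar(ref[is_indel]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a square PHYLIP distance matrix
#' @param d Symmetric matrix with row names.
#' @param path Output path.
#' @export
write_phylip_dist <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(c(formatC(rownames(d)[i], width = -10),
                       sprintf("%.6f", d[i, ])), collapse = "  "), con)
  invisible(path)
}

#' Write a tree in Newick format
#' @param tree `ape::phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file.
#' @return `ape::phylo`.
#' @export
read_newick <- function(path) ape::read.tree(path)
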