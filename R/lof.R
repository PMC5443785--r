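# Loss-of-function classification of pSSR alleles.
#
# A non-reference allele of a repeat locus is a frameshift candidate
# when the tract overlaps a transcript's CDS and the length change is
# not a multiple of 3; a splice candidate when the tract overlaps the
# 2 bp donor (intron 5' end) or acceptor (intron 3' end) core site; an
# in-frame change when it overlaps CDS with a multiple-of-3 delta.
# Consequences are assigned per (allele, transcript) with the priority
# frameshift > splice > inframe > none.

.splice_sites <- function(model) {
  rows <- list()
  for (id in names(model$introns)) {
    intr <- model$introns[[id]]
    if (length(intr) == 0L) next
    strand_i <- model$transcripts$strand[
      match(id, model$transcripts$tx_id)]
    s <- BiocGenerics::start(intr); e <- BiocGenerics::end(intr)
    ord <- order(s)
    s <- s[ord]; e <- e[ord]
    for (k in seq_along(s)) {
      if (strand_i == "-") {
        donor <- c(e[k] - 1L, e[k]); acceptor <- c(s[k], s[k] + 1L)
        intron_index <- length(s) - k + 1L
      } else {
        donor <- c(s[k], s[k] + 1L); acceptor <- c(e[k] - 1L, e[k])
        intron_index <- k
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tx_id = id,
        chrom = as.character(GenomicRanges::seqnames(intr))[1L],
        site = c("splice_donor", "splice_acceptor"),
        start1 = c(donor[1L], acceptor[1L]),
        end1 = c(donor[2L], acceptor[2L]),
        intron_index = intron_index, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(tx_id = character(), chrom = character(),
                      site = character(), start1 = integer(),
                      end1 = integer(), intron_index = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

.lof_cache <- function(model) {
  cds_rows <- list()
  for (id in names(model$cds)) {
    cd <- model$cds[[id]]
    if (length(cd) == 0L) next
    cds_rows[[length(cds_rows) + 1L]] <- data.frame(
      tx_id = id, chrom = as.character(GenomicRanges::seqnames(cd)),
      start1 = BiocGenerics::start(cd), end1 = BiocGenerics::end(cd),
      stringsAsFactors = FALSE)
  }
  cds <- if (length(cds_rows)) do.call(rbind, cds_rows) else
    data.frame(tx_id = character(), chrom = character(),
               start1 = integer(), end1 = integer(),
               stringsAsFactors = FALSE)
  ss <- .splice_sites(model)
  list(cds = cds,
       cds_gr = GenomicRanges::GRanges(
         cds$chrom, IRanges::IRanges(cds$start1, cds$end1)),
       ss = ss,
       ss_gr = GenomicRanges::GRanges(
         ss$chrom, IRanges::IRanges(ss$start1, ss$end1)))
}

#' Classify alleles of one locus for loss-of-function potential
#'
#' @param locus One-row catalogue data.frame (or the catalogue plus a
#'   `locus_id` to pick the row).
#' @param alleles Integer vector of observed allele tract lengths in bp;
#'   must include the reference length.
#' @param model A [region_model()].
#' @param locus_id Optional locus id when `locus` has several rows.
#' @param cache Precomputed feature tables from an internal helper;
#'   supplied automatically by [lof_screen()] when screening many loci.
#' @return Data.frame with one row per (non-reference allele,
#'   overlapping transcript): `locus`, `allele`, `delta`, `tx_id`,
#'   `consequence` in `{frameshift, splice_donor, splice_acceptor,
#'   inframe, none}`, `detail`. Loci overlapping no transcript yield
#'   consequence `none` with `tx_id` `NA`.
#' @export
classify_lof <- function(locus, alleles, model, locus_id = NULL,
                         cache = NULL) {
  if (!is.null(locus_id)) locus <- locus[locus$locus == locus_id, ,
                                         drop = FALSE]
  if (nrow(locus) != 1L) stop("locus must identify exactly one row")
  if (any(alleles < locus$period))
    stop("invalid allele: shorter than one repeat unit")
  ref <- locus$ref_len
  if (!ref %in% alleles)
    stop("alleles must include the reference length ", ref)
  alt <- sort(unique(alleles[alleles != ref]))
  if (is.null(cache)) cache <- .lof_cache(model)
  lgr <- .gr_from_df(locus)
  cds_tx <- unique(cache$cds$tx_id[
    IRanges::overlapsAny(cache$cds_gr, lgr, ignore.strand = TRUE)])
  ss_hit <- cache$ss[IRanges::overlapsAny(cache$ss_gr, lgr), ,
                     drop = FALSE]
  rows <- list()
  all_tx <- union(cds_tx, unique(ss_hit$tx_id))
  for (a in alt) {
    delta <- a - ref
    for (id in all_tx) {
      # one consequence per (allele, transcript):
      # frameshift > splice > inframe
      if (id %in% cds_tx && delta %% 3L != 0L) {
        cons <- "frameshift"
        detail <- sprintf("CDS length change %+d bp", delta)
      } else if (id %in% ss_hit$tx_id) {
        k <- which(ss_hit$tx_id == id)[1L]
        cons <- ss_hit$site[k]
        detail <- sprintf("overlaps %s of intron %d",
                          sub("splice_", "", cons),
                          ss_hit$intron_index[k])
      } else {
        cons <- "inframe"
        detail <- sprintf("CDS length change %+d bp", delta)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus = locus$locus, allele = a, delta = delta, tx_id = id,
        consequence = cons, detail = detail, stringsAsFactors = FALSE)
    }
    if (length(all_tx) == 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = locus$locus, allele = a, delta = delta,
        tx_id = NA_character_, consequence = "none", detail = "",
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(locus = character(), allele = integer(),
                      delta = integer(), tx_id = character(),
                      consequence = character(), detail = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen a catalogue of genotyped loci for loss-of-function alleles
#'
#' Runs [classify_lof()] over every locus in `loci`, taking observed
#' alleles from the `allele_freqs` column of a [locus_stats()] table.
#'
#' @param catalogue Catalogue data.frame.
#' @param stats A [locus_stats()] data.frame.
#' @param model A [region_model()].
#' @param loci Locus ids to screen (default: all loci in `stats`).
#' @return Combined data.frame of all non-`none` calls.
#' @export
lof_screen <- function(catalogue, stats, model, loci = stats$locus) {
  cache <- .lof_cache(model)
  rows <- list()
  for (id in loci) {
    st <- stats[stats$locus == id, , drop = FALSE]
    if (nrow(st) == 0L) next
    crow <- catalogue[catalogue$locus == id, , drop = FALSE]
    alleles <- unique(c(crow$ref_len,
                        as.integer(names(st$allele_freqs[[1L]]))))
    calls <- classify_lof(crow, alleles, model, cache = cache)
    calls <- calls[calls$consequence != "none", , drop = FALSE]
    if (nrow(calls) > 0L) rows[[length(rows) + 1L]] <- calls
  }
  if (length(rows) == 0L)
    return(data.frame(locus = character(), allele = integer(),
                      delta = integer(), tx_id = character(),
                      consequence = character(), detail = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
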