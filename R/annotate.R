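# Genomic-region annotation of SSR loci.
#
# A gene annotation (GFF3) is decomposed per transcript into CDS, 5'UTR,
# 3'UTR, non-coding exon, intron and promoter intervals; each locus is
# then classified with the priority
#   CDS > UTR5 > UTR3 > exon_noncoding > promoter > intron > intergenic.
# The promoter is the 2 kb immediately upstream of the transcription
# start site, strand-aware, clipped at the chromosome start. A locus
# hitting several transcripts with conflicting labels is flagged
# multi-transcript rather than silently resolved.

.gr_from_df <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

#' Build a region model from a gene annotation
#'
#' Parses transcripts (`mRNA`/`transcript` features), their exons and CDS
#' from a GFF3 file and derives per-transcript intron, 5'UTR, 3'UTR and
#' promoter intervals. UTRs are the exonic bases outside the CDS, split
#' by strand-aware position relative to the CDS; introns are the gaps
#' between consecutive exons; the promoter covers `promoter_width` bp
#' upstream of the TSS.
#'
#' @param gff Path to a GFF3 file, or a `GRanges` as returned by
#'   `rtracklayer::import`.
#' @param promoter_width Promoter length in bp upstream of the TSS
#'   (default 2000).
#' @param chrom_lengths Optional named vector used to clip promoters at
#'   chromosome ends.
#' @return An object of class `region_model`: a list with `transcripts`
#'   (data.frame: `tx_id`, `gene_id`, `chrom`, `strand`, `coding`) and
#'   named `GRangesList`s `exons`, `cds`, `utr5`, `utr3`, `introns`, plus
#'   a `GRanges` `promoter` (one per transcript).
#' @export
region_model <- function(gff, promoter_width = 2000L,
                         chrom_lengths = NULL) {
  gr <- if (methods::is(gff, "GRanges")) gff else
    rtracklayer::import(gff, format = "gff3")
  type <- as.character(gr$type)
  tx <- gr[type %in% c("mRNA", "transcript")]
  if (length(tx) == 0L) {
    model <- list(transcripts = data.frame(tx_id = character(),
                                           gene_id = character(),
                                           chrom = character(),
                                           strand = character(),
                                           coding = logical()),
                  exons = GenomicRanges::GRangesList(),
                  cds = GenomicRanges::GRangesList(),
                  utr5 = GenomicRanges::GRangesList(),
                  utr3 = GenomicRanges::GRangesList(),
                  introns = GenomicRanges::GRangesList(),
                  promoter = GenomicRanges::GRanges())
    class(model) <- "region_model"
    return(model)
  }
  tx_id <- as.character(tx$ID)
  parent_of <- function(feat) {
    p <- feat$Parent
    vapply(as.list(p), function(z) as.character(z)[1L], character(1L))
  }
  exons_all <- gr[type == "exon"]
  cds_all <- gr[type == "CDS"]
  exon_parent <- parent_of(exons_all)
  cds_parent <- parent_of(cds_all)

  exons <- list(); cds <- list(); utr5 <- list(); utr3 <- list()
  introns <- list()
  prom_start <- integer(length(tx)); prom_end <- integer(length(tx))
  coding <- logical(length(tx))
  for (i in seq_along(tx)) {
    id <- tx_id[i]
    strand_i <- as.character(BiocGenerics::strand(tx[i]))
    ex <- GenomicRanges::reduce(exons_all[exon_parent == id])
    if (length(ex) == 0L)   # transcript without exon children: itself exonic
      ex <- GenomicRanges::granges(tx[i])
    cd <- GenomicRanges::reduce(cds_all[cds_parent == id])
    if (length(cd) > 0L) {
      uncovered <- GenomicRanges::setdiff(cd, GenomicRanges::intersect(cd, ex))
      if (sum(BiocGenerics::width(uncovered)) > 0L)
        stop("malformed annotation: CDS of transcript '", id,
             "' not contained in its exons")
    }
    coding[i] <- length(cd) > 0L
    intr <- GenomicRanges::setdiff(range(ex), ex)
    u5 <- GenomicRanges::GRanges(); u3 <- GenomicRanges::GRanges()
    if (coding[i]) {
      utr <- GenomicRanges::setdiff(ex, cd)
      cds_lo <- min(BiocGenerics::start(cd))
      cds_hi <- max(BiocGenerics::end(cd))
      # split any UTR interval straddling the CDS bounds
      utr_up <- IRanges::restrict(utr, end = cds_lo - 1L)
      utr_dn <- IRanges::restrict(utr, start = cds_hi + 1L)
      if (strand_i == "-") { u5 <- utr_dn; u3 <- utr_up }
      else { u5 <- utr_up; u3 <- utr_dn }
    }
    tss <- if (strand_i == "-") BiocGenerics::end(tx[i]) else
      BiocGenerics::start(tx[i])
    if (strand_i == "-") {
      prom_start[i] <- tss + 1L
      prom_end[i] <- tss + promoter_width
      if (!is.null(chrom_lengths)) {
        cl <- chrom_lengths[[as.character(GenomicRanges::seqnames(tx[i]))]]
        if (!is.null(cl)) prom_end[i] <- min(prom_end[i], cl)
      }
    } else {
      prom_start[i] <- max(1L, tss - promoter_width)
      prom_end[i] <- tss - 1L
    }
    exons[[id]] <- ex; cds[[id]] <- cd
    utr5[[id]] <- u5; utr3[[id]] <- u3; introns[[id]] <- intr
  }
  prom_ok <- prom_end >= prom_start
  promoter <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(tx)),
    IRanges::IRanges(pmax(prom_start, 1L), pmax(prom_end, 0L)))[prom_ok]
  names(promoter) <- tx_id[prom_ok]
  model <- list(
    transcripts = data.frame(
      tx_id = tx_id,
      gene_id = parent_of(tx),
      chrom = as.character(GenomicRanges::seqnames(tx)),
      strand = as.character(BiocGenerics::strand(tx)),
      coding = coding, stringsAsFactors = FALSE),
    exons = GenomicRanges::GRangesList(exons),
    cds = GenomicRanges::GRangesList(cds),
    utr5 = GenomicRanges::GRangesList(utr5),
    utr3 = GenomicRanges::GRangesList(utr3),
    introns = GenomicRanges::GRangesList(introns),
    promoter = promoter)
  class(model) <- "region_model"
  model
}

.REGION_PRIORITY <- c("CDS", "UTR5", "UTR3", "exon_noncoding",
                      "promoter", "intron", "intergenic")

.tx_feature_table <- function(model) {
  # flat table of (tx_id, label, chrom, start1, end1) over genic features
  pieces <- list()
  for (lab in c("CDS", "UTR5", "UTR3", "exon_noncoding", "intron")) {
    grl <- switch(lab, CDS = model$cds, UTR5 = model$utr5,
                  UTR3 = model$utr3, intron = model$introns,
                  exon_noncoding = model$exons)
    ids <- names(grl)
    if (lab == "exon_noncoding")   # exons count as such only when no CDS
      ids <- ids[!model$transcripts$coding[match(ids, model$transcripts$tx_id)]]
    for (id in ids) {
      g <- grl[[id]]
      if (length(g) == 0L) next
      pieces[[length(pieces) + 1L]] <- data.frame(
        tx_id = id, label = lab,
        chrom = as.character(GenomicRanges::seqnames(g)),
        start1 = BiocGenerics::start(g), end1 = BiocGenerics::end(g),
        stringsAsFactors = FALSE)
    }
  }
  pr <- model$promoter
  if (length(pr) > 0L)
    pieces[[length(pieces) + 1L]] <- data.frame(
      tx_id = names(pr), label = "promoter",
      chrom = as.character(GenomicRanges::seqnames(pr)),
      start1 = BiocGenerics::start(pr), end1 = BiocGenerics::end(pr),
      stringsAsFactors = FALSE)
  if (length(pieces) == 0L)
    return(data.frame(tx_id = character(), label = character(),
                      chrom = character(), start1 = integer(),
                      end1 = integer(), stringsAsFactors = FALSE))
  do.call(rbind, pieces)
}

#' Classify SSR loci into genomic regions
#'
#' For each locus and each transcript it touches, the per-transcript
#' label follows the priority CDS > UTR5 > UTR3 > non-coding exon >
#' intron, with `promoter` assigned when the locus intersects the
#' promoter interval but no exonic/intronic feature of that transcript.
#' The summary label takes the highest-priority label over all
#' transcripts (promoter outranks intron only in the absence of any
#' genic hit of higher priority; see Details) and is `intergenic` when no
#' transcript or promoter is hit.
#'
#' @details The summary priority is CDS > UTR5 > UTR3 > exon_noncoding >
#'   promoter > intron > intergenic. Loci hitting more than one
#'   transcript with conflicting per-transcript labels are flagged in
#'   `multi_transcript`.
#'
#' @param catalogue Catalogue data.frame with a `locus` column.
#' @param model A [region_model()].
#' @return A list with `calls` (per-locus: `locus`, `label`,
#'   `n_transcripts_hit`, `multi_transcript`) and `by_transcript`
#'   (per locus x transcript labels).
#' @export
classify_region <- function(catalogue, model) {
  stopifnot(inherits(model, "region_model"))
  n <- nrow(catalogue)
  feats <- .tx_feature_table(model)
  loci_gr <- .gr_from_df(catalogue)
  if (nrow(feats) > 0L) {
    fgr <- GenomicRanges::GRanges(feats$chrom,
                                  IRanges::IRanges(feats$start1, feats$end1))
    hits <- GenomicRanges::findOverlaps(loci_gr, fgr)
    ht <- data.frame(li = S4Vectors::queryHits(hits),
                     tx_id = feats$tx_id[S4Vectors::subjectHits(hits)],
                     label = feats$label[S4Vectors::subjectHits(hits)],
                     stringsAsFactors = FALSE)
  } else {
    ht <- data.frame(li = integer(), tx_id = character(),
                     label = character(), stringsAsFactors = FALSE)
  }
  # per (locus, transcript): best label; promoter only if nothing genic
  by_tx <- unique(ht)
  if (nrow(by_tx) > 0L) {
    by_tx$rank <- match(by_tx$label, .REGION_PRIORITY)
    dt <- data.table::as.data.table(by_tx)
    by_tx <- as.data.frame(
      dt[, .SD[which.min(rank)], by = c("li", "tx_id")])
    by_tx <- by_tx[order(by_tx$li, by_tx$tx_id), , drop = FALSE]
  } else {
    by_tx$rank <- integer()
  }
  label <- rep("intergenic", n)
  n_tx <- integer(n)
  multi <- logical(n)
  if (nrow(by_tx) > 0L) {
    sp <- split(by_tx, by_tx$li)
    for (s in sp) {
      i <- s$li[1L]
      label[i] <- .REGION_PRIORITY[min(s$rank)]
      genic <- s$label != "promoter"
      n_tx[i] <- sum(genic)
      multi[i] <- length(unique(s$label[genic])) > 1L
    }
  }
  calls <- data.frame(locus = catalogue$locus, label = label,
                      n_transcripts_hit = n_tx,
                      multi_transcript = multi, stringsAsFactors = FALSE)
  by_transcript <- data.frame(
    locus = catalogue$locus[by_tx$li], tx_id = by_tx$tx_id,
    label = by_tx$label, stringsAsFactors = FALSE)
  list(calls = calls, by_transcript = by_transcript)
}

.region_union <- function(model, chrom_lengths) {
  # genome-wide disjoint union per region class (1-based, unstranded)
  take <- function(grl) {
    g <- unlist(grl, use.names = FALSE)
    BiocGenerics::strand(g) <- "*"
    GenomicRanges::reduce(g)
  }
  nc_ids <- model$transcripts$tx_id[!model$transcripts$coding]
  out <- list(
    CDS = take(model$cds),
    UTR5 = take(model$utr5),
    UTR3 = take(model$utr3),
    exon_noncoding = take(model$exons[
      names(model$exons) %in% nc_ids]),
    intron = take(model$introns),
    promoter = GenomicRanges::reduce(
      `names<-`(model$promoter, NULL)))
  genome <- GenomicRanges::GRanges(
    names(chrom_lengths),
    IRanges::IRanges(1L, as.integer(chrom_lengths)))
  genic <- GenomicRanges::reduce(do.call(c, unname(out)))
  out$intergenic <- if (length(genic)) GenomicRanges::setdiff(genome, genic)
    else genome
  out
}

#' SSR density per genomic region class and period
#'
#' Density of each region class is the SSR bp overlapping that class
#' divided by the class's total bp, reported in bp/Mb. Region classes are
#' genome-wide unions over transcripts (so a base can belong to several
#' classes if transcripts conflict). Classes of zero total length yield
#' `NA` (undefined), not zero.
#'
#' @param catalogue Catalogue data.frame.
#' @param model A [region_model()].
#' @param chrom_lengths Named chromosome lengths (bp).
#' @return Data.frame: `region`, `period`, `region_bp`, `ssr_bp`,
#'   `density_bp_per_mb`.
#' @export
region_densities <- function(catalogue, model, chrom_lengths) {
  regions <- .region_union(model, chrom_lengths)
  loci_gr <- .gr_from_df(catalogue)
  rows <- list()
  for (reg in names(regions)) {
    rg <- regions[[reg]]
    reg_bp <- sum(as.numeric(BiocGenerics::width(rg)))
    for (p in 2:6) {
      sel <- which(catalogue$period == p)
      ssr_bp <- if (length(sel) && reg_bp > 0) {
        ov <- GenomicRanges::intersect(
          GenomicRanges::reduce(loci_gr[sel]), rg)
        sum(as.numeric(BiocGenerics::width(ov)))
      } else 0
      rows[[length(rows) + 1L]] <- data.frame(
        region = reg, period = p, region_bp = reg_bp, ssr_bp = ssr_bp,
        density_bp_per_mb =
          if (reg_bp > 0) ssr_bp / (reg_bp / 1e6) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap of SSR loci with a variant interval set
#'
#' A locus is flagged when it shares at least one base with at least one
#' interval (half-open coordinates).
#'
#' @param catalogue Catalogue data.frame.
#' @param intervals Data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), or a `GRanges`.
#' @return List with `flags` (per-locus logical in catalogue order,
#'   named by locus), `n_overlapping` and `fraction`.
#' @export
overlap_variants <- function(catalogue, intervals) {
  if (!methods::is(intervals, "GRanges")) {
    if (nrow(intervals) > 0L && any(intervals$end <= intervals$start))
      stop("malformed interval: end <= start")
    intervals <- if (nrow(intervals) == 0L) GenomicRanges::GRanges()
      else .gr_from_df(intervals)
  }
  flags <- rep(FALSE, nrow(catalogue))
  if (nrow(catalogue) > 0L && length(intervals) > 0L) {
    flags <- IRanges::overlapsAny(.gr_from_df(catalogue), intervals)
  }
  names(flags) <- catalogue$locus
  list(flags = flags, n_overlapping = sum(flags),
       fraction = if (nrow(catalogue) > 0L)
         count_fraction(sum(flags), nrow(catalogue)) else NA_real_)
}
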