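# Perfect tandem-repeat scanner.
#
# Detects maximal runs of a primitive 2-6 bp unit. A run qualifies when
# its repeat count reaches the period-specific minimum implied by a
# length floor (>= 10 bp) and a global minimum repeat count (>= 3):
# with the defaults this gives minimum repeats 5, 4, 3, 3, 3 for periods
# 2..6. Runs are trimmed to whole units, anchored at the leftmost full
# unit, and only the primitive (smallest) period of a tract is emitted.
# Overlapping loci are then removed entirely.

#' Minimum repeat count per period implied by the scan thresholds
#'
#' The scanner requires a repeat tract to reach both a total length floor
#' and a global minimum repeat count; the binding constraint per period is
#' `max(ceiling(min_len / period), min_repeat)`.
#'
#' @param min_len Minimum tract length in bp (default 10).
#' @param min_repeat Global minimum repeat count (default 3).
#' @return Named integer vector over periods `"2"`..`"6"`. With the
#'   defaults: 5, 4, 3, 3, 3.
#' @export
period_min_repeats <- function(min_len = 10L, min_repeat = 3L) {
  p <- 2:6
  out <- pmax(as.integer(ceiling(min_len / p)), as.integer(min_repeat))
  names(out) <- as.character(p)
  out
}

.empty_catalogue <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             motif = character(), period = integer(),
             repeat_count = integer(), ref_len = integer(),
             stringsAsFactors = FALSE)
}

#' Scan one sequence for perfect SSRs
#'
#' Reports every maximal perfect run of a primitive 2-6 bp unit meeting
#' the period-specific minimum repeat count and the total length floor,
#' trimmed to whole repeat units. `N` never participates in a repeat; runs
#' do not span `N`s. The result may still contain loci of different
#' periods sharing bases; apply [resolve_overlaps()] to obtain a
#' non-overlapping catalogue.
#'
#' @param seq A single DNA string over `{A,C,G,T,N}` (case-insensitive),
#'   or a `Biostrings::DNAString`.
#' @param chrom Sequence name recorded in the output.
#' @param min_len,min_repeat Scan thresholds, see [period_min_repeats()].
#' @return A data.frame with columns `chrom`, `start` (0-based),
#'   `end` (exclusive), `motif` (canonical), `period`, `repeat_count`,
#'   `ref_len`, sorted by `start`.
#' @export
scan_sequence <- function(seq, chrom = "seq", min_len = 10L,
                          min_repeat = 3L) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L) stop("seq must be a single sequence")
  n <- nchar(seq)
  if (n == 0L) return(.empty_catalogue())
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (!all(x %in% c("A", "C", "G", "T", "N")))
    stop("sequence contains characters outside {A,C,G,T,N}")
  minreps <- period_min_repeats(min_len, min_repeat)
  notN <- x != "N"
  res <- vector("list", 5L)
  for (p in 2:6) {
    minrep <- minreps[[as.character(p)]]
    if (n < p * minrep) next
    idx <- seq_len(n - p)
    m <- x[idx] == x[idx + p] & notN[idx] & notN[idx + p]
    r <- rle(m)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    keep <- r$values & (r$lengths + p) >= p * minrep
    if (!any(keep)) next
    rows <- lapply(which(keep), function(k) {
      i <- run_start[k]
      total <- r$lengths[k] + p             # maximal periodic region length
      count <- total %/% p
      if (count < minrep || count * p < min_len) return(NULL)
      unit <- paste(x[i:(i + p - 1L)], collapse = "")
      if (!is_primitive(unit)) return(NULL) # smaller period owns this tract
      data.frame(chrom = chrom, start = i - 1L,
                 end = i - 1L + count * p,
                 motif = canonical_motif(unit), period = p,
                 repeat_count = count, ref_len = count * p,
                 stringsAsFactors = FALSE)
    })
    res[[p - 1L]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) return(.empty_catalogue())
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove all mutually overlapping loci
#'
#' Implements the conservative overlap policy: every locus sharing at
#' least one base with another locus is dropped (both members of a pair,
#' all members of a cluster; nested loci count as overlapping). The
#' survivors are pairwise disjoint.
#'
#' @param loci Catalogue data.frame sorted by `(chrom, start)`.
#' @return The subset of `loci` participating in no overlap.
#' @export
resolve_overlaps <- function(loci) {
  if (nrow(loci) == 0L) return(loci)
  o <- order(loci$chrom, loci$start, method = "radix")
  if (!identical(o, seq_len(nrow(loci))))
    stop("loci must be sorted by (chrom, start)")
  gr <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(loci$start + 1L, loci$end))
  hits <- GenomicRanges::findOverlaps(gr, gr)
  clash <- S4Vectors::queryHits(hits)[
    S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)]
  out <- loci[!seq_len(nrow(loci)) %in% clash, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Catalogue perfect SSRs in a genome
#'
#' Scans every sequence of a FASTA file (or `DNAStringSet`), resolves
#' overlaps per chromosome and assigns stable locus identifiers
#' `chrom:start-end` (0-based half-open).
#'
#' @param fasta Path to a FASTA file, or a `Biostrings::DNAStringSet`.
#' @param min_len,min_repeat Scan thresholds, see [period_min_repeats()].
#' @return Catalogue data.frame (columns as [scan_sequence()] plus
#'   `locus`), non-overlapping, sorted by `(chrom, start)`.
#' @export
catalogue_genome <- function(fasta, min_len = 10L, min_repeat = 3L) {
  seqs <- if (methods::is(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  nm <- names(seqs)
  if (is.null(nm) || anyNA(nm)) stop("unnamed sequence in FASTA input")
  nm <- sub("\\s.*$", "", nm)   # FASTA id = first token of header
  if (anyDuplicated(nm)) stop("duplicate sequence names in FASTA input")
  parts <- lapply(seq_along(seqs), function(i) {
    resolve_overlaps(scan_sequence(as.character(seqs[[i]]), nm[i],
                                   min_len, min_repeat))
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- .empty_catalogue()
  out <- out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
  out$locus <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  rownames(out) <- NULL
  out
}

#' SSR density per chromosome and genome-wide
#'
#' Density is total SSR bp divided by sequence length in Mb; the genome
#' fraction is total SSR bp over total genome bp.
#'
#' @param catalogue Non-overlapping catalogue data.frame.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp),
#'   covering every chromosome in the catalogue.
#' @return A list with `per_chrom` (chrom x period `ssr_bp` and
#'   `density_bp_per_mb`), `per_chrom_total`, `genome_density_bp_per_mb`
#'   and `genome_fraction`.
#' @export
density_stats <- function(catalogue, chrom_lengths) {
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)))
    stop("chrom_lengths must be named by chromosome")
  if (nrow(catalogue) > 0L) {
    miss <- setdiff(unique(catalogue$chrom), names(chrom_lengths))
    if (length(miss))
      stop("chromosome(s) missing from chrom_lengths: ",
           paste(miss, collapse = ", "))
    beyond <- catalogue$end > chrom_lengths[catalogue$chrom]
    if (any(beyond))
      stop("locus beyond chromosome length: ",
           catalogue$chrom[which(beyond)[1L]])
  }
  grid <- expand.grid(chrom = names(chrom_lengths), period = 2:6,
                      stringsAsFactors = FALSE)
  if (nrow(catalogue) > 0L) {
    agg <- stats::aggregate(ref_len ~ chrom + period, data = catalogue, sum)
  } else {
    agg <- data.frame(chrom = character(), period = integer(),
                      ref_len = integer())
  }
  per <- merge(grid, agg, by = c("chrom", "period"), all.x = TRUE)
  per$ssr_bp <- ifelse(is.na(per$ref_len), 0, per$ref_len)
  per$ref_len <- NULL
  per$density_bp_per_mb <-
    per$ssr_bp / (chrom_lengths[per$chrom] / 1e6)
  per <- per[order(per$chrom, per$period), , drop = FALSE]
  rownames(per) <- NULL
  tot <- stats::aggregate(ssr_bp ~ chrom, data = per, sum)
  tot$density_bp_per_mb <- tot$ssr_bp / (chrom_lengths[tot$chrom] / 1e6)
  genome_bp <- sum(chrom_lengths)
  ssr_bp <- sum(per$ssr_bp)
  list(per_chrom = per,
       per_chrom_total = tot,
       genome_density_bp_per_mb = ssr_bp / (genome_bp / 1e6),
       genome_fraction = ssr_bp / genome_bp)
}

#' Fraction helper used in overlap and composition summaries
#'
#' @param x Count of interest.
#' @param total Total count; must be positive.
#' @return `x / total`.
#' @keywords internal
count_fraction <- function(x, total) {
  if (any(total <= 0)) stop("total must be positive")
  x / total
}
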