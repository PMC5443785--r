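# Cross-species conservation of pSSR flanks.
#
# For every locus, the 200 bp flanks on both sides were searched against
# other genomes; a species counts as conserved for the locus when a left
# and a right flank hit land on the same target chromosome, in the same
# orientation and correct relative order, with a target-side gap of
# strictly less than 300 bp. The conservation category of a locus is the
# number of such species (0 = pig-specific .. 14 = conserved in all).

#' Pair left/right flank hits into conservation calls
#'
#' @param hits Data.frame of flank alignment hits: `locus`, `side`
#'   (`"left"`/`"right"`), `species`, `tchrom`, `tstart`, `tend`
#'   (target, 0-based half-open), `orient` (`"+"`/`"-"`).
#' @param loci Character vector of all locus ids to report (loci without
#'   hits get category 0).
#' @param max_interval Maximum target-side gap between the paired flanks,
#'   exclusive (default 300: a gap of exactly 300 bp does not count).
#' @return Data.frame `locus`, `category` (number of species with a
#'   qualifying pair), and list-column `species_hit`.
#' @export
pair_flank_hits <- function(hits, loci, max_interval = 300L) {
  if (nrow(hits) > 0L) {
    need <- c("locus", "side", "species", "tchrom", "tstart", "tend",
              "orient")
    miss <- setdiff(need, names(hits))
    if (length(miss))
      stop("hit table lacks column(s): ", paste(miss, collapse = ", "))
    if (any(hits$tend <= hits$tstart))
      stop("malformed hit coordinates (tend <= tstart)")
    if (!all(hits$side %in% c("left", "right")))
      stop("side must be 'left' or 'right'")
    if (!all(hits$orient %in% c("+", "-")))
      stop("orient must be '+' or '-'")
  }
  species_hit <- stats::setNames(
    replicate(length(loci), character(0L), simplify = FALSE), loci)
  if (nrow(hits) > 0L) {
    hits <- hits[hits$locus %in% loci, , drop = FALSE]
    sp <- split(hits, list(hits$locus, hits$species), drop = TRUE)
    for (h in sp) {
      left <- h[h$side == "left", , drop = FALSE]
      right <- h[h$side == "right", , drop = FALSE]
      if (nrow(left) == 0L || nrow(right) == 0L) next
      found <- FALSE
      for (i in seq_len(nrow(left))) {
        for (j in seq_len(nrow(right))) {
          if (left$tchrom[i] != right$tchrom[j]) next
          if (left$orient[i] != right$orient[j]) next
          gap <- if (left$orient[i] == "+")
            right$tstart[j] - left$tend[i]
          else left$tstart[i] - right$tend[j]
          if (gap >= 0 && gap < max_interval) { found <- TRUE; break }
        }
        if (found) break
      }
      if (found) {
        id <- h$locus[1L]
        species_hit[[id]] <- union(species_hit[[id]], h$species[1L])
      }
    }
  }
  out <- data.frame(locus = loci,
                    category = vapply(species_hit, length, integer(1L)),
                    stringsAsFactors = FALSE)
  out$species_hit <- unname(species_hit)
  rownames(out) <- NULL
  out
}

#' Mean conservation score over a locus's flanks
#'
#' Averages a per-base score track (bedGraph-style constant-value
#' intervals) over the two `flank` bp regions on each side of every
#' locus. Bases without a score are skipped; a locus with no scored base
#' in its flanks gets `NA`.
#'
#' @param catalogue Catalogue data.frame.
#' @param score_track Data.frame `chrom`, `start`, `end` (0-based
#'   half-open), `value`.
#' @param flank Flank width per side in bp (default 200).
#' @param chrom_lengths Optional named lengths to clip flanks at
#'   chromosome ends.
#' @return Numeric vector of mean scores, named by locus, in catalogue
#'   order.
#' @export
mean_flank_score <- function(catalogue, score_track, flank = 200L,
                             chrom_lengths = NULL) {
  n <- nrow(catalogue)
  out <- stats::setNames(rep(NA_real_, n), catalogue$locus)
  if (n == 0L || nrow(score_track) == 0L) return(out)
  fl <- data.frame(
    chrom = rep(catalogue$chrom, 2L),
    start = c(catalogue$start - flank, catalogue$end),
    end = c(catalogue$start, catalogue$end + flank),
    li = rep(seq_len(n), 2L), stringsAsFactors = FALSE)
  fl$start <- pmax(fl$start, 0)
  if (!is.null(chrom_lengths))
    fl$end <- pmin(fl$end, chrom_lengths[fl$chrom])
  fl <- fl[fl$end > fl$start, , drop = FALSE]
  fgr <- .gr_from_df(fl)
  sgr <- .gr_from_df(score_track)
  hits <- GenomicRanges::findOverlaps(fgr, sgr)
  if (length(hits) == 0L) return(out)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  obp <- pmin(fl$end[qi], score_track$end[si]) -
    pmax(fl$start[qi], score_track$start[si])
  li <- fl$li[qi]
  num <- tapply(obp * score_track$value[si], li, sum)
  den <- tapply(obp, li, sum)
  out[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  stats::setNames(out, catalogue$locus)
}

#' Summary of conservation categories
#'
#' @param calls Data.frame from [pair_flank_hits()], optionally with a
#'   `mean_score` column (e.g. from [mean_flank_score()]).
#' @param n_species Number of species searched (default 14), fixing the
#'   category range `0..n_species`.
#' @return Data.frame per category: `category`, `n_loci`, and, when
#'   scores are present, `score_q1`, `score_median`, `score_q3`.
#' @export
category_summary <- function(calls, n_species = 14L) {
  cats <- 0:n_species
  n_loci <- vapply(cats, function(k) sum(calls$category == k), integer(1L))
  out <- data.frame(category = cats, n_loci = n_loci)
  if ("mean_score" %in% names(calls)) {
    qs <- t(vapply(cats, function(k) {
      s <- calls$mean_score[calls$category == k]
      s <- s[!is.na(s)]
      if (length(s) == 0L) return(c(NA_real_, NA_real_, NA_real_))
      stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE)
    }, numeric(3L)))
    out$score_q1 <- qs[, 1L]
    out$score_median <- qs[, 2L]
    out$score_q3 <- qs[, 3L]
  }
  out
}
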