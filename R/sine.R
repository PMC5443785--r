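# SSR enrichment around SINE boundaries.
#
# Both the 5' and 3' edge of every SINE copy contribute a flank of
# `flank` bp, cut into non-overlapping `window` bp bins indexed by
# distance from the element edge (bin 1 = nearest). Density in a bin is
# SSR bp overlapping the bin divided by the bin's total bp over all
# copies; the genome-wide SSR fraction serves as the control level.
# The SINE interior is excluded.

.flank_windows <- function(sine_intervals, chrom_lengths, flank, window) {
  if (flank %% window != 0L)
    stop("flank must be a multiple of window")
  if (nrow(sine_intervals) > 0L &&
      any(sine_intervals$end <= sine_intervals$start))
    stop("degenerate SINE interval (end <= start)")
  nb <- flank %/% window
  n <- nrow(sine_intervals)
  bins <- rep(seq_len(nb), times = 2L * n)
  chrom <- rep(rep(sine_intervals$chrom, each = nb), times = 2L)
  # left flank: bin b covers [start - b*w, start - (b-1)*w)
  ls <- rep(sine_intervals$start, each = nb) - bins[seq_len(nb * n)] * window
  # right flank: bin b covers [end + (b-1)*w, end + b*w)
  rs <- rep(sine_intervals$end, each = nb) +
    (bins[seq_len(nb * n)] - 1L) * window
  df <- data.frame(chrom = chrom,
                   start = c(ls, rs),
                   end = c(ls, rs) + window,
                   bin = bins,
                   side = rep(c("left", "right"), each = nb * n),
                   stringsAsFactors = FALSE)
  # clip at chromosome ends; clipped bp leave the denominator
  cl <- chrom_lengths[df$chrom]
  df$start <- pmax(df$start, 0)
  df$end <- pmin(df$end, cl)
  df <- df[df$end > df$start, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' SSR length-density profile around SINE boundaries
#'
#' @param catalogue Catalogue data.frame.
#' @param sine_intervals Data.frame `chrom`, `start`, `end` (0-based
#'   half-open) of SINE copies.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param flank Flank width per side in bp (default 200).
#' @param window Bin width in bp (default 20); must divide `flank`.
#' @param by_motif If `TRUE`, stratify densities by canonical motif.
#' @return A list with `profile` (per bin: `bin`, `dist_lo`, `dist_hi`,
#'   `window_bp`, `ssr_bp`, `density`, and `motif` when stratified) and
#'   `control` (genome-wide SSR fraction; named per motif when
#'   stratified).
#' @export
enrichment_profile <- function(catalogue, sine_intervals, chrom_lengths,
                               flank = 200L, window = 20L,
                               by_motif = FALSE) {
  wins <- .flank_windows(sine_intervals, chrom_lengths, flank, window)
  nb <- flank %/% window
  genome_bp <- sum(chrom_lengths)
  window_bp <- vapply(seq_len(nb), function(b)
    sum(wins$end[wins$bin == b] - wins$start[wins$bin == b]), numeric(1L))
  ov <- NULL
  if (nrow(wins) > 0L && nrow(catalogue) > 0L) {
    wgr <- .gr_from_df(wins)
    lgr <- .gr_from_df(catalogue)
    hits <- GenomicRanges::findOverlaps(wgr, lgr)
    if (length(hits) > 0L) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      obp <- pmin(wins$end[qi], catalogue$end[si]) -
        pmax(wins$start[qi], catalogue$start[si])
      ov <- data.frame(bin = wins$bin[qi], motif = catalogue$motif[si],
                       bp = obp, stringsAsFactors = FALSE)
    }
  }
  dist_lo <- (seq_len(nb) - 1L) * window
  dist_hi <- seq_len(nb) * window
  if (!by_motif) {
    ssr_bp <- numeric(nb)
    if (!is.null(ov)) {
      agg <- stats::aggregate(bp ~ bin, data = ov, sum)
      ssr_bp[agg$bin] <- agg$bp
    }
    profile <- data.frame(bin = seq_len(nb), dist_lo = dist_lo,
                          dist_hi = dist_hi, window_bp = window_bp,
                          ssr_bp = ssr_bp,
                          density = ifelse(window_bp > 0,
                                           ssr_bp / window_bp, NA_real_),
                          stringsAsFactors = FALSE)
    control <- sum(as.numeric(catalogue$ref_len)) / genome_bp
    return(list(profile = profile, control = control,
                flank = flank, window = window))
  }
  motifs <- sort(unique(catalogue$motif), method = "radix")
  grid <- expand.grid(bin = seq_len(nb), motif = motifs,
                      stringsAsFactors = FALSE)
  grid$ssr_bp <- 0
  if (!is.null(ov)) {
    agg <- stats::aggregate(bp ~ bin + motif, data = ov, sum)
    key <- paste(grid$bin, grid$motif)
    grid$ssr_bp[match(paste(agg$bin, agg$motif), key)] <- agg$bp
  }
  grid$window_bp <- window_bp[grid$bin]
  grid$dist_lo <- dist_lo[grid$bin]
  grid$dist_hi <- dist_hi[grid$bin]
  grid$density <- ifelse(grid$window_bp > 0,
                         grid$ssr_bp / grid$window_bp, NA_real_)
  control <- vapply(motifs, function(m)
    sum(as.numeric(catalogue$ref_len[catalogue$motif == m])) / genome_bp,
    numeric(1L))
  list(profile = grid[, c("bin", "dist_lo", "dist_hi", "motif",
                          "window_bp", "ssr_bp", "density")],
       control = control, flank = flank, window = window)
}

#' Motifs most enriched near SINE boundaries
#'
#' Ranks motifs by their peak window density relative to their
#' genome-wide density (enrichment ratio); ties broken lexicographically.
#'
#' @param profile_by_motif Result of [enrichment_profile()] with
#'   `by_motif = TRUE`.
#' @param k Number of motifs to return (default 6); if `k` exceeds the
#'   motif count, all are returned.
#' @return Data.frame `motif`, `peak_density`, `genome_density`,
#'   `enrichment`, ranked by decreasing enrichment.
#' @export
top_enriched_motifs <- function(profile_by_motif, k = 6L) {
  pr <- profile_by_motif$profile
  if (!"motif" %in% names(pr))
    stop("profile must be motif-stratified (by_motif = TRUE)")
  ctrl <- profile_by_motif$control
  peak <- stats::aggregate(density ~ motif, data = pr,
                           function(z) max(z, na.rm = TRUE))
  peak$genome_density <- unname(ctrl[peak$motif])
  peak$enrichment <- ifelse(peak$genome_density > 0,
                            peak$density / peak$genome_density, Inf)
  names(peak)[names(peak) == "density"] <- "peak_density"
  peak <- peak[order(-peak$enrichment,
                     rank(peak$motif, ties.method = "first")), , drop = FALSE]
  rownames(peak) <- NULL
  utils::head(peak, min(k, nrow(peak)))
}
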