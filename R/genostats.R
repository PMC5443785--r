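# Per-locus population statistics from diploid STR genotype calls.
#
# Alleles are identified by the total repeat-tract length in bp. A locus
# with at least two observed alleles across the population is a
# polymorphic SSR (pSSR). PIC is computed as 1 - sum(p_i^2), the
# expected-heterozygosity form; MAF is the frequency of the
# second-most-frequent allele (0 for monomorphic loci by convention).

.check_calls <- function(calls) {
  need <- c("sample", "locus", "allele_a", "allele_b", "q", "reads")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("genotype table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(calls$q < 0 | calls$q >= 1))
    stop("q must lie in [0, 1)")
  if (any(calls$reads < 1))
    stop("reads must be >= 1")
  if (anyDuplicated(calls[, c("sample", "locus")]))
    stop("duplicate (sample, locus) genotype record")
  swap <- calls$allele_a > calls$allele_b
  if (any(swap)) {
    tmp <- calls$allele_a[swap]
    calls$allele_a[swap] <- calls$allele_b[swap]
    calls$allele_b[swap] <- tmp
  }
  calls
}

#' Per-locus population summary statistics
#'
#' Computes, for every locus present in the genotype table: number of
#' called samples, call rate, mean coverage (total mapped reads over
#' called samples), mean `-log10(1 - Q)`, the allele frequency spectrum
#' over `2 * n_called` chromosomes, allele count, minor allele frequency,
#' observed heterozygosity and PIC (`1 - sum(p_i^2)`). Missing calls are
#' absent records; loci with zero calls simply do not appear.
#'
#' @param calls Genotype data.frame with columns `sample`, `locus`,
#'   `allele_a`, `allele_b` (tract lengths in bp), `q` in `[0,1)`,
#'   `reads` (>= 1).
#' @param n_samples_total Total number of genotyped samples (>= the
#'   number of called samples at any locus).
#' @return Data.frame with one row per locus: `locus`, `n_called`,
#'   `call_rate`, `mean_coverage`, `mean_neglog1mq`, `n_alleles`, `maf`,
#'   `het_obs`, `pic`, and a list-column `allele_freqs` of named
#'   frequency vectors.
#' @export
locus_stats <- function(calls, n_samples_total) {
  calls <- .check_calls(calls)
  dt <- data.table::as.data.table(calls)
  st <- dt[, {
    alleles <- c(allele_a, allele_b)
    tab <- sort(table(alleles), decreasing = TRUE)
    p <- as.numeric(tab) / length(alleles)
    names(p) <- names(tab)
    list(n_called = .N,
         mean_coverage = sum(reads) / .N,
         mean_neglog1mq = mean(-log10(1 - q)),
         n_alleles = length(p),
         maf = if (length(p) >= 2L) sort(p, decreasing = TRUE)[2L] else 0,
         het_obs = mean(allele_a != allele_b),
         pic = 1 - sum(p^2),
         allele_freqs = list(p))
  }, by = "locus"]
  if (any(st$n_called > n_samples_total))
    stop("n_samples_total smaller than the number of called samples")
  st[, "call_rate" := st$n_called / n_samples_total]
  out <- as.data.frame(st)
  out <- out[order(out$locus, method = "radix"),
             c("locus", "n_called", "call_rate", "mean_coverage",
               "mean_neglog1mq", "n_alleles", "maf", "het_obs", "pic",
               "allele_freqs")]
  rownames(out) <- NULL
  out
}

#' Is a locus polymorphic?
#'
#' A locus is a polymorphic SSR (pSSR) when at least two alleles were
#' observed in the population.
#'
#' @param stats A [locus_stats()] data.frame (or any data.frame with an
#'   `n_alleles` column).
#' @return Logical vector along the rows of `stats`.
#' @export
is_polymorphic <- function(stats) {
  stats$n_alleles >= 2L
}

#' Select high-quality polymorphic SSRs
#'
#' Applies the quality filter to per-locus statistics: average coverage
#' strictly greater than `min_cov`; mean `-log10(1-Q)` strictly greater
#' than `min_neglog1mq`; call rate at least `min_call_rate`; reference
#' tract length at most `max_ref_len`; minor allele frequency strictly
#' greater than `min_maf`; and the locus must be polymorphic. Boundary
#' semantics follow the criteria's wording: "greater than 3x" excludes
#' exactly 3.0, "at least 60%" includes exactly 0.6.
#'
#' @param stats A [locus_stats()] data.frame.
#' @param catalogue Catalogue data.frame supplying `ref_len` per locus;
#'   every locus in `stats` must be present.
#' @param min_cov,min_neglog1mq,min_call_rate,max_ref_len,min_maf
#'   Filter thresholds (defaults 3.0, 0.6, 0.6, 80, 0.1).
#' @return Character vector of locus ids passing all criteria, in
#'   `stats` order.
#' @export
filter_high_quality <- function(stats, catalogue, min_cov = 3.0,
                                min_neglog1mq = 0.6, min_call_rate = 0.6,
                                max_ref_len = 80L, min_maf = 0.1) {
  idx <- match(stats$locus, catalogue$locus)
  if (anyNA(idx))
    stop("locus in stats but not in catalogue: ",
         stats$locus[which(is.na(idx))[1L]])
  ref_len <- catalogue$ref_len[idx]
  pass <- stats$mean_coverage > min_cov &
    stats$mean_neglog1mq > min_neglog1mq &
    stats$call_rate >= min_call_rate &
    ref_len <= max_ref_len &
    stats$maf > min_maf &
    is_polymorphic(stats)
  stats$locus[pass]
}

#' Catalogue-wide genotyping summaries
#'
#' @param calls Genotype data.frame (see [locus_stats()]).
#' @param stats A [locus_stats()] data.frame for the same table.
#' @param catalogue Catalogue data.frame.
#' @return A list of summary tables: `per_sample` (called loci per
#'   sample), `per_locus` (called samples per locus),
#'   `alleles_by_refcount` (mean allele number binned by reference
#'   repeat count and period) and `per_motif` (per motif class: locus
#'   count, mean allele number / MAF / PIC, and pSSR proportion).
#' @export
summarize_catalogue <- function(calls, stats, catalogue) {
  calls <- .check_calls(calls)
  per_sample <- stats::aggregate(locus ~ sample, data = calls, length)
  names(per_sample)[2L] <- "n_called"
  per_locus <- stats[, c("locus", "n_called")]
  idx <- match(stats$locus, catalogue$locus)
  if (anyNA(idx)) stop("stats contain loci absent from the catalogue")
  joined <- cbind(stats[, c("locus", "n_alleles", "maf", "pic")],
                  catalogue[idx, c("motif", "period", "repeat_count")])
  abr <- stats::aggregate(n_alleles ~ period + repeat_count, data = joined,
                          mean)
  names(abr)[3L] <- "mean_n_alleles"
  abr <- abr[order(abr$period, abr$repeat_count), , drop = FALSE]
  rownames(abr) <- NULL
  dtj <- data.table::as.data.table(joined)
  pm <- dtj[, list(n_loci = .N,
                   mean_n_alleles = mean(n_alleles),
                   mean_maf = mean(maf),
                   mean_pic = mean(pic),
                   pssr_prop = mean(n_alleles >= 2L)),
            by = c("motif", "period")]
  pm <- as.data.frame(pm)
  pm <- pm[order(pm$period, pm$motif), , drop = FALSE]
  rownames(pm) <- NULL
  list(per_sample = per_sample, per_locus = per_locus,
       alleles_by_refcount = abr, per_motif = pm)
}
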