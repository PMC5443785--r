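# Population genetics over high-quality pSSR genotypes.
#
# The between-individual distance is 1 - identical/(identical + distinct)
# over loci called in both samples, where a genotype is identical when
# both unordered allele-length pairs match. The neighbour-joining tree
# is built from that matrix with the Saitou-Nei Q-criterion; ties are
# broken by the smallest (i, j) index pair and negative branch lengths
# are clamped to zero at output.

.genotype_matrix <- function(calls, loci = NULL) {
  calls <- .check_calls(calls)
  if (!is.null(loci)) calls <- calls[calls$locus %in% loci, , drop = FALSE]
  samples <- sort(unique(calls$sample), method = "radix")
  locs <- sort(unique(calls$locus), method = "radix")
  G <- matrix(NA_character_, nrow = length(locs), ncol = length(samples),
              dimnames = list(locs, samples))
  G[cbind(match(calls$locus, locs), match(calls$sample, samples))] <-
    paste(calls$allele_a, calls$allele_b, sep = "/")
  G
}

#' Genotype-sharing distance between two samples
#'
#' @param sample_a,sample_b Sample ids.
#' @param calls Genotype data.frame (see [locus_stats()]), typically
#'   restricted to high-quality loci via `loci`.
#' @param loci Optional locus subset.
#' @return List with `identical`, `distinct` and
#'   `distance = 1 - identical / (identical + distinct)`.
#' @export
pairwise_distance <- function(sample_a, sample_b, calls, loci = NULL) {
  G <- .genotype_matrix(calls, loci)
  if (!all(c(sample_a, sample_b) %in% colnames(G)))
    stop("unknown sample id")
  a <- G[, sample_a]; b <- G[, sample_b]
  both <- !is.na(a) & !is.na(b)
  identical_n <- sum(both & a == b)
  distinct_n <- sum(both & a != b)
  if (identical_n + distinct_n == 0L)
    stop("undefined distance: no locus called in both samples")
  list(identical = identical_n, distinct = distinct_n,
       distance = 1 - identical_n / (identical_n + distinct_n))
}

#' Pairwise distance matrix over all samples
#'
#' @inheritParams pairwise_distance
#' @return Symmetric numeric matrix with zero diagonal, samples in
#'   sorted order.
#' @export
distance_matrix <- function(calls, loci = NULL) {
  G <- .genotype_matrix(calls, loci)
  samples <- colnames(G)
  n <- length(samples)
  D <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- G[, i]; b <- G[, j]
      both <- !is.na(a) & !is.na(b)
      idn <- sum(both & a == b); dsn <- sum(both & a != b)
      if (idn + dsn == 0L)
        stop("undefined distance between ", samples[i], " and ",
             samples[j], ": no shared called locus")
      D[i, j] <- D[j, i] <- 1 - idn / (idn + dsn)
    }
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' In-repo Saitou-Nei agglomeration: at each step the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined (ties broken by the
#' smallest `(i, j)` index pair in the current matrix), branch lengths
#' follow the standard formulas, and the final three clusters are joined
#' at an unresolved root, giving the usual unrooted NJ tree. On an
#' additive matrix the generating topology and branch lengths are
#' recovered exactly. Negative branch lengths are clamped to 0; the
#' number clamped is recorded in the `clamped` attribute.
#'
#' @param d Symmetric numeric matrix with zero diagonal, no `NA`/`NaN`,
#'   at least 3 labelled taxa.
#' @return An `ape::phylo` tree (unrooted; serialisable with
#'   `ape::write.tree`).
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("d must be a square matrix")
  if (anyNA(d) || any(!is.finite(d)))
    stop("d contains NA/NaN/Inf")
  if (max(abs(d - t(d))) > 1e-12) stop("d must be symmetric")
  if (any(diag(d) != 0)) stop("d must have a zero diagonal")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  clamped <- 0L
  fmt <- function(x) {
    if (x < 0) clamped <<- clamped + 1L
    sprintf("%.15g", max(x, 0))
  }
  frag <- labels
  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li),
                       frag[j], fmt(lj))
    keep <- setdiff(seq_len(m), c(i, j))
    newd <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd),
                c(newd, 0))
    D <- D2
    frag <- c(frag[keep], newfrag)
  }
  # three-point formulas close the star
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(la),
                    frag[2], fmt(lb), frag[3], fmt(lc))
  tree <- ape::read.tree(text = newick)
  attr(tree, "clamped") <- clamped
  tree
}

#' Homozygous/heterozygous genotype counts per breed
#'
#' @param calls Genotype data.frame.
#' @param breed_map Data.frame `sample`, `breed`.
#' @param loci Optional locus subset (e.g. high-quality pSSRs).
#' @return List with `per_sample` (`sample`, `breed`, `n_hom`, `n_het`)
#'   and `per_breed` (mean counts over the breed's samples).
#' @export
breed_het_counts <- function(calls, breed_map, loci = NULL) {
  calls <- .check_calls(calls)
  if (!is.null(loci)) calls <- calls[calls$locus %in% loci, , drop = FALSE]
  if (!all(calls$sample %in% breed_map$sample))
    stop("sample(s) missing from breed map")
  dt <- data.table::as.data.table(calls)
  ps <- as.data.frame(dt[, list(n_hom = sum(allele_a == allele_b),
                                n_het = sum(allele_a != allele_b)),
                         by = "sample"])
  ps$breed <- breed_map$breed[match(ps$sample, breed_map$sample)]
  if (anyNA(ps$breed)) stop("unknown breed id")
  ps <- ps[order(ps$breed, ps$sample), c("sample", "breed", "n_hom",
                                         "n_het")]
  rownames(ps) <- NULL
  pb <- stats::aggregate(cbind(n_hom, n_het) ~ breed, data = ps, mean)
  names(pb)[2:3] <- c("mean_hom", "mean_het")
  list(per_sample = ps, per_breed = pb)
}

#' Windowed heterozygous-genotype ratio per breed
#'
#' For each sample, each non-overlapping window of `window` bp and each
#' chromosome: the number of heterozygous called loci divided by the
#' number of called loci in the window. Windows with no called locus are
#' `NA` and excluded from breed summaries.
#'
#' @param calls Genotype data.frame.
#' @param catalogue Catalogue data.frame supplying locus coordinates.
#' @param breed_map Data.frame `sample`, `breed`.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param window Window width in bp (default 10 Mb).
#' @param loci Optional locus subset.
#' @return List with `per_sample` (sample x window ratios), `per_breed`
#'   (breed mean ratio per window) and `breed_summary` (per breed: mean
#'   and median of its windowed ratios).
#' @export
windowed_het_ratio <- function(calls, catalogue, breed_map, chrom_lengths,
                               window = 1e7, loci = NULL) {
  calls <- .check_calls(calls)
  if (!is.null(loci)) calls <- calls[calls$locus %in% loci, , drop = FALSE]
  idx <- match(calls$locus, catalogue$locus)
  if (anyNA(idx)) stop("genotyped locus absent from catalogue")
  calls$chrom <- catalogue$chrom[idx]
  calls$win <- catalogue$start[idx] %/% window
  dt <- data.table::as.data.table(calls)
  ps <- as.data.frame(dt[, list(n = .N,
                                n_het = sum(allele_a != allele_b)),
                         by = c("sample", "chrom", "win")])
  ps$ratio <- ps$n_het / ps$n
  ps$breed <- breed_map$breed[match(ps$sample, breed_map$sample)]
  if (anyNA(ps$breed)) stop("unknown breed id")
  pb <- stats::aggregate(ratio ~ breed + chrom + win, data = ps, mean)
  bs <- do.call(rbind, lapply(split(pb$ratio, pb$breed), function(z)
    data.frame(mean_ratio = mean(z), median_ratio = stats::median(z))))
  bs <- cbind(breed = rownames(bs), bs)
  rownames(bs) <- NULL
  list(per_sample = ps[order(ps$sample, ps$chrom, ps$win), , drop = FALSE],
       per_breed = pb[order(pb$breed, pb$chrom, pb$win), , drop = FALSE],
       breed_summary = bs)
}

#' Per-locus heterozygous ratio and PIC within groups
#'
#' @param calls Genotype data.frame.
#' @param group_map Data.frame `sample`, `group`.
#' @param loci Optional locus subset.
#' @return Data.frame `locus`, `group`, `n_called`, `het_ratio`
#'   (heterozygous individuals over called individuals in the group) and
#'   `pic` (`1 - sum(p_i^2)` over the group's allele frequencies).
#' @export
group_locus_stats <- function(calls, group_map, loci = NULL) {
  calls <- .check_calls(calls)
  if (!is.null(loci)) calls <- calls[calls$locus %in% loci, , drop = FALSE]
  calls$group <- group_map$group[match(calls$sample, group_map$sample)]
  if (anyNA(calls$group)) stop("sample(s) missing from group map")
  dt <- data.table::as.data.table(calls)
  out <- as.data.frame(dt[, {
    p <- as.numeric(table(c(allele_a, allele_b))) / (2 * .N)
    list(n_called = .N,
         het_ratio = mean(allele_a != allele_b),
         pic = 1 - sum(p^2))
  }, by = c("locus", "group")])
  out <- out[order(out$locus, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
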