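test_that("pairwise distance follows the genotype-sharing formula", {
  rows <- list()
  for (li in 1:10) {
    g <- if (li == 1) c(12L, 14L) else c(12L, 12L)   # one differing locus
    rows[[length(rows) + 1]] <- make_calls(
      list("a", sprintf("L%02d", li), 12, 12, 0.9, 5),
      list("b", sprintf("L%02d", li), g[1], g[2], 0.9, 5))
  }
  calls <- do.call(rbind, rows)
  pc <- pairwise_distance("a", "b", calls)
  expect_equal(pc$identical, 9L)
  expect_equal(pc$distinct, 1L)
  expect_equal(pc$distance, 0.1)
  expect_equal(pairwise_distance("a", "a", calls)$distance, 0)
  # loci missing in either sample are excluded from both counts
  calls2 <- rbind(calls, make_calls(list("a", "L99", 10, 10, 0.9, 5)))
  pc2 <- pairwise_distance("a", "b", calls2)
  expect_equal(pc2$identical + pc2$distinct, 10L)
  only_a <- make_calls(list("a", "L1", 10, 10, 0.9, 5),
                       list("b", "L2", 10, 10, 0.9, 5))
  expect_error(pairwise_distance("a", "b", only_a), "undefined")
})

test_that("distance matrix agrees with a per-pair oracle on random tables", {
  set.seed(13)
  samples <- sprintf("s%d", 1:6)
  rows <- list()
  for (li in 1:30) for (s in samples) {
    if (runif(1) < 0.15) next
    g <- sort(sample(c(10L, 12L, 14L), 2, replace = TRUE))
    rows[[length(rows) + 1]] <- make_calls(
      list(s, sprintf("L%02d", li), g[1], g[2], 0.9, 4))
  }
  calls <- do.call(rbind, rows)
  D <- distance_matrix(calls)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:5) for (j in (i + 1):6) {
    # naive per-locus comparison
    id <- 0L; ds <- 0L
    for (li in unique(calls$locus)) {
      a <- calls[calls$locus == li & calls$sample == samples[i], ]
      b <- calls[calls$locus == li & calls$sample == samples[j], ]
      if (nrow(a) == 0 || nrow(b) == 0) next
      same <- a$allele_a == b$allele_a && a$allele_b == b$allele_b
      if (same) id <- id + 1L else ds <- ds + 1L
    }
    expect_equal(D[samples[i], samples[j]], 1 - id / (id + ds))
  }
})

test_that("three-taxon trees solve the closed-form branch lengths", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- nj_tree(d)
  el <- setNames(tree$edge.length,
                 tree$tip.label[tree$edge[, 2]])
  expect_equal(el[["a"]], 1)   # (3+5-6)/2
  expect_equal(el[["b"]], 2)   # (3+6-5)/2
  expect_equal(el[["c"]], 4)   # (5+6-3)/2
  expect_error(nj_tree(d[1:2, 1:2]), "3 taxa")
  dd <- d; dd[1, 2] <- 9
  expect_error(nj_tree(dd), "symmetric")
  dn <- d; dn[1, 2] <- dn[2, 1] <- NA
  expect_error(nj_tree(dn), "NA")
})

test_that("neighbour joining recovers random additive trees exactly", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    ref <- ape::rtree(n, rooted = FALSE,
                      br = function(k) runif(k, 0.1, 1))
    D <- ape::cophenetic.phylo(ref)
    D <- D[order(rownames(D)), order(colnames(D))]
    tree <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(ref), tree), 0,
                 ignore_attr = TRUE)
    co <- ape::cophenetic.phylo(tree)
    co <- co[rownames(D), colnames(D)]
    expect_lt(max(abs(co - D)), 1e-9)
  }
})

test_that("our NJ topology matches the reference implementation", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 8
    D <- as.matrix(stats::dist(matrix(runif(n * 4), n)))
    dimnames(D) <- list(sprintf("t%d", 1:n), sprintf("t%d", 1:n))
    mine <- nj_tree(D)
    ref <- ape::nj(D)
    expect_equal(ape::dist.topo(mine, ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("newick serialisation round-trips topology and lengths", {
  set.seed(4)
  ref <- ape::rtree(9, rooted = FALSE)
  D <- ape::cophenetic.phylo(ref)
  tree <- nj_tree(D)
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, tf)
  back <- read_newick(tf)
  expect_equal(ape::dist.topo(tree, back), 0, ignore_attr = TRUE)
  co1 <- ape::cophenetic.phylo(tree)
  co2 <- ape::cophenetic.phylo(back)[rownames(co1), colnames(co1)]
  expect_lt(max(abs(co1 - co2)), 1e-9)
})

test_that("breed counts conserve calls and split hom/het", {
  calls <- make_calls(list("s1", "L1", 10, 10, .9, 3),
                      list("s1", "L2", 10, 12, .9, 3),
                      list("s1", "L3", 12, 12, .9, 3),
                      list("s2", "L1", 10, 10, .9, 3),
                      list("s2", "L2", 10, 10, .9, 3))
  bm <- data.frame(sample = c("s1", "s2"), breed = "B1")
  hc <- breed_het_counts(calls, bm)
  expect_equal(hc$per_sample$n_hom + hc$per_sample$n_het, c(3L, 2L))
  expect_equal(hc$per_sample$n_het, c(1L, 0L))
  expect_equal(hc$per_breed$mean_het, 0.5)
  expect_error(breed_het_counts(calls,
                                data.frame(sample = "s1", breed = "B1")),
               "missing")
})

test_that("windowed heterozygous ratios tile and skip empty windows", {
  cat6 <- toy_catalogue(6, spacing = 40000L)  # loci at 40k..240k
  calls <- do.call(rbind, lapply(seq_len(6), function(li)
    make_calls(list("s1", cat6$locus[li], 10,
                    if (li <= 2) 12 else 10, .9, 3))))
  bm <- data.frame(sample = "s1", breed = "B1")
  wr <- windowed_het_ratio(calls, cat6, bm, c(chr1 = 3e5), window = 1e5)
  # window 0: loci at 40k, 80k (both het) -> 1; window 1: 120k,160k,200k
  # (hom) -> 0; window 2: 240k -> 0
  pw <- wr$per_sample[order(wr$per_sample$win), ]
  expect_equal(pw$ratio, c(1, 0, 0))
  expect_equal(wr$breed_summary$median_ratio, 0)
  # a window with no called locus is absent, not zero
  calls2 <- calls[cat6$start[match(calls$locus, cat6$locus)] < 2e5, ]
  wr2 <- windowed_het_ratio(calls2, cat6, bm, c(chr1 = 3e5),
                            window = 1e5)
  expect_equal(nrow(wr2$per_sample), 2L)
})

test_that("per-group locus statistics match the printed examples", {
  # group of 4 with 1 heterozygote -> ratio 0.25
  calls <- make_calls(list("s1", "L1", 10, 12, .9, 3),
                      list("s2", "L1", 10, 10, .9, 3),
                      list("s3", "L1", 10, 10, .9, 3),
                      list("s4", "L1", 10, 10, .9, 3))
  gm <- data.frame(sample = sprintf("s%d", 1:4), group = "CH")
  gs <- group_locus_stats(calls, gm)
  expect_equal(gs$het_ratio, 0.25)
  # allele freqs (0.9, 0.1) -> PIC = 1 - 0.81 - 0.01 = 0.18
  calls2 <- make_calls(list("s1", "L1", 10, 12, .9, 3),
                       list("s2", "L1", 10, 10, .9, 3),
                       list("s3", "L1", 10, 10, .9, 3),
                       list("s4", "L1", 10, 10, .9, 3),
                       list("s5", "L1", 10, 10, .9, 3))
  gm2 <- data.frame(sample = sprintf("s%d", 1:5), group = "CH")
  expect_equal(group_locus_stats(calls2, gm2)$pic, 0.18)
})
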