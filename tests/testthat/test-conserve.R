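hit_row <- function(locus, side, species, tchrom, tstart, tend,
                    orient = "+") {
  data.frame(locus = locus, side = side, species = species,
             tchrom = tchrom, tstart = tstart, tend = tend,
             orient = orient, stringsAsFactors = FALSE)
}

test_that("flank pairing enforces chromosome, orientation, order and gap", {
  loci <- c("L1", "L2", "L3", "L4", "L5")
  hits <- rbind(
    # L1: qualifying pair, gap 250
    hit_row("L1", "left", "cow", "t1", 800, 1000),
    hit_row("L1", "right", "cow", "t1", 1250, 1450),
    # L2: gap exactly 300 does not count
    hit_row("L2", "left", "cow", "t1", 800, 1000),
    hit_row("L2", "right", "cow", "t1", 1300, 1500),
    # L3: different target chromosomes
    hit_row("L3", "left", "cow", "t1", 800, 1000),
    hit_row("L3", "right", "cow", "t2", 1100, 1300),
    # L4: minus-orientation pair, right upstream of left in target
    hit_row("L4", "right", "cow", "t1", 800, 1000, "-"),
    hit_row("L4", "left", "cow", "t1", 1100, 1300, "-"),
    # L4 second species: mixed orientation never pairs
    hit_row("L4", "left", "rat", "t1", 800, 1000, "+"),
    hit_row("L4", "right", "rat", "t1", 1100, 1300, "-"))
  calls <- pair_flank_hits(hits, loci)
  expect_equal(calls$category[calls$locus == "L1"], 1L)
  expect_equal(calls$category[calls$locus == "L2"], 0L)
  expect_equal(calls$category[calls$locus == "L3"], 0L)
  expect_equal(calls$category[calls$locus == "L4"], 1L)
  expect_identical(calls$species_hit[calls$locus == "L4"][[1]], "cow")
  # no hits at all: pig-specific
  expect_equal(calls$category[calls$locus == "L5"], 0L)
  expect_error(pair_flank_hits(hit_row("L1", "left", "cow", "t1", 10, 10),
                               loci),
               "malformed")
})

test_that("a species counts once however many pairs qualify", {
  hits <- rbind(
    hit_row("L1", "left", "cow", "t1", 800, 1000),
    hit_row("L1", "right", "cow", "t1", 1100, 1300),
    hit_row("L1", "left", "cow", "t1", 5000, 5200),
    hit_row("L1", "right", "cow", "t1", 5300, 5500),
    hit_row("L1", "left", "dog", "t9", 10, 210),
    hit_row("L1", "right", "dog", "t9", 300, 500))
  calls <- pair_flank_hits(hits, "L1")
  expect_equal(calls$category, 2L)
  expect_setequal(calls$species_hit[[1]], c("cow", "dog"))
})

test_that("adding a qualifying hit never decreases the category", {
  base <- rbind(hit_row("L1", "left", "cow", "t1", 800, 1000),
                hit_row("L1", "right", "cow", "t1", 1100, 1300))
  c0 <- pair_flank_hits(base, "L1")$category
  more <- rbind(base,
                hit_row("L1", "left", "dog", "t2", 800, 1000),
                hit_row("L1", "right", "dog", "t2", 1100, 1300))
  expect_gte(pair_flank_hits(more, "L1")$category, c0)
})

test_that("flank score averaging equals a per-base oracle", {
  cat3 <- toy_catalogue(3, spacing = 5000L)
  cl <- c(chr1 = 1e5)
  # constant track over everything
  tr1 <- data.frame(chrom = "chr1", start = 0L, end = 1e5, value = 1.5)
  expect_equal(unname(mean_flank_score(cat3, tr1, chrom_lengths = cl)),
               rep(1.5, 3))
  # left flank all 0, right flank all 2 for the first locus
  tr2 <- rbind(
    data.frame(chrom = "chr1", start = cat3$start[1] - 200L,
               end = cat3$start[1], value = 0),
    data.frame(chrom = "chr1", start = cat3$end[1],
               end = cat3$end[1] + 200L, value = 2))
  sc <- mean_flank_score(cat3, tr2, chrom_lengths = cl)
  expect_equal(unname(sc[1]), 1.0)
  expect_true(all(is.na(sc[2:3])))   # no scored base in their flanks
  # gappy random track vs brute-force per-base average
  set.seed(21)
  pieces <- lapply(1:40, function(i) {
    s <- sample(0:19999, 1)
    data.frame(chrom = "chr1", start = s, end = s + sample(5:60, 1),
               value = round(runif(1, -2, 2), 3))
  })
  tr3 <- do.call(rbind, pieces)
  tr3 <- tr3[order(tr3$start), ]
  tr3 <- tr3[!duplicated(tr3$start), ]
  # drop overlapping rows so per-base values are unambiguous
  keep <- rep(TRUE, nrow(tr3))
  hi <- -1
  for (i in seq_len(nrow(tr3))) {
    if (tr3$start[i] < hi) keep[i] <- FALSE else hi <- tr3$end[i]
  }
  tr3 <- tr3[keep, ]
  base_val <- rep(NA_real_, 1e5)
  for (i in seq_len(nrow(tr3)))
    base_val[(tr3$start[i] + 1):tr3$end[i]] <- tr3$value[i]
  sc3 <- mean_flank_score(cat3, tr3, chrom_lengths = cl)
  for (k in 1:3) {
    fl <- c((cat3$start[k] - 200 + 1):cat3$start[k],
            (cat3$end[k] + 1):(cat3$end[k] + 200))
    v <- base_val[fl[fl >= 1 & fl <= 1e5]]
    expect_equal(unname(sc3[k]),
                 if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  }
})

test_that("category summaries count every locus once", {
  calls <- data.frame(locus = sprintf("L%d", 1:6),
                      category = c(0L, 0L, 3L, 14L, 14L, 7L),
                      mean_score = c(-1, -0.9, 0.1, 2, 2.1, 0.8))
  cs <- category_summary(calls)
  expect_equal(sum(cs$n_loci), 6L)
  expect_equal(cs$n_loci[cs$category == 14], 2L)
  expect_equal(cs$score_median[cs$category == 14], 2.05)
  expect_true(is.na(cs$score_median[cs$category == 1]))
})
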