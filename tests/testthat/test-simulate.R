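test_that("genome simulation is deterministic and honours the plan", {
  cfg <- sim_config(seed = 5,
                    genome = list(chrom_length = 2e5),
                    ssr_plan = list(n_loci = c(`2` = 20L, `3` = 15L,
                                               `4` = 10L, `5` = 5L,
                                               `6` = 5L)),
                    gene_plan = list(n_genes = 3L),
                    sine_plan = list(n_sines = 6L,
                                     n_boundary_ssrs = 6L))
  sim1 <- simulate_genome(cfg)
  sim2 <- simulate_genome(cfg)
  expect_identical(as.character(sim1$genome), as.character(sim2$genome))
  expect_equal(nrow(sim1$truth), 55L + 6L)
  expect_true(all(sim1$truth$ref_len >= 10))
  expect_true(all(sim1$truth$ref_len ==
                    sim1$truth$repeat_count * sim1$truth$period))
})

test_that("the scanner recovers exactly the planted loci", {
  cfg <- sim_config(seed = 8,
                    genome = list(chrom_length = 2e5),
                    ssr_plan = list(n_loci = c(`2` = 15L, `3` = 10L,
                                               `4` = 10L, `5` = 5L,
                                               `6` = 5L)),
                    gene_plan = list(n_genes = 3L),
                    sine_plan = list(n_sines = 5L,
                                     n_boundary_ssrs = 5L))
  sim <- simulate_genome(cfg)
  found <- catalogue_genome(sim$genome)
  key <- function(df) sprintf("%s:%d-%d:%d:%s:%d", df$chrom, df$start,
                              df$end, df$period, df$motif,
                              df$repeat_count)
  expect_setequal(key(found), key(sim$truth))
  # zero plan: nothing to find
  cfg0 <- sim_config(seed = 9,
                     genome = list(chrom_length = 5e4),
                     ssr_plan = list(n_loci = c(`2` = 0L, `3` = 0L,
                                                `4` = 0L, `5` = 0L,
                                                `6` = 0L)),
                     gene_plan = list(n_genes = 1L),
                     sine_plan = list(n_sines = 2L,
                                      n_boundary_ssrs = 0L))
  expect_equal(nrow(catalogue_genome(simulate_genome(cfg0)$genome)), 0L)
})

test_that("genotype simulation respects missingness and planted frequencies", {
  cat40 <- toy_catalogue(40)
  cfg <- sim_config(seed = 2, pop_plan = list(missing_rate = 0))
  g <- simulate_genotypes(cfg, cat40)
  st <- locus_stats(g$calls, nrow(g$breed_map))
  expect_true(all(st$call_rate == 1))
  # fixed 50/50 frequencies under random mating at n = 200: PIC near 0.5
  cfgH <- sim_config(seed = 6,
                     pop_plan = list(n_breeds = 1L,
                                     samples_per_breed = 200L,
                                     group_of_breed = "CH",
                                     het_mode = "hwe",
                                     fixed_freqs = c(0.5, 0.5),
                                     missing_rate = 0))
  gH <- simulate_genotypes(cfgH, toy_catalogue(30))
  stH <- locus_stats(gH$calls, 200L)
  expect_lt(max(abs(stH$pic - 0.5)), 0.03)
  expect_lt(max(abs(stH$maf - 0.5)), 0.08)
})

test_that("conservation simulation plants recoverable categories", {
  cat30 <- toy_catalogue(30, spacing = 2000L)
  cfg <- sim_config(seed = 12)
  cons <- simulate_conservation(cfg, cat30, c(chr1 = 1e5))
  calls <- pair_flank_hits(cons$hits, cat30$locus)
  expect_identical(calls$category[match(cons$truth$locus, calls$locus)],
                   cons$truth$category)
  sc <- mean_flank_score(cat30, cons$score_track,
                         chrom_lengths = c(chr1 = 1e5))
  ok <- !is.na(sc)
  expect_gt(sum(ok), 0)
  expect_lt(max(abs(sc[ok] - cons$truth$score_level[ok])), 1e-9)
})

test_that("genotype files round-trip through the TSV dialects", {
  cat5 <- toy_catalogue(5)
  g <- simulate_genotypes(sim_config(seed = 3), cat5)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g$calls, tf)
  back <- read_genotypes(tf)
  ord <- function(df) {
    df <- df[order(df$sample, df$locus), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(ord(back), ord(g$calls), tolerance = 1e-12)
  # offsets dialect
  off <- g$calls
  ref <- cat5$ref_len[match(off$locus, cat5$locus)]
  off$allele_a <- off$allele_a - ref
  off$allele_b <- off$allele_b - ref
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(off, tf2)
  back2 <- read_genotypes(tf2, offsets = TRUE, catalogue = cat5)
  expect_equal(ord(back2), ord(g$calls), tolerance = 1e-12)
})
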