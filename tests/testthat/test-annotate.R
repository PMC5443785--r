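make_locus <- function(start, end, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, motif = "AC",
             period = 2L, repeat_count = as.integer((end - start) / 2),
             ref_len = end - start,
             locus = sprintf("%s:%d-%d", chrom, start, end),
             stringsAsFactors = FALSE)
}

test_that("region model derives UTRs, introns and promoters per strand", {
  model <- region_model(toy_model_granges(),
                        chrom_lengths = c(chr1 = 1e6))
  expect_s3_class(model, "region_model")
  expect_identical(model$transcripts$coding, c(TRUE, FALSE))
  # plus-strand transcript: 5'UTR before the CDS, 3'UTR after
  u5 <- model$utr5[["t1"]]
  expect_equal(BiocGenerics::start(u5), 10001)
  expect_equal(BiocGenerics::end(u5), 10100)
  u3 <- model$utr3[["t1"]]
  expect_equal(BiocGenerics::start(u3), 12401)
  expect_equal(BiocGenerics::end(u3), 12500)
  intr <- model$introns[["t1"]]
  expect_equal(BiocGenerics::start(intr), 11001)
  expect_equal(BiocGenerics::end(intr), 12000)
  # exon bp == CDS bp + UTR bp for the coding transcript
  bp <- function(g) sum(BiocGenerics::width(g))
  expect_equal(bp(model$exons[["t1"]]),
               bp(model$cds[["t1"]]) + bp(u5) + bp(u3))
  # promoters: 2 kb upstream, strand-aware
  pr <- model$promoter
  expect_equal(BiocGenerics::start(pr["t1"]), 8001)
  expect_equal(BiocGenerics::end(pr["t1"]), 10000)
  expect_equal(BiocGenerics::start(pr["t2"]), 30801)
  expect_equal(BiocGenerics::end(pr["t2"]), 32800)
})

test_that("malformed annotation with CDS outside exons is rejected", {
  gr <- toy_model_granges()
  bad <- gr
  BiocGenerics::end(bad)[bad$ID == "t1.c2"] <- 12600  # CDS past exon end
  expect_error(region_model(bad), "malformed annotation")
})

test_that("locus classification follows the region priority", {
  model <- region_model(toy_model_granges(),
                        chrom_lengths = c(chr1 = 1e6))
  cases <- rbind(
    make_locus(10200L, 10220L),   # inside CDS
    make_locus(10020L, 10040L),   # inside 5'UTR
    make_locus(12420L, 12440L),   # inside 3'UTR
    make_locus(11500L, 11520L),   # inside intron
    make_locus(9400L, 9420L),     # 500 bp upstream of the plus-strand TSS
    make_locus(31000L, 31020L),   # upstream of minus-strand TSS: promoter
    make_locus(30100L, 30120L),   # in the non-coding exon
    make_locus(500000L, 500020L), # far from everything
    make_locus(10090L, 10110L),   # straddles UTR5/CDS: CDS wins
    make_locus(10990L, 11010L))   # straddles exon/intron: CDS wins
  rc <- classify_region(cases, model)
  expect_identical(rc$calls$label,
                   c("CDS", "UTR5", "UTR3", "intron", "promoter",
                     "promoter", "exon_noncoding", "intergenic", "CDS",
                     "CDS"))
  expect_identical(rc$calls$n_transcripts_hit[c(5, 6, 8)], c(0L, 0L, 0L))
  expect_equal(sum(table(rc$calls$label)), nrow(cases))
})

test_that("empty annotation labels every locus intergenic", {
  model <- region_model(GenomicRanges::GRanges(type = character()))
  cases <- rbind(make_locus(100L, 120L), make_locus(900L, 920L))
  rc <- classify_region(cases, model)
  expect_identical(rc$calls$label, c("intergenic", "intergenic"))
})

test_that("region densities use overlapping bp over region bp", {
  model <- region_model(toy_model_granges(),
                        chrom_lengths = c(chr1 = 1e5))
  cases <- rbind(make_locus(11500L, 11520L),  # 20 bp in the intron
                 make_locus(50000L, 50020L))  # intergenic
  rd <- region_densities(cases, model, c(chr1 = 1e5))
  intron2 <- rd[rd$region == "intron" & rd$period == 2, ]
  expect_equal(intron2$ssr_bp, 20)
  expect_equal(intron2$region_bp, 1000)
  expect_equal(intron2$density_bp_per_mb, 20 / (1000 / 1e6))
  u3 <- rd[rd$region == "UTR3" & rd$period == 2, ]
  expect_equal(u3$ssr_bp, 0)
  # zero-length region classes are undefined, not zero
  empty_model <- region_model(GenomicRanges::GRanges(type = character()))
  rd0 <- region_densities(cases, empty_model, c(chr1 = 1e5))
  expect_true(all(is.na(rd0$density_bp_per_mb[rd0$region == "CDS"])))
  expect_equal(rd0$ssr_bp[rd0$region == "intergenic" & rd0$period == 2],
               40)
})

test_that("variant overlap uses half-open semantics", {
  cases <- rbind(make_locus(100L, 110L), make_locus(300L, 310L),
                 make_locus(500L, 510L))
  iv <- data.frame(chrom = "chr1", start = c(105L, 310L),
                   end = c(106L, 311L), stringsAsFactors = FALSE)
  ov <- overlap_variants(cases, iv)
  expect_identical(unname(ov$flags), c(TRUE, FALSE, FALSE))
  expect_equal(ov$n_overlapping, 1L)
  expect_equal(ov$fraction, 1 / 3)
  expect_error(overlap_variants(cases,
                                data.frame(chrom = "chr1", start = 10L,
                                           end = 10L)),
               "malformed")
  # monotone as intervals are added
  iv2 <- rbind(iv, data.frame(chrom = "chr1", start = 505L, end = 508L))
  expect_gte(overlap_variants(cases, iv2)$fraction, ov$fraction)
})
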