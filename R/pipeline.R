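# End-to-end pipeline over simulator output.

#' Run the full SSR analysis pipeline on synthetic data
#'
#' Generates a synthetic study (genome, annotation, SINEs, genotypes,
#' conservation inputs) from a [sim_config()], then runs every analysis
#' stage: genome cataloguing, region classification and densities, SINE
#' enrichment, per-locus population statistics, high-quality pSSR
#' filtering, conservation categorisation and scoring,
#' loss-of-function screening, and the neighbour-joining tree with
#' breed-level diversity summaries. When `out_dir` is given, all
#' artefacts are written in their standard formats.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @param het_window Window width (bp) for the windowed heterozygous
#'   ratio; default 2e5, suited to the default synthetic chromosome
#'   length.
#' @return A list with all intermediate and final artefacts (see the
#'   vignette for a tour).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         het_window = 2e5) {
  sim <- simulate_genome(config)
  catalogue <- catalogue_genome(sim$genome)
  dens <- density_stats(catalogue, sim$chrom_lengths)
  model <- region_model(sim$genes, chrom_lengths = sim$chrom_lengths)
  regions <- classify_region(catalogue, model)
  rdens <- region_densities(catalogue, model, sim$chrom_lengths)
  sine_prof <- enrichment_profile(catalogue, sim$sines,
                                  sim$chrom_lengths)
  sine_motif <- enrichment_profile(catalogue, sim$sines,
                                   sim$chrom_lengths, by_motif = TRUE)
  top_motifs <- top_enriched_motifs(sine_motif)
  geno <- simulate_genotypes(config, catalogue)
  n_samples <- nrow(geno$breed_map)
  stats <- locus_stats(geno$calls, n_samples)
  hq <- filter_high_quality(stats, catalogue)
  summaries <- summarize_catalogue(geno$calls, stats, catalogue)
  cons <- simulate_conservation(config, catalogue, sim$chrom_lengths)
  cons_calls <- pair_flank_hits(cons$hits, catalogue$locus)
  cons_calls$mean_score <- unname(
    mean_flank_score(catalogue, cons$score_track,
                     chrom_lengths = sim$chrom_lengths))
  cons_summary <- category_summary(cons_calls)
  lof <- lof_screen(catalogue, stats, model, loci = hq)
  D <- distance_matrix(geno$calls, loci = hq)
  tree <- nj_tree(D)
  het <- breed_het_counts(geno$calls, geno$breed_map, loci = hq)
  winhet <- windowed_het_ratio(geno$calls, catalogue, geno$breed_map,
                               sim$chrom_lengths, window = het_window,
                               loci = hq)
  grp <- group_locus_stats(geno$calls,
                           data.frame(sample = geno$breed_map$sample,
                                      group = geno$breed_map$group),
                           loci = hq)
  out <- list(sim = sim, catalogue = catalogue, densities = dens,
              model = model, regions = regions,
              region_densities = rdens, sine_profile = sine_prof,
              sine_top_motifs = top_motifs, genotypes = geno,
              stats = stats, hq_loci = hq, summaries = summaries,
              conservation = list(inputs = cons, calls = cons_calls,
                                  summary = cons_summary),
              lof = lof, distances = D, tree = tree,
              het_counts = het, windowed_het = winhet,
              group_stats = grp)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(out_dir, x)
    write_fasta(sim$genome, fp("genome.fa"))
    write_gff3(sim$genes, fp("genes.gff3"))
    write_catalogue_bed(catalogue, fp("catalogue.bed"))
    data.table::fwrite(sim$sines, fp("sines.bed"), sep = "\t",
                       col.names = FALSE)
    write_genotypes(geno$calls, fp("genotypes.tsv"))
    data.table::fwrite(geno$breed_map, fp("breeds.tsv"), sep = "\t")
    data.table::fwrite(regions$calls, fp("regions.tsv"), sep = "\t")
    data.table::fwrite(rdens, fp("region_densities.tsv"), sep = "\t")
    data.table::fwrite(sine_prof$profile, fp("sine_profile.tsv"),
                       sep = "\t")
    st <- stats; st$allele_freqs <- NULL
    data.table::fwrite(st, fp("locus_stats.tsv"), sep = "\t")
    writeLines(hq, fp("high_quality_loci.txt"))
    cc <- cons_calls; cc$species_hit <- NULL
    data.table::fwrite(cc, fp("conservation.tsv"), sep = "\t")
    write_bedgraph(cons$score_track, fp("scores.bedgraph"))
    if (nrow(lof)) data.table::fwrite(lof, fp("lof.tsv"), sep = "\t")
    write_phylip_dist(D, fp("distances.phylip"))
    write_newick(tree, fp("tree.nwk"))
    data.table::fwrite(winhet$breed_summary, fp("windowed_het.tsv"),
                       sep = "\t")
  }
  out
}
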