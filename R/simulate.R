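# Synthetic-data generator with planted ground truth.
#
# The generator produces every input the pipeline consumes: a genome
# with planted perfect SSRs (background re-sampled until the scanner
# finds exactly the planted set, so truth tables are complete), gene
# models with exon/CDS/UTR structure, SINE intervals with A/T-rich
# boundary SSRs, breed-structured diploid genotype calls with quality
# and coverage, and cross-species flank hit tables plus a conservation
# score track. All outputs are deterministic under a fixed seed.

.SIM_SPECIES <- c("bosTau", "canFam", "equCab", "felCat", "gorGor",
                  "loxAfr", "macEug", "ornAna", "oryCun", "oviAri",
                  "panTro", "ratNor", "musMus", "homSap")

#' Simulation configuration
#'
#' Builds the default study design for the synthetic pipeline: a small
#' two-chromosome genome with ~540 planted SSR loci, a dozen gene models,
#' 40 SINE copies with A/T-rich boundary repeats, and 8 breeds x 2
#' samples split into a high-diversity "CH" and a low-diversity "EU"
#' group (forced heterozygosity 0.25 vs 0.10). Any component can be
#' overridden by passing a partial list with the same field names.
#'
#' @param seed Integer seed driving every random draw.
#' @param genome,ssr_plan,gene_plan,sine_plan,pop_plan,score_plan,
#'   conserve_plan Partial lists merged over the defaults.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome = list(), ssr_plan = list(),
                       gene_plan = list(), sine_plan = list(),
                       pop_plan = list(), score_plan = list(),
                       conserve_plan = list()) {
  cfg <- list(
    seed = as.integer(seed),
    genome = list(n_chroms = 2L, chrom_length = 1e6, gc = 0.42),
    ssr_plan = list(
      n_loci = c(`2` = 150L, `3` = 100L, `4` = 120L, `5` = 70L,
                 `6` = 60L),
      repeat_geom_p = 0.5,   # extra repeats beyond the minimum
      max_len = 72L,
      at_weight = 2),        # motif weight = exp(at_weight * AT fraction)
    gene_plan = list(n_genes = 12L, n_exons = 4L, exon_len = 300L,
                     intron_len = 800L, utr5_len = 180L, utr3_len = 150L,
                     frac_tri_utr5 = 0.2),
    sine_plan = list(n_sines = 40L, sine_len = 300L,
                     n_boundary_ssrs = 40L,
                     boundary_motifs = c("AAAT", "AAAC", "AAAG"),
                     boundary_dist = 40L),
    pop_plan = list(n_breeds = 8L, samples_per_breed = 2L,
                    group_of_breed = rep(c("CH", "EU"), each = 4L),
                    het = c(CH = 0.25, EU = 0.10),
                    het_mode = "forced",   # or "hwe"
                    divergence = 0.3,      # Dirichlet concentration
                    fixed_freqs = NULL,    # force identical freqs everywhere
                    missing_rate = 0.1,
                    cov_lambda = 5,
                    q_shape1 = 8, q_shape2 = 2,
                    allele_rate = 0.2,     # Poisson rate per ref repeat
                    indel_noise = 0),
    score_plan = list(base = -0.5, step = 0.2),
    conserve_plan = list(species = .SIM_SPECIES,
                         category_probs = 0.6 ^ (0:14),
                         gap_max = 250L,
                         decoy_rate = 0.25))
  over <- list(genome = genome, ssr_plan = ssr_plan,
               gene_plan = gene_plan, sine_plan = sine_plan,
               pop_plan = pop_plan, score_plan = score_plan,
               conserve_plan = conserve_plan)
  for (nm in names(over))
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
  structure(cfg, class = "sim_config")
}

# interval reservation helper: occupied is a per-chrom list of
# two-column matrices [start, end) with a guard buffer
.sim_free <- function(occupied, chrom, start, end, buffer = 6L) {
  occ <- occupied[[chrom]]
  if (is.null(occ) || nrow(occ) == 0L) return(TRUE)
  !any(start - buffer < occ[, 2L] & end + buffer > occ[, 1L])
}

.sim_reserve <- function(occupied, chrom, start, end) {
  occupied[[chrom]] <- rbind(occupied[[chrom]], c(start, end))
  occupied
}

.sim_place <- function(occupied, chrom_lengths, len, buffer = 6L,
                       chrom = NULL, lo = NULL, hi = NULL,
                       ignore_occupied = FALSE, max_tries = 2000L) {
  for (k in seq_len(max_tries)) {
    ch <- if (is.null(chrom))
      sample(names(chrom_lengths), 1L) else chrom
    a <- if (is.null(lo)) buffer else lo
    b <- if (is.null(hi)) chrom_lengths[[ch]] - buffer - len else hi - len
    if (b < a) next
    s <- a + floor(stats::runif(1L) * (b - a + 1L))
    if (ignore_occupied || .sim_free(occupied, ch, s, s + len, buffer))
      return(list(chrom = ch, start = s, end = s + len))
  }
  stop("simulation plan infeasible: could not place an interval of ",
       len, " bp")
}

.sim_motif_weights <- function(motifs, at_weight) {
  at <- vapply(strsplit(motifs, "", fixed = TRUE), function(z)
    mean(z %in% c("A", "T")), numeric(1L))
  w <- exp(at_weight * at)
  w / sum(w)
}

.sim_random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Simulate a genome with planted SSRs, genes and SINEs
#'
#' Plants perfect SSR tracts (buffered so they cannot extend), gene
#' models and SINE copies on a random background, then iteratively
#' re-samples any background region in which the scanner finds a repeat
#' that was not planted. At return, [scan_sequence()] on each chromosome
#' yields exactly the truth table.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (`DNAStringSet`), `chrom_lengths`, `truth`
#'   (planted catalogue: coordinates, canonical motif, period, repeat
#'   count, `planted_in` tag), `genes` (`GRanges` with GFF3-style
#'   `type`/`ID`/`Parent` columns), `sines` (data.frame) and the config.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gp <- config$genome
  chroms <- paste0("chr", seq_len(gp$n_chroms))
  chrom_lengths <- stats::setNames(rep(gp$chrom_length, gp$n_chroms),
                                   chroms)
  occupied <- stats::setNames(vector("list", length(chroms)), chroms)

  ## --- gene models -------------------------------------------------
  gn <- config$gene_plan
  span <- gn$n_exons * gn$exon_len + (gn$n_exons - 1L) * gn$intron_len
  gene_rows <- list(); utr5_slots <- list()
  for (g in seq_len(gn$n_genes)) {
    strand <- if (g %% 2L == 0L) "-" else "+"
    pl <- .sim_place(occupied, chrom_lengths, span + 4000L,
                     buffer = 2500L)  # keep promoters clear of neighbours
    occupied <- .sim_reserve(occupied, pl$chrom, pl$start,
                             pl$start + span + 4000L)
    tx_start <- pl$start + 2000L
    exon_s <- tx_start + (seq_len(gn$n_exons) - 1L) *
      (gn$exon_len + gn$intron_len)
    exon_e <- exon_s + gn$exon_len
    tx_end <- exon_e[gn$n_exons]
    if (strand == "+") {
      cds_lo <- tx_start + gn$utr5_len; cds_hi <- tx_end - gn$utr3_len
      u5 <- c(tx_start, tx_start + gn$utr5_len)
    } else {
      cds_lo <- tx_start + gn$utr3_len; cds_hi <- tx_end - gn$utr5_len
      u5 <- c(tx_end - gn$utr5_len, tx_end)
    }
    cds_s <- pmax(exon_s, cds_lo); cds_e <- pmin(exon_e, cds_hi)
    keep <- cds_e > cds_s
    # GFF3 phase: bases to skip before the first whole codon, walking
    # the CDS pieces in transcript orientation
    w <- (cds_e - cds_s)[keep]
    if (strand == "-") w <- rev(w)
    ph <- (3L - cumsum(c(0L, w[-length(w)])) %% 3L) %% 3L
    if (strand == "-") ph <- rev(ph)
    gid <- sprintf("gene%02d", g); tid <- sprintf("tx%02d", g)
    gene_rows[[g]] <- data.frame(
      chrom = pl$chrom,
      type = c("gene", "mRNA", rep("exon", gn$n_exons),
               rep("CDS", sum(keep))),
      start = c(tx_start, tx_start, exon_s, cds_s[keep]),
      end = c(tx_end, tx_end, exon_e, cds_e[keep]),
      strand = strand,
      ID = c(gid, tid, sprintf("%s.e%d", tid, seq_len(gn$n_exons)),
             sprintf("%s.c%d", tid, seq_len(sum(keep)))),
      Parent = c(NA, gid, rep(tid, gn$n_exons + sum(keep))),
      phase = c(rep(NA_integer_, 2L + gn$n_exons), ph),
      stringsAsFactors = FALSE)
    utr5_slots[[g]] <- data.frame(chrom = pl$chrom, start = u5[1L],
                                  end = u5[2L], used = FALSE,
                                  stringsAsFactors = FALSE)
  }
  genes_df <- do.call(rbind, gene_rows)
  utr5_slots <- do.call(rbind, utr5_slots)

  ## --- SINE copies --------------------------------------------------
  sp <- config$sine_plan
  sine_rows <- list()
  for (s in seq_len(sp$n_sines)) {
    pl <- .sim_place(occupied, chrom_lengths, sp$sine_len, buffer = 300L)
    occupied <- .sim_reserve(occupied, pl$chrom, pl$start, pl$end)
    sine_rows[[s]] <- data.frame(chrom = pl$chrom, start = pl$start,
                                 end = pl$end, stringsAsFactors = FALSE)
  }
  sines <- do.call(rbind, sine_rows)

  ## --- SSR plan -----------------------------------------------------
  minreps <- period_min_repeats()
  ssr_rows <- list()
  plant_ssr <- function(period, motif, count, where, chrom = NULL,
                        lo = NULL, hi = NULL, ignore_occupied = FALSE) {
    len <- count * period
    pl <- .sim_place(occupied, chrom_lengths, len, buffer = 6L,
                     chrom = chrom, lo = lo, hi = hi,
                     ignore_occupied = ignore_occupied)
    occupied <<- .sim_reserve(occupied, pl$chrom, pl$start, pl$end)
    ssr_rows[[length(ssr_rows) + 1L]] <<- data.frame(
      chrom = pl$chrom, start = pl$start, end = pl$end, motif = motif,
      period = period, repeat_count = count, ref_len = len,
      planted_in = where, stringsAsFactors = FALSE)
  }
  # boundary SSRs hugging SINE edges (A/T-rich, tetranucleotide)
  for (b in seq_len(sp$n_boundary_ssrs)) {
    motif <- sample(sp$boundary_motifs, 1L)
    p <- nchar(motif)
    count <- minreps[[as.character(p)]] + sample(0:2, 1L)
    len <- count * p
    placed <- FALSE
    for (try in seq_len(200L)) {
      si <- sample(nrow(sines), 1L)
      side <- sample(c("left", "right"), 1L)
      off <- sample.int(max(sp$boundary_dist - len, 1L), 1L) - 1L
      s0 <- if (side == "left") sines$start[si] - off - len
        else sines$end[si] + off
      if (s0 < 10L || s0 + len > chrom_lengths[[sines$chrom[si]]] - 10L)
        next
      if (.sim_free(occupied, sines$chrom[si], s0, s0 + len, 6L)) {
        occupied <- .sim_reserve(occupied, sines$chrom[si], s0, s0 + len)
        ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
          chrom = sines$chrom[si], start = s0, end = s0 + len,
          motif = canonical_motif(motif), period = p,
          repeat_count = count, ref_len = len,
          planted_in = "sine_boundary", stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("simulation plan infeasible: SINE boundary SSRs")
  }
  # main plan, with a fraction of trinucleotide loci inside 5'UTRs
  for (p in 2:6) {
    n <- config$ssr_plan$n_loci[[as.character(p)]]
    if (is.null(n) || n == 0L) next
    classes <- enumerate_motif_classes(p)
    w <- .sim_motif_weights(classes, config$ssr_plan$at_weight)
    n_utr <- if (p == 3L)
      min(round(gn$frac_tri_utr5 * n), sum(!utr5_slots$used)) else 0L
    for (i in seq_len(n)) {
      motif <- sample(classes, 1L, prob = w)
      maxc <- config$ssr_plan$max_len %/% p
      count <- min(minreps[[as.character(p)]] +
                     stats::rgeom(1L, config$ssr_plan$repeat_geom_p),
                   maxc)
      if (i <= n_utr) {
        slot <- which(!utr5_slots$used)[1L]
        utr5_slots$used[slot] <- TRUE
        count <- min(count, (utr5_slots$end[slot] -
                               utr5_slots$start[slot] - 14L) %/% p)
        # UTR5 interiors sit inside reserved gene spans; one locus per
        # slot, so the reservation check is bypassed
        plant_ssr(p, motif, count, "utr5",
                  chrom = utr5_slots$chrom[slot],
                  lo = utr5_slots$start[slot] + 7L,
                  hi = utr5_slots$end[slot] - 7L,
                  ignore_occupied = TRUE)
      } else {
        plant_ssr(p, motif, count, "background")
      }
    }
  }
  truth <- do.call(rbind, ssr_rows)
  if (is.null(truth)) {
    truth <- .empty_catalogue()
    truth$planted_in <- character(0L)
  }
  truth <- truth[order(truth$chrom, truth$start, method = "radix"), ,
                 drop = FALSE]
  truth$locus <- sprintf("%s:%d-%d", truth$chrom, truth$start, truth$end)
  rownames(truth) <- NULL

  ## --- sequence synthesis and rejection against the scanner ---------
  seqs <- lapply(chroms, function(ch) {
    x <- .sim_random_bases(chrom_lengths[[ch]], gp$gc)
    tr <- truth[truth$chrom == ch, , drop = FALSE]
    planted <- logical(chrom_lengths[[ch]])
    for (k in seq_len(nrow(tr))) {
      unit <- strsplit(tr$motif[k], "", fixed = TRUE)[[1L]]
      pos <- (tr$start[k] + 1L):tr$end[k]
      x[pos] <- rep_len(unit, length(pos))
      planted[pos] <- TRUE
    }
    enforce_buffers <- function(x) {
      for (k in seq_len(nrow(tr))) {
        unit <- strsplit(tr$motif[k], "", fixed = TRUE)[[1L]]
        pp <- tr$period[k]
        # left buffer: prevent s[start-1] == s[start-1+p] (= unit[p])
        bl <- tr$start[k]          # 1-based index of base before tract
        if (bl >= 1L && x[bl] == unit[pp])
          x[bl] <- sample(setdiff(c("A", "C", "G", "T"), unit[pp]), 1L)
        # right buffer: prevent s[end+1] == s[end+1-p] (= unit[1])
        br <- tr$end[k] + 1L
        if (br <= length(x) && x[br] == unit[1L])
          x[br] <- sample(setdiff(c("A", "C", "G", "T"), unit[1L]), 1L)
      }
      x
    }
    x <- enforce_buffers(x)
    truth_key <- sprintf("%d:%d:%d", tr$start, tr$end, tr$period)
    for (iter in seq_len(80L)) {
      det <- scan_sequence(paste(x, collapse = ""), ch)
      det_key <- sprintf("%d:%d:%d", det$start, det$end, det$period)
      spurious <- det[!det_key %in% truth_key, , drop = FALSE]
      missing <- !truth_key %in% det_key
      if (nrow(spurious) == 0L && !any(missing)) break
      for (k in seq_len(nrow(spurious))) {
        pos <- (spurious$start[k] + 1L):spurious$end[k]
        pos <- pos[!planted[pos]]
        if (length(pos) > 0L)
          x[pos] <- .sim_random_bases(length(pos), gp$gc)
      }
      x <- enforce_buffers(x)
      if (iter == 80L)
        stop("background rejection did not converge on ", ch)
    }
    paste(x, collapse = "")
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chroms

  genes_gr <- GenomicRanges::GRanges(
    genes_df$chrom,
    IRanges::IRanges(genes_df$start + 1L, genes_df$end),
    strand = genes_df$strand)
  genes_gr$type <- genes_df$type
  genes_gr$ID <- genes_df$ID
  genes_gr$Parent <- IRanges::CharacterList(
    lapply(genes_df$Parent, function(z)
      if (is.na(z)) character(0L) else z))
  genes_gr$phase <- genes_df$phase

  list(genome = genome, chrom_lengths = chrom_lengths, truth = truth,
       genes = genes_gr, sines = sines, config = config)
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g <- pmax(g, 1e-9)   # small shapes can underflow to exactly 0
  g / sum(g)
}

#' Simulate breed-structured diploid genotype calls
#'
#' For each locus, a planted allele set is drawn (allele count grows
#' stochastically with the reference repeat count; alleles differ from
#' the reference by whole repeat units unless `indel_noise` is set),
#' breed-specific frequencies are drawn from a Dirichlet around a common
#' base spectrum, and diploid calls are generated per sample with the
#' configured heterozygosity, missing rate, coverage and quality
#' distributions.
#'
#' @param config A [sim_config()].
#' @param catalogue Catalogue (or truth) data.frame with `locus`,
#'   `period`, `repeat_count`, `ref_len` (and coordinates if windowed
#'   statistics are to follow).
#' @return List with `calls` (genotype data.frame), `breed_map`
#'   (`sample`, `breed`, `group`) and `truth` (per-locus planted allele
#'   sets, per-breed frequency list, planted heterozygosity per group).
#' @export
simulate_genotypes <- function(config, catalogue) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  pp <- config$pop_plan
  breeds <- sprintf("breed%02d", seq_len(pp$n_breeds))
  group <- rep_len(pp$group_of_breed, pp$n_breeds)
  samples <- sprintf("%s_s%d", rep(breeds, each = pp$samples_per_breed),
                     seq_len(pp$samples_per_breed))
  breed_of <- rep(breeds, each = pp$samples_per_breed)
  group_of <- rep(group, each = pp$samples_per_breed)
  breed_map <- data.frame(sample = samples, breed = breed_of,
                          group = group_of, stringsAsFactors = FALSE)
  n_loci <- nrow(catalogue)
  rows <- vector("list", n_loci)
  freq_truth <- vector("list", n_loci)
  allele_truth <- vector("list", n_loci)
  for (li in seq_len(n_loci)) {
    p <- catalogue$period[li]; ref <- catalogue$ref_len[li]
    if (!is.null(pp$fixed_freqs)) {
      alleles <- ref + p * (seq_along(pp$fixed_freqs) - 1L)
      base_p <- pp$fixed_freqs / sum(pp$fixed_freqs)
      bf <- lapply(breeds, function(b) stats::setNames(base_p, alleles))
    } else {
      n_extra <- min(stats::rpois(1L, pp$allele_rate *
                                    catalogue$repeat_count[li]), 5L)
      shifts <- sample(setdiff(-3:3, 0L), n_extra)
      alleles <- sort(unique(c(ref, pmax(ref + p * shifts, p))))
      if (pp$indel_noise > 0 && stats::runif(1L) < pp$indel_noise)
        alleles <- sort(unique(c(alleles,
                                 max(ref - 1L, p),
                                 max(ref - 2L, p))))
      base_p <- .rdirichlet1(rep(1.5, length(alleles)))
      bf <- lapply(breeds, function(b)
        stats::setNames(.rdirichlet1(pp$divergence * length(alleles) *
                                       base_p), alleles))
    }
    names(bf) <- breeds
    freq_truth[[li]] <- bf
    allele_truth[[li]] <- alleles
    called <- stats::runif(length(samples)) >= pp$missing_rate
    if (!any(called)) next
    aa <- integer(sum(called)); ab <- integer(sum(called))
    ci <- 0L
    for (si in which(called)) {
      ci <- ci + 1L
      f <- bf[[breed_of[si]]]
      av <- as.integer(names(f))
      if (identical(pp$het_mode, "hwe") || length(av) < 2L) {
        g <- av[sample.int(length(av), 2L, replace = TRUE, prob = f)]
      } else {
        h <- pp$het[[group_of[si]]]
        if (stats::runif(1L) < h) {
          g <- av[sample.int(length(av), 2L, replace = FALSE, prob = f)]
        } else {
          g <- rep(av[sample.int(length(av), 1L, prob = f)], 2L)
        }
      }
      aa[ci] <- min(g); ab[ci] <- max(g)
    }
    rows[[li]] <- data.frame(
      sample = samples[called], locus = catalogue$locus[li],
      allele_a = aa, allele_b = ab,
      q = pmin(stats::rbeta(sum(called), pp$q_shape1, pp$q_shape2),
               1 - 1e-12),
      reads = 1L + stats::rpois(sum(called), pp$cov_lambda),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  list(calls = calls, breed_map = breed_map,
       truth = list(alleles = stats::setNames(allele_truth,
                                              catalogue$locus),
                    freqs = stats::setNames(freq_truth, catalogue$locus),
                    het = pp$het, group_of_breed = group))
}

#' Simulate cross-species flank hits and a conservation score track
#'
#' Assigns each locus a true conservation category (0..14), writes
#' qualifying left/right flank hit pairs for exactly the assigned
#' species, adds decoy hits that violate the pairing rules (gap of
#' exactly the cut-off, different target chromosome, wrong order, or a
#' single side only), and emits a per-base score track whose level
#' increases with category. Track bases covered by the flanks of more
#' than one locus are omitted, so every locus's flank mean equals its
#' planted level exactly.
#'
#' @param config A [sim_config()].
#' @param catalogue Catalogue data.frame with coordinates.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @return List with `hits` (flank hit data.frame), `score_track`
#'   (bedGraph-style data.frame) and `truth` (`locus`, `category`,
#'   `score_level`).
#' @export
simulate_conservation <- function(config, catalogue, chrom_lengths) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  cp <- config$conserve_plan
  sp <- config$score_plan
  n_species <- length(cp$species)
  n <- nrow(catalogue)
  category <- sample(0:n_species, n, replace = TRUE,
                     prob = cp$category_probs)
  hit_rows <- list()
  add_hit <- function(locus, side, species, tchrom, tstart, tend,
                      orient) {
    hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
      locus = locus, side = side, species = species, tchrom = tchrom,
      tstart = tstart, tend = tend, orient = orient,
      stringsAsFactors = FALSE)
  }
  for (li in seq_len(n)) {
    id <- catalogue$locus[li]
    true_sp <- sample(cp$species, category[li])
    for (s in true_sp) {
      orient <- sample(c("+", "-"), 1L)
      tchrom <- sprintf("%s_chr%d", s, sample(1:3, 1L))
      base <- sample.int(1e7, 1L)
      gap <- sample.int(cp$gap_max, 1L) - 1L   # 0 .. gap_max-1 < 300
      if (orient == "+") {
        add_hit(id, "left", s, tchrom, base, base + 200L, orient)
        add_hit(id, "right", s, tchrom, base + 200L + gap,
                base + 400L + gap, orient)
      } else {
        add_hit(id, "right", s, tchrom, base, base + 200L, orient)
        add_hit(id, "left", s, tchrom, base + 200L + gap,
                base + 400L + gap, orient)
      }
    }
    # decoys for species that must NOT count
    for (s in setdiff(cp$species, true_sp)) {
      if (stats::runif(1L) >= cp$decoy_rate) next
      kind <- sample(c("gap_at_cutoff", "diff_chrom", "wrong_order",
                       "one_side"), 1L)
      tchrom <- sprintf("%s_chr%d", s, sample(1:3, 1L))
      base <- sample.int(1e7, 1L)
      if (kind == "gap_at_cutoff") {
        add_hit(id, "left", s, tchrom, base, base + 200L, "+")
        add_hit(id, "right", s, tchrom, base + 500L, base + 700L, "+")
      } else if (kind == "diff_chrom") {
        add_hit(id, "left", s, tchrom, base, base + 200L, "+")
        add_hit(id, "right", s, paste0(tchrom, "b"), base + 250L,
                base + 450L, "+")
      } else if (kind == "wrong_order") {
        add_hit(id, "right", s, tchrom, base, base + 200L, "+")
        add_hit(id, "left", s, tchrom, base + 250L, base + 450L, "+")
      } else {
        add_hit(id, "left", s, tchrom, base, base + 200L, "+")
      }
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(locus = character(), side = character(),
               species = character(), tchrom = character(),
               tstart = integer(), tend = integer(),
               orient = character(), stringsAsFactors = FALSE)
  # score track: per-locus flanks at the planted level; shared bases
  # (covered by two loci's flanks) are dropped so means stay exact
  level <- sp$base + sp$step * category
  fl <- data.frame(
    chrom = rep(catalogue$chrom, 2L),
    start = c(catalogue$start - 200L, catalogue$end),
    end = c(catalogue$start, catalogue$end + 200L),
    value = rep(level, 2L), stringsAsFactors = FALSE)
  fl$start <- pmax(fl$start, 0)
  fl$end <- pmin(fl$end, chrom_lengths[fl$chrom])
  fl <- fl[fl$end > fl$start, , drop = FALSE]
  fgr <- .gr_from_df(fl)
  dj <- GenomicRanges::disjoin(fgr)
  cov <- GenomicRanges::countOverlaps(dj, fgr)
  dj1 <- dj[cov == 1L]
  src <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(dj1, fgr))
  track <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(dj1)),
    start = BiocGenerics::start(dj1) - 1L,
    end = BiocGenerics::end(dj1),
    value = fl$value[src], stringsAsFactors = FALSE)
  track <- track[order(track$chrom, track$start), , drop = FALSE]
  rownames(track) <- NULL
  list(hits = hits,
       score_track = track,
       truth = data.frame(locus = catalogue$locus, category = category,
                          score_level = level, stringsAsFactors = FALSE))
}
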