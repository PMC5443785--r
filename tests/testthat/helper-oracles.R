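# Independent oracles and fixture builders shared across the suite.

# Brute-force perfect-repeat detector: walks every candidate start and
# extends base by base. Independent of the rle-based scanner.
oracle_scan <- function(seq, chrom = "seq", min_len = 10L,
                        min_repeat = 3L) {
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(x)
  rows <- list()
  for (p in 2:6) {
    minrep <- max(ceiling(min_len / p), min_repeat)
    i <- 1L
    while (i + 2L * p - 1L <= n) {
      unit <- x[i:(i + p - 1L)]
      if (!any(unit == "N") &&
          all(x[(i + p):(i + 2L * p - 1L)] == unit) &&
          (i == 1L || x[i - 1L] == "N" || x[i - 1L] != x[i + p - 1L])) {
        j <- i + 2L * p - 1L
        while (j + 1L <= n && x[j + 1L] != "N" &&
               x[j + 1L] == x[j + 1L - p]) j <- j + 1L
        total <- j - i + 1L
        count <- total %/% p
        ustr <- paste(unit, collapse = "")
        if (count >= minrep && count * p >= min_len &&
            is_primitive(ustr)) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, start = i - 1L, end = i - 1L + count * p,
            motif = canonical_motif(ustr), period = p,
            repeat_count = count, ref_len = count * p,
            stringsAsFactors = FALSE)
        }
        i <- j - p + 2L
      } else {
        i <- i + 1L
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), motif = character(),
                      period = integer(), repeat_count = integer(),
                      ref_len = integer(), stringsAsFactors = FALSE))
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Orbit enumeration by explicit string manipulation (no shared helpers):
# groups all primitive k-mers under rotation + reverse complement.
oracle_motif_classes <- function(p) {
  bases <- c("A", "C", "G", "T")
  kmers <- apply(do.call(expand.grid, rep(list(bases), p)), 1L,
                 paste, collapse = "")
  rotations <- function(s) {
    n <- nchar(s)
    vapply(seq_len(n), function(i)
      paste0(substring(s, i, n), substring(s, 1L, i - 1L)), "")
  }
  revcomp <- function(s)
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  primitive <- function(s) {
    n <- nchar(s)
    divs <- seq_len(n - 1L)[n %% seq_len(n - 1L) == 0L]
    !any(vapply(divs, function(d)
      s == paste(rep(substring(s, 1L, d), n / d), collapse = ""),
      logical(1L)))
  }
  kmers <- kmers[vapply(kmers, primitive, logical(1L))]
  reps <- vapply(kmers, function(s)
    min(c(rotations(s), rotations(revcomp(s)))), "")
  sort(unique(unname(reps)))
}

# Naive per-chromosome allele tally for locus statistics.
oracle_locus_stats <- function(calls, locus, n_samples_total) {
  sub <- calls[calls$locus == locus, , drop = FALSE]
  alleles <- c(sub$allele_a, sub$allele_b)
  tab <- table(alleles)
  p <- as.numeric(tab) / length(alleles)
  list(n_called = nrow(sub),
       call_rate = nrow(sub) / n_samples_total,
       mean_coverage = sum(sub$reads) / nrow(sub),
       mean_neglog1mq = mean(-log10(1 - sub$q)),
       n_alleles = length(tab),
       maf = if (length(p) >= 2) sort(p, decreasing = TRUE)[2] else 0,
       het_obs = mean(sub$allele_a != sub$allele_b),
       pic = 1 - sum(p^2))
}

# Small deterministic genotype table.
make_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample = r[[1L]], locus = r[[2L]],
               allele_a = as.integer(r[[3L]]),
               allele_b = as.integer(r[[4L]]),
               q = as.numeric(r[[5L]]), reads = as.integer(r[[6L]]),
               stringsAsFactors = FALSE)))
}

# Toy catalogue of regularly spaced dinucleotide loci.
toy_catalogue <- function(n = 10L, chrom = "chr1", spacing = 1000L,
                          ref_len = 20L, period = 2L) {
  df <- data.frame(chrom = chrom,
                   start = seq_len(n) * spacing,
                   end = seq_len(n) * spacing + ref_len,
                   motif = "AC", period = period,
                   repeat_count = as.integer(ref_len / period),
                   ref_len = as.integer(ref_len),
                   stringsAsFactors = FALSE)
  df$locus <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  df
}

# Minimal two-gene annotation as a GFF3-style GRanges:
#   plus-strand tx with 2 exons (CDS inside exon 1 and 2, UTRs at the
#   ends) and a minus-strand single-exon non-coding transcript.
toy_model_granges <- function() {
  df <- data.frame(
    chrom = "chr1",
    type = c("gene", "mRNA", "exon", "exon", "CDS", "CDS",
             "gene", "transcript", "exon"),
    start1 = c(10001, 10001, 10001, 12001, 10101, 12001,
               30001, 30001, 30001),
    end1 = c(12500, 12500, 11000, 12500, 11000, 12400,
             30800, 30800, 30800),
    strand = c(rep("+", 6L), rep("-", 3L)),
    ID = c("g1", "t1", "t1.e1", "t1.e2", "t1.c1", "t1.c2",
           "g2", "t2", "t2.e1"),
    Parent = c(NA, "g1", "t1", "t1", "t1", "t1", NA, "g2", "t2"),
    stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start1, df$end1), strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(z) if (is.na(z)) character(0L) else z))
  gr
}

# Engineered genotype table for the quality filter: each locus is built
# to fail exactly one criterion (or none); the expected pass set is
# fixed by construction, not by running the filter.
engineered_filter_fixture <- function() {
  n_samples <- 10L
  cat10 <- toy_catalogue(10L)
  cat10$ref_len[9L] <- 90L   # locus 9 fails the <= 80 bp rule
  cat10$end[9L] <- cat10$start[9L] + 90L
  cat10$locus <- sprintf("%s:%d-%d", cat10$chrom, cat10$start, cat10$end)
  good_q <- 0.9      # -log10(0.1) = 1 > 0.6
  bad_q <- 0.5       # -log10(0.5) ~ 0.301 < 0.6
  rows <- list()
  for (li in seq_len(10L)) {
    id <- cat10$locus[li]
    n_called <- if (li == 5L) 5L else 8L      # locus 5: call rate 0.5
    reads <- if (li == 3L) 2L else 6L         # locus 3: coverage 2 <= 3
    q <- if (li == 4L) bad_q else good_q      # locus 4: weak quality
    for (s in seq_len(n_called)) {
      # locus 6 monomorphic; locus 7 has MAF 1/16 < 0.1 (one het carrier)
      g <- if (li == 6L) c(20L, 20L)
      else if (li == 7L) { if (s == 1L) c(20L, 22L) else c(20L, 20L) }
      else { if (s <= n_called / 2) c(20L, 22L) else c(22L, 22L) }
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("s%02d", s), locus = id, allele_a = g[1L],
        allele_b = g[2L], q = q, reads = reads, stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows)
  list(calls = calls, catalogue = cat10, n_samples = n_samples,
       expected_pass = cat10$locus[c(1L, 2L, 8L, 10L)])
}
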