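test_that("random genomes hit the requested composition and are seed-deterministic", {
  g0 <- random_genome(c(a = 5000L), gc = 0, seed = 1)
  expect_false(grepl("[GC]", g0$seq[["a"]]))

  g <- random_genome(c(a = 1000000L), gc = 0.36, seed = 2)
  gc_obs <- gc_count(g, g4_track("a", 0L, 1000000L)) / 1e6
  expect_lt(abs(gc_obs - 0.36), 0.005)

  expect_identical(random_genome(c(a = 20000L), 0.4, seed = 9)$seq,
                   random_genome(c(a = 20000L), 0.4, seed = 9)$seq)
  expect_false(identical(random_genome(c(a = 20000L), 0.4, seed = 9)$seq,
                         random_genome(c(a = 20000L), 0.4, seed = 10)$seq))
})

test_that("planted motifs are all detected, with extras explained by background", {
  g <- random_genome(c(a = 80000L, b = 40000L), gc = 0.2, seed = 3)
  pl <- plant_motifs(g, 10, seed = 4)
  sc <- scan_genome(pl$genome)
  expect_gte(nrow(sc), 10L)
  found <- merge(pl$truth, sc[, c("chrom", "start", "end", "strand")])
  expect_equal(nrow(found), 10L)
  # pre/post scan difference equals the planted count
  expect_equal(nrow(sc) - nrow(pl$background), 10L)

  # minus-strand plants are reported on the minus strand
  plm <- plant_motifs(random_genome(c(a = 50000L), 0.2, seed = 5), 6,
                      prob_minus = 1, seed = 6)
  scm <- scan_genome(plm$genome)
  expect_true(all(plm$truth$strand == "-"))
  expect_equal(nrow(merge(plm$truth, scm[, c("chrom", "start", "end", "strand")])), 6L)

  # an overcrowded request fails loudly
  expect_error(plant_motifs(random_genome(c(t = 400L), 0.2, seed = 7), 50, seed = 8),
               "crowded")
})

test_that("feature co-location fractions are honoured at the extremes", {
  g <- random_genome(c(a = 200000L), 0.36, seed = 11)
  pl <- plant_motifs(g, 40, seed = 12)
  full <- synth_features(pl$genome, pl$truth,
                         list(list(name = "f", n = 30, length = 400, colocate = 1)),
                         seed = 13)$f
  hits <- vapply(seq_len(nrow(full)), function(i)
    count_in_region(pl$truth, full$chrom[i], full$start[i], full$end[i]) > 0, NA)
  expect_true(all(hits))

  gene_cl <- list(name = "genes", n = 25, length = 900, stranded = TRUE,
                  colocate = 0.4, expression = TRUE, template_strand = TRUE)
  genes <- synth_features(pl$genome, pl$truth, list(gene_cl), seed = 14)$genes
  expect_true(all(genes$strand %in% c("+", "-")))
  expect_true(is.numeric(genes$expression))
  # template-strand placement drives the transcribed-strand bias
  sb <- strand_bias_in_genes(pl$truth, genes)
  expect_gte(sb$n_transcribed / sb$n_total, 0.5)
})

test_that("unenriched features show no association signal", {
  set.seed(121)
  hits <- 0L
  for (rep in 1:12) {
    g <- random_genome(c(a = 150000L), 0.36, seed = 200 + rep)
    pl <- plant_motifs(g, 30, seed = 300 + rep)
    feats <- synth_features(pl$genome, pl$truth,
                            list(list(name = "f", n = 25, length = 500, colocate = 0)),
                            seed = 400 + rep)
    cs <- build_control_sets(pl$truth, pl$genome, n_sets = 100, seed = 500 + rep)
    et <- enrichment_test(pl$truth, cs, feats$f, 0, "f")
    if (et$p_value <= 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 2L)
})

test_that("simulated motif density rises with GC and is seed-stable within error", {
  dens <- vapply(c(0.2, 0.3, 0.4, 0.5), function(gc)
    expected_density_by_simulation(gc, 4e5, seed = 17)$per_kb, 0)
  expect_equal(dens[1], sort(dens)[1])
  expect_true(all(diff(dens) > 0))
  expect_equal(expected_density_by_simulation(0, 2e5, seed = 18)$per_kb, 0)

  d1 <- expected_density_by_simulation(0.5, 8e5, seed = 19)
  d2 <- expected_density_by_simulation(0.5, 8e5, seed = 20)
  se <- sqrt(d1$se_per_kb^2 + d2$se_per_kb^2)
  expect_lt(abs(d1$per_kb - d2$per_kb), 3 * se)
})

test_that("synthetic peak sets respect the background-rate contract", {
  g <- random_genome(c(a = 250000L), 0.36, seed = 21)
  pl <- plant_motifs(g, 25, seed = 22, min_spacing = 1200L)
  pk0 <- synth_peaks(pl$genome, pl$truth, frac_peaked = 0.4,
                     background_per_mb = 0, mean_len = 400, sd_len = 60,
                     min_len = 200, seed = 23)
  hit <- associate_motifs(pl$truth, pk0, 0)
  expect_equal(which(as.logical(hit)), attr(pk0, "peaked_ids"))
  expect_equal(length(attr(pk0, "peaked_ids")), 10L)
  expect_true(all(pk0$signif >= 5))
  # with background, associations are a superset of the planted ones
  pkb <- synth_peaks(pl$genome, pl$truth, frac_peaked = 0.4,
                     background_per_mb = 20, mean_len = 400, sd_len = 60,
                     min_len = 200, seed = 23)
  hb <- associate_motifs(pl$truth, pkb, 0)
  expect_true(all(as.logical(hit)[as.logical(hb) == FALSE] == FALSE))
  expect_gte(sum(hb), sum(hit))
})

test_that("round-trip through on-disk formats preserves a simulated study", {
  g <- random_genome(c(a = 60000L), 0.36, seed = 31)
  pl <- plant_motifs(g, 8, seed = 32)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "genome.fa")
  write_genome_fasta(pl$genome, fa)
  g2 <- read_genome_fasta(fa)
  expect_identical(g2$seq, pl$genome$seq)
  expect_equal(scan_genome(g2)[, c("chrom", "start", "end", "strand")],
               scan_genome(pl$genome)[, c("chrom", "start", "end", "strand")])

  pk <- synth_peaks(pl$genome, pl$truth, frac_peaked = 0.5,
                    background_per_mb = 10, seed = 33)
  np <- file.path(dir, "peaks.narrowPeak")
  write_narrowpeak(pk, np)
  pk2 <- read_intervals(np, "narrowPeak")
  expect_equal(pk2[, c("chrom", "start", "end")], pk[, c("chrom", "start", "end")],
               ignore_attr = TRUE)
  expect_equal(pk2$signif, pk$signif, tolerance = 1e-6)
})
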