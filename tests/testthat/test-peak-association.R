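test_that("motif-peak association respects the edge-gap window", {
  motifs <- g4_track("c1", 1700L, 1730L, "+")
  peaks <- peak_set(g4_track("c1", 1000L, 1500L, "*", signif = 8), "Pfh1", "wt")
  expect_true(associate_motifs(motifs, peaks, 300)[1])   # gap 200
  expect_false(associate_motifs(motifs, peaks, 0)[1])
  # windows nest: 0 implies 300 implies 500
  set.seed(101)
  m <- g4_track("c1", ms <- sample.int(50000L, 60), ms + 20L)
  p <- peak_set(g4_track("c1", ps <- sample.int(50000L, 15), ps + 1000L, "*",
                         signif = runif(15, 5, 30)), "f", "c")
  a0 <- associate_motifs(m, p, 0); a300 <- associate_motifs(m, p, 300)
  a500 <- associate_motifs(m, p, 500)
  expect_true(all(a300[a0]))
  expect_true(all(a500[a300]))
})

test_that("planted peak fixtures are recovered exactly with zero background", {
  g <- random_genome(c(c1 = 200000L), 0.36, seed = 15)
  pl <- plant_motifs(g, 30, seed = 16, min_spacing = 1200L)
  ids <- sort(sample(seq_len(30), 12))
  # short peaks so a peak can only touch the motif it was planted on
  pk <- synth_peaks(pl$genome, pl$truth, peaked_ids = ids,
                    background_per_mb = 0, mean_len = 400, sd_len = 60,
                    min_len = 200, seed = 17)
  hit <- associate_motifs(pl$truth, pk, 300)
  expect_equal(which(hit), ids)
  ph <- attr(hit, "peak_hits")
  expect_true(all(ph))
})

test_that("motif classes follow the helicase-dependence definitions on all 32 patterns", {
  pats <- expand.grid(pfh1_wt = c(FALSE, TRUE), cdc20_wt = c(FALSE, TRUE),
                      cdc20_dep = c(FALSE, TRUE), gh2a_wt = c(FALSE, TRUE),
                      gh2a_dep = c(FALSE, TRUE))
  pats$motif_id <- seq_len(nrow(pats))
  cl <- classify_motifs(pats)
  # independent restatement of the definitions
  for (i in seq_len(nrow(pats))) {
    uw <- pats$cdc20_wt[i] || pats$gh2a_wt[i]
    ud <- pats$cdc20_dep[i] || pats$gh2a_dep[i]
    expect_equal(cl$class_I[i], pats$pfh1_wt[i])
    expect_equal(cl$class_II[i], ud && !uw)
    expect_equal(cl$class_III[i], uw && ud)
  }
  expect_false(any(cl$class_II & cl$class_III))
  expect_error(classify_motifs(pats[, 1:3]), "missing column")

  # single-pattern sanity: Pfh1 only -> Class I only; damage in both -> III
  one <- data.frame(motif_id = 1:3,
                    pfh1_wt = c(TRUE, FALSE, FALSE),
                    cdc20_wt = FALSE,
                    cdc20_dep = c(FALSE, TRUE, FALSE),
                    gh2a_wt = c(FALSE, FALSE, TRUE),
                    gh2a_dep = c(FALSE, FALSE, TRUE))
  lab <- classify_motifs(one)$label
  expect_equal(lab, c("I", "II", "III"))
})

test_that("classification recovers a planted partition from noise-free peaks", {
  g <- random_genome(c(c1 = 400000L), 0.36, seed = 25)
  pl <- plant_motifs(g, 60, seed = 26, min_spacing = 1500L)
  n <- nrow(pl$truth)
  set.seed(113)
  idx <- sample(seq_len(n))
  pfh1_ids <- sort(idx[1:15])
  # class III motifs: unstable in both conditions; class II: only depleted
  iii_ids <- sort(idx[16:30]); ii_ids <- sort(idx[31:45])
  mk <- function(ids, fac, cond, seed) {
    # short peaks: each signal peak can only touch its own motif, so the
    # noise-free association is exactly the planted subset
    synth_peaks(pl$genome, pl$truth, peaked_ids = ids, background_per_mb = 0,
                mean_len = 400, sd_len = 60, min_len = 200,
                factor = fac, condition = cond, seed = seed)
  }
  sets <- list(
    pfh1_wt = mk(pfh1_ids, "Pfh1", "wt", 27),
    cdc20_wt = mk(iii_ids, "Cdc20", "wt", 28),
    cdc20_dep = mk(sort(c(iii_ids, ii_ids)), "Cdc20", "dep", 29),
    gh2a_wt = mk(integer(), "gH2A", "wt", 30),
    gh2a_dep = mk(ii_ids, "gH2A", "dep", 31))
  win <- c(pfh1_wt = 0, cdc20_wt = 0, cdc20_dep = 0, gh2a_wt = 0, gh2a_dep = 0)
  assoc <- build_association_matrix(pl$truth, sets, win)
  cl <- classify_motifs(assoc)
  expect_false(any(cl$class_II & cl$class_III))
  expect_equal(which(cl$class_I), pfh1_ids)
  expect_equal(which(cl$class_II), ii_ids)
  expect_equal(which(cl$class_III), iii_ids)
})

test_that("Fisher's exact test matches enumeration and the printed convention", {
  expect_equal(fisher_exact_2x2(contingency_2x2(1, 1, 1, 1)), 1)
  set.seed(111)
  for (i in 1:120) {
    tot <- sample(4:30, 1)
    cnt <- as.vector(stats::rmultinom(1, tot, rep(0.25, 4)))
    if (sum(cnt[1:2]) == 0 || sum(cnt[3:4]) == 0) next
    if (sum(cnt[c(1, 3)]) == 0 || sum(cnt[c(2, 4)]) == 0) next
    got <- fisher_exact_2x2(contingency_2x2(cnt[1], cnt[2], cnt[3], cnt[4]))
    want <- oracle_fisher_two_sided(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(got, want, tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(contingency_2x2(0, 0, 1, 2)), NA)
})

test_that("contingency tables report counts and row percentages consistently", {
  assoc <- data.frame(pfh1 = rep(c(TRUE, FALSE), c(90, 356)),
                      cdc20 = c(rep(c(TRUE, FALSE), c(36, 54)),
                                rep(c(TRUE, FALSE), c(14, 342))))
  bt <- build_table(assoc, "pfh1", "cdc20")
  expect_equal(as.vector(t(unclass(bt$table))), c(36L, 54L, 14L, 342L))
  expect_equal(unname(round(bt$row_percent)), c(40, 4))
  expect_equal(unname(bt$row_percent[1]), 100 * 36 / 90)

  allf <- data.frame(s = c(TRUE, TRUE, FALSE), o = FALSE)
  bt2 <- build_table(allf, "s", "o")
  expect_equal(sum(unclass(bt2$table)[, 1]), 0L)
})

test_that("paired peak-significance comparison handles degenerate and one-sided cases", {
  motifs <- g4_track("c1", (0:9) * 10000L + 100L, (0:9) * 10000L + 130L, "+")
  mk_peaks <- function(sig) {
    peak_set(g4_track("c1", motifs$start - 50L, motifs$end + 50L, "*", signif = sig),
             "gH2A", "x")
  }
  siga <- 8 + (0:9) / 10
  pa <- mk_peaks(siga)
  expect_warning(r <- paired_peak_significance_comparison(motifs, pa, pa, 5000),
                 "degenerate")
  expect_equal(r$wilcoxon_p, 1)

  # condition B uniformly more significant at every motif
  pb <- mk_peaks(siga + 7)
  r2 <- paired_peak_significance_comparison(motifs, pa, pb, 5000)
  expect_lt(r2$mean_pB, r2$mean_pA)
  d <- 10^-siga - 10^-(siga + 7)
  expect_equal(r2$wilcoxon_p, oracle_signed_rank(d), tolerance = 1e-8)

  # unpeaked motifs get P = 1
  sparse <- peak_set(g4_track("c1", 90L, 200L, "*", signif = 10), "gH2A", "x")
  r3 <- paired_peak_significance_comparison(motifs, sparse, sparse[0, ], 0)
  expect_equal(r3$mean_pB, 1)
  expect_equal(r3$mean_pA, (9 + 1e-10) / 10)
})
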