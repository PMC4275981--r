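test_that("the association window rule handles adjacency and gap boundaries", {
  a <- g4_track("c1", 0L, 10L)
  expect_false(is_associated(a, g4_track("c1", 10L, 20L), 0))
  expect_true(is_associated(a, g4_track("c1", 10L, 20L), 1))
  expect_true(is_associated(a, g4_track("c1", 310L, 320L), 300))   # gap 300
  expect_false(is_associated(a, g4_track("c1", 311L, 320L), 300))  # gap 301
  expect_true(is_associated(a, g4_track("c1", 5L, 8L), 0))         # containment
  expect_false(is_associated(a, g4_track("c2", 0L, 10L), 300))     # other chrom
  expect_error(is_associated(a, a, -5), "window")
})

test_that("query-side association counts match the quadratic oracle", {
  motifs <- g4_track("c1", c(0L, 100L, 400L), c(10L, 120L, 420L))
  feat <- g4_track("c1", 105L, 410L)
  expect_equal(count_associated(motifs, feat, 0), 2L)
  expect_equal(count_associated(motifs, g4_track("c1", integer(), integer())[0, ], 0), 0L)
  set.seed(71)
  for (i in 1:20) {
    q <- g4_track(chrom = sample(c("a", "b"), 40, TRUE),
                  start = qs <- sample.int(5000L, 40), end = qs + sample.int(200L, 40))
    s <- g4_track(chrom = sample(c("a", "b"), 25, TRUE),
                  start = ss <- sample.int(5000L, 25), end = ss + sample.int(400L, 25))
    for (w in c(0, 1, 50, 300)) {
      expect_equal(count_associated(q, s, w), oracle_count_associated(q, s, w))
    }
  }
})

test_that("empirical P-values count ties as extreme and never return zero by default", {
  expect_equal(empirical_p(54, rep(10, 1000), "enriched"), 1 / 1001)
  expect_equal(empirical_p(5, rep(5, 100), "enriched"), 1)
  expect_equal(empirical_p(5, rep(5, 100), "depleted"), 1)
  nulls <- rep(5:14, each = 100)
  expect_equal(empirical_p(10, nulls, "enriched"), 501 / 1001)
  expect_equal(empirical_p(10, nulls, "enriched", mode = "paper-literal"), 0.5)
  expect_equal(empirical_p(54, rep(10, 1000), "enriched", mode = "paper-literal"), 0)
  # enrichment and depletion P for the same data sum to >= 1
  set.seed(3)
  for (i in 1:20) {
    nc <- rpois(100, 8); obs <- rpois(1, 8)
    expect_gte(empirical_p(obs, nc, "enriched") + empirical_p(obs, nc, "depleted"), 1)
  }
  expect_error(empirical_p(1, numeric()), "non-empty")
})

test_that("enrichment_test saturates on a whole-genome feature and zeroes on unreachable ones", {
  g <- random_genome(c(c1 = 150000L), 0.36, seed = 5)
  pl <- plant_motifs(g, 25, seed = 6)
  cs <- build_control_sets(pl$truth, pl$genome, n_sets = 50, seed = 7)
  whole <- g4_track("c1", 0L, g$lengths[["c1"]])
  et <- enrichment_test(pl$truth, cs, whole, 0, "genome", mode = "paper-literal")
  expect_equal(et$observed, nrow(pl$truth))
  expect_equal(et$expected, nrow(pl$truth))
  expect_equal(et$p_value, 1)

  none <- g4_track("none", integer(), integer())[0, ]
  et0 <- enrichment_test(pl$truth, cs, none, 0, "empty")
  expect_equal(et0$observed, 0L)
  expect_error(enrichment_test(pl$truth[1:3, ], cs, whole, 0), "control sets")
})

test_that("q-values reduce to Benjamini-Hochberg when pi0 = 1 and are monotone", {
  expect_equal(qvalues(rep(1, 30)), rep(1, 30))
  set.seed(81)
  for (i in 1:50) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    p[p == 0] <- 1e-12
    q <- qvalues(p, pi0 = 1)
    expect_equal(q, p.adjust(p, "BH"))
    o <- order(p)
    expect_true(all(diff(qvalues(p)[o]) >= -1e-12))
  }
  # Storey pi0 estimate shrinks q-values when many tests are non-null
  set.seed(82)
  p <- c(runif(300, 0, 0.001), runif(100))
  expect_true(all(qvalues(p) <= p.adjust(p, "BH") + 1e-12))
  expect_error(qvalues(c(0.5, 0)), "0, 1")
  expect_error(qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("transcribed-strand bias counts motifs opposite the gene strand", {
  motifs <- g4_track("c1", c(10L, 200L, 400L), c(25L, 215L, 415L),
                     strand = c("-", "+", "+"))
  genes <- g4_track("c1", c(0L, 150L, 390L), c(100L, 300L, 500L),
                    strand = c("+", "+", "-"))
  r <- strand_bias_in_genes(motifs, genes)
  # motif1: -/+ transcribed; motif2: +/+ coding; motif3: +/- transcribed
  expect_equal(r$n_transcribed, 2L)
  expect_equal(r$n_total, 3L)
  expect_equal(r$p_value, binom.test(2, 3, 0.5)$p.value)
  expect_lt(binom.test(219, 303, 0.5)$p.value, 1e-12)
  expect_equal(binom.test(150, 300, 0.5)$p.value, 1)
  expect_error(strand_bias_in_genes(motifs, g4_track("c1", 0L, 9L, "*")), "unstranded")
})

test_that("multi-gene overlaps resolve to the largest overlap", {
  motifs <- g4_track("c1", 90L, 130L, "+")
  genes <- g4_track("c1", c(0L, 100L), c(100L, 300L), c("+", "-"),
                    name = c("small", "big"))
  # overlap with 'small' = 10 bp, with 'big' = 30 bp -> big (strand -) wins
  r <- strand_bias_in_genes(motifs, genes)
  expect_equal(r$n_transcribed, 1L)
})

test_that("top-expressed selection matches a full sort", {
  set.seed(91)
  genes <- g4_track("c1", st <- sample.int(10000L, 40), st + 100L, "+",
                    name = sprintf("g%02d", 1:40),
                    expression = round(rlnorm(40, 3, 2), 3))
  top3 <- select_top_expressed(genes, 3)
  expect_equal(sort(top3$expression, decreasing = TRUE),
               sort(genes$expression, decreasing = TRUE)[1:3])
  expect_equal(nrow(select_top_expressed(genes, 100)), 40L)
  o <- order(-genes$expression, genes$name)
  expect_equal(select_top_expressed(genes, 10)$name, genes$name[o][1:10])
  expect_error(select_top_expressed(genes[, setdiff(names(genes), "expression")], 3),
               "expression")
})
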