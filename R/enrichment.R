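#' Are two intervals associated at a window?
#'
#' `window = 0` demands strict overlap; `window > 0` also admits a gap
#' (bases strictly between the intervals) of at most `window` bp, the rule
#' used for peak association (300 bp, the ChIP shearing size, for helicase
#' and polymerase peaks; 5 kb for the damage mark, which spreads around a
#' break). Intervals on different chromosomes are never associated.
#'
#' @param a,b tracks or single-row data.frames with chrom/start/end.
#' @param window non-negative bp.
#' @return logical (vectorised over rows, recycled as usual).
#' @export
is_associated <- function(a, b, window = 0) {
  w2 <- window_threshold(window)
  (a$chrom == b$chrom) &
    (a$start - b$end <= w2) &
    (b$start - a$end <= w2)
}

#' Count query intervals associated with at least one subject interval
#'
#' Each query element is counted once no matter how many subject elements
#' it touches (an enrichment table counts motifs, not motif-feature pairs).
#'
#' @param query,subject track data.frames.
#' @param window association window in bp (see [is_associated()]).
#' @return integer count of query rows with >= 1 association.
#' @export
count_associated <- function(query, subject, window = 0) {
  if (nrow(query) == 0L || nrow(subject) == 0L) return(0L)
  prep <- prepare_subjects(subject, window)
  sum(hits_any(prep, query$chrom, query$start, query$end))
}

#' Empirical P-value against a resampling null
#'
#' `b` is the number of null counts at least as extreme as the observation
#' (ties count as extreme on both sides). The default add-one estimator
#' `(b+1)/(n+1)` never returns 0 — the observation itself is one more draw
#' under the null. The "paper-literal" mode returns `b/n`, which can report
#' 0 when no null set is as extreme.
#'
#' @param observed observed count.
#' @param null_counts numeric vector of null counts (length n_sets >= 1).
#' @param direction "enriched" (null >= observed extreme) or "depleted".
#' @param mode "add-one" (default) or "paper-literal".
#' @return a probability.
#' @export
empirical_p <- function(observed, null_counts,
                        direction = c("enriched", "depleted"),
                        mode = c("add-one", "paper-literal")) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  n <- length(null_counts)
  if (n < 1L) stop_g4("null_counts must be non-empty")
  b <- if (direction == "enriched") sum(null_counts >= observed)
       else sum(null_counts <= observed)
  if (mode == "add-one") (b + 1) / (n + 1) else b / n
}

#' Test motif-feature association against the matched-control null
#'
#' The observed statistic is the number of motifs associated with >= 1
#' feature interval; the null distribution is the same count over each
#' control set. The reported direction is "enriched" when the observation
#' exceeds the null mean, else "depleted", with the corresponding one-sided
#' empirical P.
#'
#' @param motifs motif track the control sets were built from.
#' @param controls a [build_control_sets()] result for those motifs.
#' @param feature feature track.
#' @param window association window in bp.
#' @param feature_name label for reporting.
#' @param mode empirical-P mode, see [empirical_p()].
#' @return object of class `g4_enrichment` (also a one-row data.frame via
#'   [enrichment_report()]).
#' @export
enrichment_test <- function(motifs, controls, feature, window = 0,
                            feature_name = "feature",
                            mode = c("add-one", "paper-literal")) {
  mode <- match.arg(mode)
  if (nrow(motifs) != nrow(controls$motifs)) {
    stop_g4("control sets were built for %d motifs, got %d",
            nrow(controls$motifs), nrow(motifs))
  }
  prep <- prepare_subjects(feature, window)
  observed <- sum(hits_any(prep, motifs$chrom, motifs$start, motifs$end))
  ends <- controls$starts + controls$lengths
  null_counts <- vapply(seq_len(controls$n_sets), function(i) {
    sum(hits_any(prep, controls$motifs$chrom,
                 controls$starts[, i], ends[, i]))
  }, 0L)
  expected <- mean(null_counts)
  direction <- if (observed > expected) "enriched" else "depleted"
  p <- empirical_p(observed, null_counts, direction, mode)
  structure(list(feature_name = feature_name,
                 n_features = nrow(feature),
                 observed = observed, expected = expected,
                 null_counts = null_counts,
                 direction = direction, p_value = p,
                 window = window, mode = mode),
            class = "g4_enrichment")
}

#' @export
print.g4_enrichment <- function(x, ...) {
  cat(sprintf("%s: observed %d vs expected %.1f (%s), empirical P = %.4g [window %g bp]\n",
              x$feature_name, x$observed, x$expected, x$direction,
              x$p_value, x$window))
  invisible(x)
}

#' Tabulate enrichment tests and attach q-values
#'
#' @param tests list of [enrichment_test()] results.
#' @param q_threshold significance call threshold (default 0.05).
#' @return data.frame with one row per feature class, mirroring a
#'   motif-status table: observed, expected, direction, P, q, significant.
#' @export
enrichment_report <- function(tests, q_threshold = 0.05) {
  df <- do.call(rbind, lapply(tests, function(x) {
    data.frame(feature = x$feature_name, n_features = x$n_features,
               observed = x$observed, expected = x$expected,
               direction = x$direction, p_value = x$p_value,
               window = x$window, stringsAsFactors = FALSE)
  }))
  df$q_value <- qvalues(df$p_value)
  df$significant <- df$q_value < q_threshold
  df
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0, 0.05, ..., 0.90
#' with a cubic smoothing spline evaluated at the largest lambda, clamped
#' to (0, 1], then applies the step-up rule
#' `q_i = min over {j : p_j >= p_i} of pi0 * n * p_j / rank_j`.
#' With fewer than 20 tests (or a failed spline fit) pi0 falls back to 1,
#' which reduces exactly to Benjamini-Hochberg.
#'
#' @param p P-values in (0, 1].
#' @param pi0 optional fixed pi0 (e.g. 1 forces Benjamini-Hochberg).
#' @return q-values, same order as `p`.
#' @export
qvalues <- function(p, pi0 = NULL) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop_g4("p-values must lie in (0, 1]")
  }
  n <- length(p)
  if (is.null(pi0)) {
    pi0 <- if (n < 20L) 1 else estimate_pi0(p)
  }
  if (pi0 <= 0 || pi0 > 1) stop_g4("pi0 must lie in (0, 1]")
  o <- order(p, decreasing = TRUE)
  r <- rank(p, ties.method = "max")
  q <- pi0 * n * p / r
  q[o] <- cummin(q[o])
  pmin(q, 1)
}

estimate_pi0 <- function(p, lambda = seq(0, 0.90, 0.05)) {
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
  fit <- tryCatch(smooth.spline(lambda, pi0_l, df = 3),
                  error = function(e) NULL)
  if (is.null(fit)) return(1)
  pi0 <- predict(fit, x = max(lambda))$y
  min(max(pi0, .Machine$double.eps), 1)
}

#' Transcribed-strand bias of motifs inside stranded genes
#'
#' A motif overlapping a gene lies on the transcribed (template) strand iff
#' its strand differs from the gene's annotated (coding) strand — such a
#' motif is absent from the mRNA. Motifs overlapping several genes are
#' resolved to the gene with the largest overlap (ties to the first gene in
#' (chrom, start) order; both events are logged). The null of no bias is a
#' two-sided exact binomial test at probability 0.5.
#'
#' @param motifs stranded motif track.
#' @param genes stranded gene track; unstranded records are an error.
#' @return list(n_transcribed, n_total, p_value).
#' @export
strand_bias_in_genes <- function(motifs, genes) {
  if (any(genes$strand == "*")) stop_g4("gene track contains unstranded intervals")
  if (any(motifs$strand == "*")) stop_g4("motif track contains unstranded intervals")
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  n_multi <- 0L
  n_tie <- 0L
  hit_strand <- character(0)
  for (i in seq_len(nrow(motifs))) {
    g <- which(genes$chrom == motifs$chrom[i] &
               genes$start < motifs$end[i] &
               motifs$start[i] < genes$end)
    if (!length(g)) next
    if (length(g) > 1L) {
      ov <- pmin(genes$end[g], motifs$end[i]) - pmax(genes$start[g], motifs$start[i])
      n_multi <- n_multi + 1L
      if (sum(ov == max(ov)) > 1L) n_tie <- n_tie + 1L
      g <- g[which.max(ov)]
    }
    hit_strand <- c(hit_strand, if (motifs$strand[i] != genes$strand[g]) "T" else "C")
  }
  if (n_multi) {
    g4_log("%d motif(s) overlapped multiple genes (largest overlap kept; %d tie(s) broken by gene order)",
           n_multi, n_tie)
  }
  n_total <- length(hit_strand)
  n_trans <- sum(hit_strand == "T")
  p <- if (n_total == 0L) NA_real_ else binom.test(n_trans, n_total, 0.5)$p.value
  list(n_transcribed = n_trans, n_total = n_total, p_value = p)
}

#' Select the most highly expressed genes
#'
#' @param genes track with a numeric `expression` column.
#' @param n number of genes to keep (500 in the canonical analysis; 100 as
#'   a robustness check). Ties at the cutoff are broken by gene name
#'   (logged).
#' @return the top-n sub-track.
#' @export
select_top_expressed <- function(genes, n = 500L) {
  if (!"expression" %in% names(genes) || !is.numeric(genes$expression)) {
    stop_g4("gene track must carry a numeric 'expression' column")
  }
  if (n >= nrow(genes)) return(genes)
  id <- if ("name" %in% names(genes)) genes$name else as.character(seq_len(nrow(genes)))
  o <- order(-genes$expression, id)
  cut <- genes$expression[o][n]
  if (sum(genes$expression == cut) > 1L) {
    g4_log("expression ties at the top-%d cutoff broken by gene id", n)
  }
  out <- genes[o[seq_len(n)], , drop = FALSE]
  rownames(out) <- NULL
  out
}
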