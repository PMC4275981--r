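#' ChIP-seq peak set constructor
#'
#' Peaks are consumed as called intervals with a per-peak significance on
#' the -log10 P scale (narrowPeak column 8); calling itself is upstream of
#' this package. The upstream caller's P cutoff is carried as metadata.
#'
#' @param track track data.frame with a `signif` column (-log10 P).
#' @param factor factor label (e.g. "Pfh1", "Cdc20", "gH2A").
#' @param condition condition label (e.g. "expressed", "depleted").
#' @param source_cutoff upstream -log10 P calling threshold (default 5).
#' @return the track with class `g4_peaks` and metadata attributes.
#' @export
peak_set <- function(track, factor = "factor", condition = "condition",
                     source_cutoff = 5) {
  track <- validate_track(track)
  if (!"signif" %in% names(track)) stop_g4("peak track needs a 'signif' column")
  if (nrow(track) && (any(!is.finite(track$signif)) || any(track$signif < 0))) {
    stop_g4("peak significance (-log10 P) must be finite and non-negative")
  }
  structure(track, class = c("g4_peaks", class(track)),
            factor = factor, condition = condition,
            source_cutoff = source_cutoff)
}

#' Associate motifs with a peak set
#'
#' @param motifs motif track.
#' @param peaks peak track (a [peak_set()] or any track).
#' @param window association window in bp; edge-to-edge gap rule of
#'   [is_associated()].
#' @return logical vector, one per motif; the symmetric peak-side vector
#'   (peaks associated with >= 1 motif) is attached as attribute
#'   `"peak_hits"` — several peaks can hit one motif and vice versa.
#' @export
associate_motifs <- function(motifs, peaks, window = 300) {
  if (nrow(motifs) == 0L) return(logical())
  if (nrow(peaks) == 0L) {
    out <- rep(FALSE, nrow(motifs))
    attr(out, "peak_hits") <- logical(0)
    return(out)
  }
  prep_p <- prepare_subjects(peaks, window)
  out <- hits_any(prep_p, motifs$chrom, motifs$start, motifs$end)
  prep_m <- prepare_subjects(motifs, window)
  attr(out, "peak_hits") <- hits_any(prep_m, peaks$chrom, peaks$start, peaks$end)
  out
}

#' Build the motif x experiment association matrix
#'
#' @param motifs motif track.
#' @param peak_sets named list of peak tracks; canonical names are
#'   `pfh1_wt`, `cdc20_wt`, `cdc20_dep`, `gh2a_wt`, `gh2a_dep`.
#' @param windows named numeric vector of association windows, one per peak
#'   set (300 bp for helicase/polymerase peaks, 5000 bp for the damage
#'   mark).
#' @return data.frame: `motif_id` plus one logical column per peak set,
#'   with the windows stored in attribute `"windows"`.
#' @export
build_association_matrix <- function(motifs, peak_sets, windows) {
  if (is.null(names(peak_sets)) || any(names(peak_sets) == "")) {
    stop_g4("peak_sets must be a named list")
  }
  miss <- setdiff(names(peak_sets), names(windows))
  if (length(miss)) stop_g4("no window given for: %s", paste(miss, collapse = ", "))
  out <- data.frame(motif_id = seq_len(nrow(motifs)))
  for (nm in names(peak_sets)) {
    out[[nm]] <- as.logical(associate_motifs(motifs, peak_sets[[nm]],
                                             windows[[nm]]))
  }
  attr(out, "windows") <- windows[names(peak_sets)]
  out
}

#' Classify motifs by helicase dependence
#'
#' Class I: bound by the helicase in wild-type cells. Per condition,
#' "instability" is fork pausing and/or DNA damage (polymerase OR damage
#' mark association). Class II: unstable only after helicase depletion.
#' Class III: unstable in both conditions. Classes II and III are disjoint
#' by construction; Class I may intersect either.
#'
#' @param assoc association matrix from [build_association_matrix()] with
#'   columns `pfh1_wt`, `cdc20_wt`, `cdc20_dep`, `gh2a_wt`, `gh2a_dep`.
#' @return data.frame with logical columns `class_I`, `class_II`,
#'   `class_III` and a readable `label` column.
#' @export
classify_motifs <- function(assoc) {
  need <- c("pfh1_wt", "cdc20_wt", "cdc20_dep", "gh2a_wt", "gh2a_dep")
  miss <- setdiff(need, names(assoc))
  if (length(miss)) stop_g4("association matrix missing column(s): %s",
                            paste(miss, collapse = ", "))
  unstable_wt <- assoc$cdc20_wt | assoc$gh2a_wt
  unstable_dep <- assoc$cdc20_dep | assoc$gh2a_dep
  cl <- data.frame(motif_id = assoc$motif_id,
                   class_I = assoc$pfh1_wt,
                   class_II = unstable_dep & !unstable_wt,
                   class_III = unstable_wt & unstable_dep)
  lab <- apply(cl[, c("class_I", "class_II", "class_III")], 1L, function(x) {
    if (!any(x)) "none" else paste(c("I", "II", "III")[x], collapse = "+")
  })
  cl$label <- lab
  cl
}

#' Validated 2x2 contingency table
#'
#' Layout: rows are the stratum (TRUE / FALSE), columns the outcome
#' (TRUE / FALSE): `a` stratum+outcome, `b` stratum+no-outcome, `c`
#' no-stratum+outcome, `d` neither.
#'
#' @param a,b,c,d non-negative counts.
#' @return matrix of class `g4_table2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop_g4("counts must be non-negative integers")
  if (sum(cnt) == 0) stop_g4("table total must be > 0")
  m <- matrix(as.integer(cnt), 2L, 2L, byrow = TRUE,
              dimnames = list(stratum = c("yes", "no"),
                              outcome = c("yes", "no")))
  class(m) <- c("g4_table2x2", class(m))
  m
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with fixed margins. `alternative =
#' "two.sided"` uses the point-probability rule (all tables with point
#' probability <= the observed one); `"greater"` is the one-sided
#' enrichment test, the convention under which the fork-pausing and
#' DNA-damage contingency tables print their P-values.
#'
#' @param tbl a [contingency_2x2()] (or plain 2x2 matrix).
#' @param alternative "two.sided", "greater" or "less".
#' @return the P-value.
#' @export
fisher_exact_2x2 <- function(tbl, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  m <- unclass(tbl)
  if (!is.matrix(m) || !all(dim(m) == 2L)) stop_g4("need a 2x2 table")
  if (any(rowSums(m) == 0) && any(colSums(m) == 0)) stop_g4("degenerate all-zero margin")
  fisher.test(m, alternative = alternative)$p.value
}

#' Build a 2x2 table from two association-matrix columns
#'
#' @param assoc association matrix ([build_association_matrix()] output or
#'   any data.frame of logicals).
#' @param stratum_col,outcome_col column names.
#' @return list with the [contingency_2x2()] `table` and `row_percent`
#'   (percent of each stratum row with the outcome).
#' @export
build_table <- function(assoc, stratum_col, outcome_col) {
  for (cn in c(stratum_col, outcome_col)) {
    if (!cn %in% names(assoc)) stop_g4("no column '%s' in association matrix", cn)
  }
  s <- assoc[[stratum_col]]
  o <- assoc[[outcome_col]]
  tb <- contingency_2x2(sum(s & o), sum(s & !o), sum(!s & o), sum(!s & !o))
  list(table = tb,
       row_percent = c(stratum_yes = 100 * tb[1, 1] / max(sum(tb[1, ]), 1L),
                       stratum_no = 100 * tb[2, 1] / max(sum(tb[2, ]), 1L)))
}

#' Paired comparison of peak significance at motifs across two conditions
#'
#' For each motif, the most significant overlapping peak (largest -log10 P)
#' within `window` is taken in each condition; motifs with no peak in a
#' condition get P = 1. Returns the per-condition mean P and the two-sided
#' Wilcoxon signed-rank P over the paired vectors, dropping zero
#' differences. If every difference is zero the test is degenerate and is
#' reported as P = 1 with a warning. Comparability assumes the two peak
#' sets were called from equal-depth read sets upstream; this is
#' documented, not enforced.
#'
#' @param motifs motif track.
#' @param peaks_a,peaks_b peak tracks with `signif` (-log10 P).
#' @param window association window in bp.
#' @return list(mean_pA, mean_pB, wilcoxon_p, n_nonzero).
#' @export
paired_peak_significance_comparison <- function(motifs, peaks_a, peaks_b,
                                                window = 5000) {
  pa <- best_peak_p(motifs, peaks_a, window)
  pb <- best_peak_p(motifs, peaks_b, window)
  d <- pa - pb
  nz <- d[d != 0]
  if (!length(nz)) {
    warning("all paired differences are zero; signed-rank test degenerate, P = 1")
    wp <- 1
  } else {
    wp <- suppressWarnings(wilcox.test(nz, mu = 0)$p.value)
  }
  list(mean_pA = mean(pa), mean_pB = mean(pb),
       wilcoxon_p = wp, n_nonzero = length(nz))
}

best_peak_p <- function(motifs, peaks, window) {
  w2 <- window_threshold(window)
  vapply(seq_len(nrow(motifs)), function(i) {
    j <- which(peaks$chrom == motifs$chrom[i] &
               peaks$start - motifs$end[i] <= w2 &
               motifs$start[i] - peaks$end <= w2)
    if (!length(j)) 1 else 10^(-max(peaks$signif[j]))
  }, 0)
}
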