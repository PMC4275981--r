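#' Cumulative GC index of a genome
#'
#' For each chromosome, `cum[i+1]` is the number of G or C bases in the
#' first `i` bases, so the GC count of `[start, end)` is
#' `cum[end+1] - cum[start+1]` in O(1). N (and any other base) contributes
#' nothing.
#'
#' @param genome a [g4_genome()].
#' @return named list of integer vectors, class `g4_gc_index`.
#' @export
gc_index <- function(genome) {
  idx <- lapply(genome$seq, function(s) {
    r <- charToRaw(s)
    gc <- (r == charToRaw("G")[1L]) | (r == charToRaw("C")[1L])
    c(0L, cumsum(as.integer(gc)))
  })
  structure(idx, class = "g4_gc_index")
}

gc_from_index <- function(idx_chrom, start, end) {
  idx_chrom[end + 1L] - idx_chrom[start + 1L]
}

#' GC count of one or more intervals
#'
#' Counts G plus C bases on the spanned reference sequence; N contributes 0.
#' Because matched control regions have the same length as their motif,
#' matching the count is the same as matching the fraction, without float
#' tolerance questions.
#'
#' @param genome a [g4_genome()].
#' @param track a track data.frame (or anything with chrom/start/end).
#' @param idx optional pre-built [gc_index()].
#' @return integer vector of GC counts, one per interval.
#' @export
gc_count <- function(genome, track, idx = NULL) {
  if (nrow(track) == 0L) return(integer())
  check_track_in_genome(track, genome)
  if (is.null(idx)) idx <- gc_index(genome)
  vapply(seq_len(nrow(track)), function(i) {
    gc_from_index(idx[[track$chrom[i]]], track$start[i], track$end[i])
  }, 0L)
}

#' Sample one control region matched to a motif
#'
#' Draws uniform-random start positions on the motif's chromosome and
#' rejects until the candidate's GC count equals the motif's. If
#' `max_attempts` draws fail, the tolerance widens by 1 GC count at a time
#' (each widening is logged) until a region is found. With
#' `match_gc = FALSE` the first draw is returned. Uses the current RNG
#' state; seed outside (e.g. [build_control_sets()] derives one stream per
#' control set).
#'
#' @param genome a [g4_genome()].
#' @param chrom,length,gc chromosome, length (bp) and GC count to match.
#' @param idx pre-built [gc_index()].
#' @param max_attempts rejection draws before widening the tolerance.
#' @param match_gc match GC count (TRUE) or length/chromosome only.
#' @return list(start, tol): 0-based start and the GC tolerance used.
#' @export
sample_matched_region <- function(genome, chrom, length, gc, idx = NULL,
                                  max_attempts = 50000L, match_gc = TRUE) {
  res <- sample_matched_group(genome, chrom, length, gc, n = 1L, idx = idx,
                              max_attempts = max_attempts, match_gc = match_gc)
  list(start = res$start[1L], tol = res$tol[1L])
}

# Vectorised core: n regions for one (chrom, length, gc) combination.
sample_matched_group <- function(genome, chrom, length, gc, n, idx = NULL,
                                 max_attempts = 50000L, match_gc = TRUE) {
  L <- genome$lengths[[chrom]]
  if (is.null(L)) stop_g4("chromosome '%s' not in genome", chrom)
  if (L < length) {
    stop_g4("chromosome %s (length %d) shorter than region length %d",
            chrom, L, length)
  }
  n_pos <- L - length + 1L
  if (!match_gc) {
    return(list(start = sample.int(n_pos, n, replace = TRUE) - 1L,
                tol = rep(0L, n)))
  }
  if (is.null(idx)) idx <- gc_index(genome)
  cum <- idx[[chrom]]
  starts <- integer(0)
  tols <- integer(0)
  tol <- 0L
  attempts <- 0L
  batch <- as.integer(min(max(4L * n, 2000L), 50000L))
  while (length(starts) < n) {
    cand <- sample.int(n_pos, batch, replace = TRUE) - 1L
    ok <- abs(gc_from_index(cum, cand, cand + length) - gc) <= tol
    acc <- cand[ok]
    if (length(acc)) {
      take <- min(length(acc), n - length(starts))
      starts <- c(starts, acc[seq_len(take)])
      tols <- c(tols, rep(tol, take))
      attempts <- 0L
    } else {
      attempts <- attempts + batch
      if (attempts >= max_attempts) {
        tol <- tol + 1L
        g4_log("GC tolerance widened to +/-%d for %s length=%d gc=%d",
               tol, chrom, length, gc)
        attempts <- 0L
      }
    }
  }
  list(start = starts, tol = tols)
}

#' Build matched control sets for a motif track
#'
#' Generates `n_sets` collections of random regions, each matched 1:1 to
#' the motifs by chromosome, exact length and (by default) exact GC count,
#' the resampling null used by every enrichment test. Control regions may
#' overlap each other or real motifs; no exclusion is applied. Set `i` uses
#' a child RNG stream derived from `(seed, i)`, so the collection is
#' reproducible bit-for-bit and sets could be generated in any order.
#'
#' @param motifs motif track (non-empty).
#' @param genome a [g4_genome()].
#' @param n_sets number of control sets (default 1000).
#' @param seed master seed.
#' @param match_gc constrain GC count (default TRUE).
#' @param max_attempts rejection budget per region before the GC tolerance
#'   widens by 1 (logged).
#' @return object of class `g4_control_sets` with `starts` and `tol`
#'   (n_motifs x n_sets integer matrices), the motif frame, seed and flags.
#' @export
build_control_sets <- function(motifs, genome, n_sets = 1000L, seed = 1L,
                               match_gc = TRUE, max_attempts = 50000L) {
  if (nrow(motifs) == 0L) stop_g4("motif track is empty")
  check_track_in_genome(motifs, genome)
  idx <- gc_index(genome)
  len <- motifs$end - motifs$start
  gc <- gc_count(genome, motifs, idx)
  key <- paste(motifs$chrom, len, if (match_gc) gc else 0L)
  groups <- split(seq_len(nrow(motifs)), factor(key, levels = unique(key)))
  starts <- matrix(0L, nrow(motifs), n_sets)
  tol <- matrix(0L, nrow(motifs), n_sets)
  for (i in seq_len(n_sets)) {
    with_seed(child_seed(seed, i), {
      for (g in groups) {
        r <- sample_matched_group(genome, motifs$chrom[g[1L]], len[g[1L]],
                                  gc[g[1L]], n = length(g), idx = idx,
                                  max_attempts = max_attempts,
                                  match_gc = match_gc)
        starts[g, i] <- r$start
        tol[g, i] <- r$tol
      }
    })
  }
  structure(list(motifs = motifs[, c("chrom", "start", "end", "strand")],
                 lengths = len, gc = gc,
                 starts = starts, tol = tol,
                 n_sets = n_sets, seed = seed, match_gc = match_gc),
            class = "g4_control_sets")
}

#' Extract control set i as a track
#' @param controls a `g4_control_sets` object.
#' @param i set index in 1..n_sets.
#' @export
control_set <- function(controls, i) {
  stopifnot(i >= 1L, i <= controls$n_sets)
  data.frame(chrom = controls$motifs$chrom,
             start = controls$starts[, i],
             end = controls$starts[, i] + controls$lengths,
             strand = "*",
             stringsAsFactors = FALSE)
}

#' @export
print.g4_control_sets <- function(x, ...) {
  cat(sprintf(
    "g4_control_sets: %d sets x %d regions (seed %d, match_gc=%s); GC tolerance 0 for %.1f%% of regions\n",
    x$n_sets, nrow(x$motifs), x$seed, x$match_gc,
    100 * mean(x$tol == 0L)))
  invisible(x)
}

#' Write control sets as a TSV (set index column) plus a metadata JSON
#' @param controls a `g4_control_sets` object.
#' @param path output TSV path; metadata goes to `<path>.meta.json`.
#' @export
write_control_sets <- function(controls, path) {
  n <- nrow(controls$motifs)
  df <- data.frame(
    set = rep(seq_len(controls$n_sets), each = n),
    chrom = rep(controls$motifs$chrom, controls$n_sets),
    start = as.vector(controls$starts),
    end = as.vector(controls$starts) + rep(controls$lengths, controls$n_sets),
    gc_tolerance = as.vector(controls$tol))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(n_sets = controls$n_sets, seed = controls$seed,
               match_gc = controls$match_gc,
               max_tolerance = max(controls$tol),
               frac_exact = mean(controls$tol == 0L))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
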