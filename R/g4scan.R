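#' Scan parameters for G4 motif discovery
#'
#' The defaults encode the canonical intramolecular G4 query pattern
#' (G>=3 N1-25)3 G>=3: at least four G-islands of three or more consecutive
#' guanines separated by loops of 1-25 bases. Runs of G-islands longer than
#' four that satisfy the loop constraint are merged and counted as a single
#' motif (maximal chaining).
#'
#' @param min_g_run minimum G-island length (>= 2; default 3).
#' @param max_loop maximum loop length in bp (>= 1; default 25).
#' @param min_islands minimum number of G-islands per motif (>= 2; default 4).
#' @param strands strands to scan, subset of c("+", "-").
#' @return an object of class `g4_scan_params`.
#' @export
scan_params <- function(min_g_run = 3L, max_loop = 25L, min_islands = 4L,
                        strands = c("+", "-")) {
  min_g_run <- as.integer(min_g_run)
  max_loop <- as.integer(max_loop)
  min_islands <- as.integer(min_islands)
  if (min_g_run < 2L) stop_g4("min_g_run must be >= 2")
  if (max_loop < 1L) stop_g4("max_loop must be >= 1")
  if (min_islands < 2L) stop_g4("min_islands must be >= 2")
  if (!length(strands) || !all(strands %in% c("+", "-"))) {
    stop_g4("strands must be a non-empty subset of c('+', '-')")
  }
  structure(list(min_g_run = min_g_run, max_loop = max_loop,
                 min_islands = min_islands, strands = strands),
            class = "g4_scan_params")
}

#' Find maximal runs of a letter
#'
#' Returns every maximal run of `letter` of length at least `min_len`,
#' in order of position. Because the runs are maximal, two reported runs
#' are always separated by at least one other base.
#'
#' @param seq a sequence string over \{A,C,G,T,N\}.
#' @param min_len minimum run length.
#' @param letter the run letter (default "G").
#' @return data.frame with 0-based `start` and `length` columns.
#' @export
find_g_runs <- function(seq, min_len = 3L, letter = "G") {
  m <- gregexpr(sprintf("%s{%d,}", letter, as.integer(min_len)), seq)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(), length = integer()))
  }
  data.frame(start = as.integer(m) - 1L,
             length = attr(m, "match.length"))
}

# Chain runs whose successive gaps are within [1, max_loop]; each maximal
# chain with >= min_islands runs becomes one motif. A gap > max_loop splits
# the chain and each side qualifies (or not) on its own.
chain_runs <- function(runs, params) {
  n <- nrow(runs)
  if (n == 0L) return(list())
  ends <- runs$start + runs$length
  gaps <- if (n > 1L) runs$start[-1L] - ends[-n] else integer()
  grp <- cumsum(c(1L, as.integer(gaps > params$max_loop)))
  out <- list()
  for (g in split(seq_len(n), factor(grp, levels = unique(grp)))) {
    if (length(g) < params$min_islands) next
    idx <- g
    loop_lengths <- if (length(idx) > 1L) {
      runs$start[idx[-1L]] - ends[idx[-length(idx)]]
    } else integer()
    out[[length(out) + 1L]] <- list(
      start = runs$start[idx[1L]],
      end = ends[idx[length(idx)]],
      island_starts = runs$start[idx],
      island_lengths = runs$length[idx],
      loop_lengths = loop_lengths)
  }
  out
}

motif_rows <- function(chains, chrom, strand, seq = NULL) {
  if (!length(chains)) return(empty_motif_track())
  df <- data.frame(
    chrom = chrom,
    start = vapply(chains, `[[`, 0L, "start"),
    end = vapply(chains, `[[`, 0L, "end"),
    strand = strand,
    n_islands = vapply(chains, function(x) length(x$island_starts), 0L),
    island_starts = vapply(chains, function(x) paste(x$island_starts, collapse = ","), ""),
    island_lengths = vapply(chains, function(x) paste(x$island_lengths, collapse = ","), ""),
    loop_lengths = vapply(chains, function(x) paste(x$loop_lengths, collapse = ","), ""),
    stringsAsFactors = FALSE)
  df$sequence <- if (is.null(seq)) NA_character_ else
    substring(seq, df$start + 1L, df$end)
  df
}

empty_motif_track <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), n_islands = integer(),
             island_starts = character(), island_lengths = character(),
             loop_lengths = character(), sequence = character(),
             stringsAsFactors = FALSE)
}

#' Scan the plus strand of a single sequence for G4 motifs
#'
#' @param seq sequence string.
#' @param params a [scan_params()] object.
#' @param chrom chromosome label for the output track.
#' @return motif track data.frame (strand "+") with island/loop detail;
#'   island starts are 0-based offsets on the given sequence.
#' @export
scan_plus_strand <- function(seq, params = scan_params(), chrom = "seq") {
  runs <- find_g_runs(seq, params$min_g_run, "G")
  motif_rows(chain_runs(runs, params), chrom, "+", seq)
}

#' Scan a genome for G4 motifs on both strands
#'
#' Plus-strand motifs are chains of G-runs; minus-strand motifs are chains
#' of C-runs on the reference, reported in reference coordinates with
#' strand "-" (equivalent to scanning the reverse complement). N never
#' counts as G or C, so N bases can sit in loops but never in islands.
#' Motifs on the same strand never overlap; a cross-strand overlap is two
#' distinct motifs because intramolecular G4 formation is strand-specific.
#'
#' @param genome a [g4_genome()].
#' @param params a [scan_params()] object.
#' @return motif track data.frame sorted by (chrom, start), with a `name`
#'   column encoding the island/loop signature and `score` = n_islands.
#' @export
scan_genome <- function(genome, params = scan_params()) {
  pieces <- list()
  for (ch in names(genome$seq)) {
    s <- genome$seq[[ch]]
    if ("+" %in% params$strands) {
      runs <- find_g_runs(s, params$min_g_run, "G")
      pieces[[length(pieces) + 1L]] <- motif_rows(chain_runs(runs, params), ch, "+", s)
    }
    if ("-" %in% params$strands) {
      runs <- find_g_runs(s, params$min_g_run, "C")
      pieces[[length(pieces) + 1L]] <- motif_rows(chain_runs(runs, params), ch, "-", s)
    }
  }
  out <- do.call(rbind, c(pieces, list(empty_motif_track())))
  ord <- order(match(out$chrom, names(genome$seq)), out$start, out$strand)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) {
    out$name <- sprintf("G4|%dI|%s/%s", out$n_islands,
                        out$island_lengths, out$loop_lengths)
    out$score <- out$n_islands
  } else {
    out$name <- character()
    out$score <- integer()
  }
  out
}

#' Motif density per bp and per kb
#'
#' @param n_motifs motif count.
#' @param total_bp genome (or region set) size in bp; must be > 0.
#' @return list with `per_bp` and `per_kb`.
#' @export
motif_density <- function(n_motifs, total_bp) {
  if (total_bp <= 0) stop_g4("total_bp must be > 0")
  list(per_bp = n_motifs / total_bp, per_kb = 1000 * n_motifs / total_bp)
}

#' Count motifs strictly overlapping a region
#'
#' @param motifs motif track.
#' @param chrom,start,end region (0-based half-open).
#' @return integer count.
#' @export
count_in_region <- function(motifs, chrom, start, end) {
  sum(motifs$chrom == chrom & motifs$start < end & start < motifs$end)
}
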