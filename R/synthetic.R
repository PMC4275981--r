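#' Random genome of a given GC composition
#'
#' Bases are i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) = (1-gc)/2,
#' the simplest null sequence model for "random sequence of the same GC
#' content" statements. Deterministic for a given seed.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param gc target G+C fraction in (0, 1); 0.36 matches a fission-yeast
#'   nuclear genome.
#' @param seed integer seed.
#' @return a [g4_genome()].
#' @export
random_genome <- function(chrom_lengths = c(sim_I = 500000L), gc = 0.36,
                          seed = 1L) {
  if (gc < 0 || gc >= 1) stop_g4("gc must lie in [0, 1)")
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("sim_", seq_along(chrom_lengths))
  }
  p <- c(G = gc / 2, C = gc / 2, A = (1 - gc) / 2, T = (1 - gc) / 2)
  seqs <- with_seed(seed, {
    vapply(chrom_lengths, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, "")
  })
  g4_genome(seqs)
}

default_template <- function() "GGGTGGGTGGGTGGG"

#' Plant G4 motifs into a genome with a known truth set
#'
#' Writes copies of `template` (its reverse complement for "-" strand
#' plants) at uniformly drawn positions. Fixed 1-bp loops in the default
#' template make detection unambiguous. A candidate site is accepted only
#' if, after writing, a local scan reports a motif with exactly the
#' planted interval and strand — sites whose flanking context would extend
#' or break the chain are redrawn — and planted sites keep a clearance of
#' `max_loop + 1` bp from each other so two plants can never merge.
#' Background motifs already present elsewhere remain and are reported by
#' comparing to a pre-plant scan.
#'
#' @param genome a [g4_genome()].
#' @param n number of motifs to plant.
#' @param template plus-strand motif sequence.
#' @param prob_minus probability a plant goes on the minus strand.
#' @param params [scan_params()] used for the local verification scan.
#' @param seed integer seed.
#' @param max_tries total placement attempts before giving up.
#' @param min_spacing minimum bp between planted motifs; defaults to
#'   `max_loop + 1` (just enough that two plants can never chain). Raise it
#'   when a fixture needs each downstream peak or feature to touch exactly
#'   one motif.
#' @return list(genome, truth, background): the edited genome, the truth
#'   track (chrom/start/end/strand) sorted by position, and the pre-plant
#'   background motif track.
#' @export
plant_motifs <- function(genome, n, template = default_template(),
                         prob_minus = 0.5, params = scan_params(),
                         seed = 1L, max_tries = 500L * n,
                         min_spacing = NULL) {
  len <- nchar(template)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(template)))
  background <- scan_genome(genome, params)
  clearance <- max(params$max_loop + 1L, min_spacing %||% 0L)
  chroms <- names(genome$seq)
  chrom_p <- genome$lengths / sum(genome$lengths)
  placed <- data.frame(chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       stringsAsFactors = FALSE)
  seqs <- genome$seq
  ctx <- params$max_loop + params$min_g_run + 5L
  with_seed(seed, {
    tries <- 0L
    while (nrow(placed) < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop_g4("could not place %d motifs in %d tries; genome too crowded",
                n, max_tries)
      }
      ch <- sample(chroms, 1L, prob = chrom_p)
      L <- genome$lengths[[ch]]
      if (L < len + 2L * ctx) next
      start <- sample.int(L - len - 2L * ctx, 1L) + ctx
      same <- placed[placed$chrom == ch, , drop = FALSE]
      if (nrow(same) && any(start - clearance < same$end &
                            same$start - clearance < start + len)) next
      strand <- if (runif(1L) < prob_minus) "-" else "+"
      ins <- if (strand == "+") template else rc
      lo <- max(0L, start - ctx)
      hi <- min(L, start + len + ctx)
      local <- substring(seqs[[ch]], lo + 1L, hi)
      substr(local, start - lo + 1L, start - lo + len) <- ins
      found <- scan_genome(g4_genome(setNames(local, ch)), params)
      ok <- any(found$start == start - lo & found$end == start + len - lo &
                found$strand == strand)
      if (!ok) next
      substr(seqs[[ch]], start + 1L, start + len) <- ins
      placed[nrow(placed) + 1L, ] <- list(ch, start, start + len, strand)
    }
  })
  placed <- placed[order(match(placed$chrom, chroms), placed$start), , drop = FALSE]
  rownames(placed) <- NULL
  list(genome = g4_genome(seqs), truth = placed, background = background)
}

#' Simulate annotation tracks with controlled motif co-location
#'
#' For each feature class, `n` intervals of the given length are placed: a
#' fraction `colocate` on top of distinct randomly chosen truth motifs
#' (uniformly offset so feature and motif strictly overlap), the remainder
#' uniformly on the genome. Stranded classes draw strands 50/50 unless the
#' class requests the motif's template strand; gene-like classes draw a
#' log-normal `expression` attribute.
#'
#' @param genome a [g4_genome()].
#' @param truth planted-motif truth track (may be empty for pure
#'   background classes).
#' @param classes list of class specs: `list(name=, n=, length=,
#'   stranded=FALSE, colocate=0, expression=FALSE,
#'   template_strand=FALSE)`.
#' @param seed integer seed.
#' @return named list of track data.frames.
#' @export
synth_features <- function(genome, truth, classes, seed = 1L) {
  chroms <- names(genome$seq)
  chrom_p <- genome$lengths / sum(genome$lengths)
  out <- list()
  with_seed(seed, {
    for (cl in classes) {
      n <- cl$n
      flen <- cl$length
      n_co <- round((cl$colocate %||% 0) * n)
      if (n_co > nrow(truth)) stop_g4("class '%s': co-location needs %d motifs, truth has %d",
                                      cl$name, n_co, nrow(truth))
      rows <- list()
      if (n_co > 0L) {
        pick <- sample.int(nrow(truth), n_co)
        for (k in pick) {
          mlen <- truth$end[k] - truth$start[k]
          # any start in (motif_start - flen, motif_end) overlaps the motif
          off <- sample.int(flen + mlen - 1L, 1L) - flen
          st <- max(0L, min(truth$start[k] + off,
                            genome$lengths[[truth$chrom[k]]] - flen))
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = truth$chrom[k], start = st, end = st + flen,
            motif_strand = truth$strand[k], stringsAsFactors = FALSE)
        }
      }
      n_bg <- n - n_co
      if (n_bg > 0L) {
        ch <- sample(chroms, n_bg, replace = TRUE, prob = chrom_p)
        st <- vapply(ch, function(c2) {
          sample.int(max(genome$lengths[[c2]] - flen, 1L), 1L) - 1L
        }, 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = st, end = st + flen,
          motif_strand = NA_character_, stringsAsFactors = FALSE)
      }
      tr <- do.call(rbind, rows)
      tr$strand <- "*"
      if (isTRUE(cl$stranded)) {
        tr$strand <- sample(c("+", "-"), nrow(tr), replace = TRUE)
        if (isTRUE(cl$template_strand)) {
          # put each co-located gene on the strand that makes the motif
          # fall on its transcribed (template) strand: gene strand must
          # differ from motif strand
          co <- !is.na(tr$motif_strand)
          tr$strand[co] <- ifelse(tr$motif_strand[co] == "+", "-", "+")
        }
      }
      tr$motif_strand <- NULL
      tr$name <- sprintf("%s_%03d", cl$name, seq_len(nrow(tr)))
      if (isTRUE(cl$expression)) tr$expression <- rlnorm(nrow(tr), 3, 1.5)
      tr <- tr[order(match(tr$chrom, chroms), tr$start), , drop = FALSE]
      rownames(tr) <- NULL
      out[[cl$name]] <- validate_track(tr)
    }
  })
  out
}

#' Simulate a ChIP-seq peak set around a motif subset
#'
#' A chosen fraction (or explicit id set) of the truth motifs receives a
#' signal peak: length drawn from a truncated normal emulating caller
#' output (mean 1838 bp, sd 983 bp, floor 200 bp — typical MACS peak
#' geometry at 300 bp shearing), positioned to strictly overlap the motif.
#' Background peaks are placed uniformly at `background_per_mb` with lower
#' significance on average. Significances are -log10 P, floored at the
#' caller cutoff (5, i.e. P = 1E-5).
#'
#' @param genome a [g4_genome()].
#' @param truth planted-motif truth track.
#' @param frac_peaked fraction of motifs receiving a signal peak (ignored
#'   when `peaked_ids` is given).
#' @param peaked_ids optional explicit motif row indices to peak.
#' @param background_per_mb background peak rate per Mb (0 for noise-free).
#' @param mean_len,sd_len,min_len peak length distribution (bp).
#' @param signal_signif,background_signif mean added -log10 P
#'   (exponential) above the cutoff for signal and background peaks.
#' @param factor,condition labels for [peak_set()].
#' @param seed integer seed.
#' @return a [peak_set()] with attribute `"peaked_ids"` (the truth rows
#'   that received a signal peak).
#' @export
synth_peaks <- function(genome, truth, frac_peaked = 0.2, peaked_ids = NULL,
                        background_per_mb = 2, mean_len = 1838, sd_len = 983,
                        min_len = 200, signal_signif = 20,
                        background_signif = 3, factor = "factor",
                        condition = "condition", seed = 1L) {
  chroms <- names(genome$seq)
  chrom_p <- genome$lengths / sum(genome$lengths)
  with_seed(seed, {
    if (is.null(peaked_ids)) {
      k <- round(frac_peaked * nrow(truth))
      peaked_ids <- if (k > 0L) sort(sample.int(nrow(truth), k)) else integer()
    }
    rows <- list()
    for (i in peaked_ids) {
      plen <- max(min_len, round(rnorm(1L, mean_len, sd_len)))
      mlen <- truth$end[i] - truth$start[i]
      off <- sample.int(plen + mlen - 1L, 1L) - plen
      st <- max(0L, min(truth$start[i] + off,
                        genome$lengths[[truth$chrom[i]]] - plen))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = truth$chrom[i], start = st, end = st + plen,
        signif = 5 + rexp(1L, 1 / signal_signif), stringsAsFactors = FALSE)
    }
    n_bg <- rpois(1L, background_per_mb * sum(genome$lengths) / 1e6)
    if (n_bg > 0L) {
      ch <- sample(chroms, n_bg, replace = TRUE, prob = chrom_p)
      plen <- pmax(min_len, round(rnorm(n_bg, mean_len, sd_len)))
      st <- vapply(seq_len(n_bg), function(j) {
        sample.int(max(genome$lengths[[ch[j]]] - plen[j], 1L), 1L) - 1L
      }, 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = st, end = st + plen,
        signif = 5 + rexp(n_bg, 1 / background_signif),
        stringsAsFactors = FALSE)
    }
    tr <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 signif = numeric(), stringsAsFactors = FALSE)
    tr$strand <- rep_len("*", nrow(tr))
    tr$name <- sprintf("%s_%s_peak_%03d", factor, condition,
                       seq_len(nrow(tr)))
    tr <- tr[order(match(tr$chrom, chroms), tr$start), , drop = FALSE]
    rownames(tr) <- NULL
    ps <- peak_set(tr, factor, condition)
    attr(ps, "peaked_ids") <- peaked_ids
    ps
  })
}

#' Expected motif density in random sequence, by simulation
#'
#' Scans replicate random chromosomes of the requested composition and
#' returns the both-strand motif density with its Monte-Carlo standard
#' error across replicates.
#'
#' @param gc G+C fraction.
#' @param total_bp total simulated bp (>= 1e6 recommended for a stable
#'   estimate).
#' @param params [scan_params()].
#' @param seed integer seed.
#' @param n_chunks replicate chromosomes to split the total into.
#' @return list(per_kb, se_per_kb, n_motifs, total_bp).
#' @export
expected_density_by_simulation <- function(gc, total_bp, params = scan_params(),
                                           seed = 1L, n_chunks = 10L) {
  chunk <- as.integer(ceiling(total_bp / n_chunks))
  dens <- vapply(seq_len(n_chunks), function(i) {
    g <- random_genome(c(chunk = chunk), gc, seed = child_seed(seed, i))
    1000 * nrow(scan_genome(g, params)) / chunk
  }, 0)
  list(per_kb = mean(dens),
       se_per_kb = stats::sd(dens) / sqrt(n_chunks),
       n_motifs = round(mean(dens) * total_bp / 1000),
       total_bp = n_chunks * chunk)
}

#' Write a narrowPeak file from a peak track
#' @param peaks track with `signif` column.
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- data.frame(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = if ("name" %in% names(peaks)) peaks$name else ".",
    score = 0L,
    strand = ifelse(peaks$strand == "*", ".", peaks$strand),
    signalValue = if ("signal" %in% names(peaks)) peaks$signal else peaks$signif,
    pValue = peaks$signif, qValue = -1, peak = -1L)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
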