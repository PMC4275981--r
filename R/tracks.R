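#' Interval tracks
#'
#' An annotation track is a plain data.frame with at least the columns
#' `chrom` (character), `start` and `end` (integers, 0-based half-open) and
#' `strand` (one of "+", "-", "*"). Extra columns (`name`, `score`,
#' `signif`, `expression`, ...) ride along. A `g4_track()` call validates
#' and normalises the frame.
#'
#' @param chrom,start,end,strand interval columns (recycled as usual).
#' @param ... further per-interval columns.
#' @return a validated track data.frame.
#' @export
g4_track <- function(chrom = character(), start = integer(), end = integer(),
                     strand = "*", ...) {
  n <- length(start)
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.integer(start),
                   end = rep_len(as.integer(end), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  dots <- list(...)
  for (nm in names(dots)) df[[nm]] <- rep_len(dots[[nm]], n)
  validate_track(df)
}

validate_track <- function(df, genome = NULL) {
  need <- c("chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_g4("track is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(df)) {
    bad <- which(!(df$start >= 0L & df$end > df$start))
    if (length(bad)) {
      stop_g4("invalid interval(s) (end <= start or negative start) at record(s): %s",
              paste(head(bad, 5L), collapse = ", "))
    }
    if (any(!df$strand %in% c("+", "-", "*"))) stop_g4("strand must be +, - or *")
  }
  if (!is.null(genome)) check_track_in_genome(df, genome)
  df
}

# Chromosome-name mismatches between sequence and tracks are hard errors:
# a silent misjoin would corrupt every downstream count.
check_track_in_genome <- function(track, genome) {
  unknown <- setdiff(unique(track$chrom), names(genome$seq))
  if (length(unknown)) {
    stop_g4("track chromosome(s) not in genome: %s", paste(unknown, collapse = ", "))
  }
  over <- track$end > genome$lengths[track$chrom]
  if (any(over)) {
    stop_g4("interval(s) extend past chromosome end at record(s): %s",
            paste(head(which(over), 5L), collapse = ", "))
  }
  invisible(TRUE)
}

narrowpeak_cols <- c(signalValue = "numeric", pValue = "numeric",
                     qValue = "numeric", peak = "integer")

#' Read an interval file (BED, GFF3 or narrowPeak)
#'
#' BED starts are used as-is (already 0-based half-open); GFF3 coordinates
#' (1-based inclusive) are shifted to the internal convention by
#' subtracting 1 from the start; narrowPeak column 8 (the caller's
#' -log10 P) is stored in a `signif` column.
#'
#' @param path input file.
#' @param format one of "BED", "GFF3", "narrowPeak".
#' @return a track data.frame; narrowPeak input additionally carries
#'   `signif` and `signal` columns.
#' @export
read_intervals <- function(path, format = c("BED", "GFF3", "narrowPeak")) {
  format <- match.arg(format)
  gr <- switch(format,
    BED = rtracklayer::import(path, format = "BED"),
    GFF3 = rtracklayer::import(path, format = "GFF3"),
    narrowPeak = rtracklayer::import(path, format = "BED",
                                     extraCols = narrowpeak_cols))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  mc <- as.data.frame(GenomicRanges::mcols(gr))
  if (format == "narrowPeak") {
    if (!all(is.finite(mc$pValue)) || any(mc$pValue < 0)) {
      stop_g4("narrowPeak -log10 P values must be finite and non-negative")
    }
    df$name <- as.character(mc$name %||% ".")
    df$signif <- mc$pValue
    df$signal <- mc$signalValue
  } else if (format == "GFF3") {
    df$name <- as.character(mc$ID %||% mc$Name %||% rep(NA_character_, nrow(df)))
    df$type <- as.character(mc$type %||% rep(NA_character_, nrow(df)))
    for (extra in c("expression", "essential")) {
      if (extra %in% names(mc)) df[[extra]] <- utils::type.convert(as.character(mc[[extra]]), as.is = TRUE)
    }
  } else {
    if ("name" %in% names(mc)) df$name <- as.character(mc$name)
    if ("score" %in% names(mc)) df$score <- mc$score
  }
  validate_track(df)
}

#' Write a track as BED6 or TSV
#'
#' BED6 writes chrom/start/end/name/score/strand (missing name -> ".",
#' missing score -> 0, strand "*" -> "."); `read_intervals(..., "BED")` on
#' the result round-trips the interval columns. TSV writes every column
#' with a header.
#'
#' @param track a track data.frame.
#' @param path output path.
#' @param format "BED6" or "TSV".
#' @export
write_intervals <- function(track, path, format = c("BED6", "TSV")) {
  format <- match.arg(format)
  track <- validate_track(track)
  if (format == "TSV") {
    write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  out <- data.frame(
    chrom = track$chrom,
    start = track$start,
    end = track$end,
    name = if ("name" %in% names(track)) ifelse(is.na(track$name), ".", track$name) else ".",
    score = if ("score" %in% names(track)) ifelse(is.na(track$score), 0, track$score) else 0,
    strand = ifelse(track$strand == "*", ".", track$strand))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- low-level interval machinery (0-based half-open throughout) ---------

# Association rule: window = 0 means strict overlap; window > 0 additionally
# admits pairs separated by a gap (bases strictly between) of at most
# `window` bp. Encoded as a single threshold: a pair is associated iff
#   start_a - end_b <= w2  AND  start_b - end_a <= w2
# with w2 = -1 for window 0 (strict) and w2 = window otherwise.
window_threshold <- function(window) {
  if (length(window) != 1L || is.na(window) || window < 0) {
    stop_g4("window must be a single non-negative number")
  }
  if (window == 0) -1L else as.integer(window)
}

# Pre-merge subject intervals (expanded by the association threshold) per
# chromosome so any-hit queries are a binary search.
prepare_subjects <- function(subject, window) {
  w2 <- window_threshold(window)
  out <- list()
  for (ch in unique(subject$chrom)) {
    s <- subject[subject$chrom == ch, , drop = FALSE]
    st <- pmax(s$start - w2 - 1L, -1L)
    en <- s$end + w2 + 1L
    o <- order(st, en)
    st <- st[o]; en <- en[o]
    # merge overlapping/abutting expanded intervals
    keep_start <- st
    keep_end <- cummax(en)
    new_block <- c(TRUE, st[-1L] > keep_end[-length(keep_end)])
    grp <- cumsum(new_block)
    out[[ch]] <- list(start = tapply(st, grp, min),
                      end = tapply(en, grp, max))
  }
  out
}

# logical: does query row i hit any (prepared, merged) subject interval?
hits_any <- function(prep, chrom, start, end) {
  res <- logical(length(start))
  for (ch in unique(chrom)) {
    p <- prep[[ch]]
    idx <- which(chrom == ch)
    if (is.null(p)) next
    qs <- start[idx]; qe <- end[idx]
    n_s <- length(p$start)
    j <- findInterval(qs, p$start)
    in_left <- j >= 1L & qs < p$end[pmax(j, 1L)]
    j2 <- pmin(j + 1L, n_s)
    in_right <- j < n_s & p$start[j2] < qe
    res[idx] <- in_left | in_right
  }
  res
}
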