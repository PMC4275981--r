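#' Pairwise alignment block set
#'
#' Blocks map intervals of a source genome onto a target genome. Each
#' block carries optional gapped alignment rows (`src_aln`, `tgt_aln`,
#' equal-length strings with "-" gaps); without them the block is treated
#' as ungapped and colinear (equal widths required). Source intervals must
#' not overlap; all coordinates are 0-based half-open on the forward
#' strand of each genome.
#'
#' @param blocks data.frame with columns `src_chrom`, `src_start`,
#'   `src_end`, `tgt_chrom`, `tgt_start`, `tgt_end` and optionally
#'   `src_aln`, `tgt_aln`.
#' @param species character(2): source and target labels.
#' @return object of class `g4_alignment`.
#' @export
alignment_blocks <- function(blocks, species = c("A", "B")) {
  need <- c("src_chrom", "src_start", "src_end", "tgt_chrom", "tgt_start", "tgt_end")
  miss <- setdiff(need, names(blocks))
  if (length(miss)) stop_g4("blocks missing column(s): %s", paste(miss, collapse = ", "))
  if (!"src_aln" %in% names(blocks)) blocks$src_aln <- NA_character_
  if (!"tgt_aln" %in% names(blocks)) blocks$tgt_aln <- NA_character_
  for (i in seq_len(nrow(blocks))) {
    sw <- blocks$src_end[i] - blocks$src_start[i]
    tw <- blocks$tgt_end[i] - blocks$tgt_start[i]
    if (sw <= 0 || tw <= 0) stop_g4("block %d has non-positive width", i)
    if (is.na(blocks$src_aln[i])) {
      if (sw != tw) stop_g4("ungapped block %d must have equal source/target widths", i)
    } else {
      sa <- blocks$src_aln[i]; ta <- blocks$tgt_aln[i]
      if (nchar(sa) != nchar(ta)) stop_g4("block %d alignment rows differ in length", i)
      if (nchar(gsub("-", "", sa)) != sw) stop_g4("block %d source row inconsistent with width", i)
      if (nchar(gsub("-", "", ta)) != tw) stop_g4("block %d target row inconsistent with width", i)
    }
  }
  # source intervals must not overlap within a chromosome
  for (ch in unique(blocks$src_chrom)) {
    b <- blocks[blocks$src_chrom == ch, , drop = FALSE]
    b <- b[order(b$src_start), , drop = FALSE]
    if (nrow(b) > 1L && any(b$src_start[-1L] < b$src_end[-nrow(b)])) {
      stop_g4("overlapping source blocks on %s", ch)
    }
  }
  structure(list(blocks = blocks, species = species), class = "g4_alignment")
}

#' Read pairwise alignment blocks from a MAF file
#'
#' Supports the pairwise subset of MAF: each "a" paragraph must contain
#' exactly two "s" lines, source first. A "-" strand row is converted to
#' forward-strand coordinates using the MAF source-size field; its aligned
#' text is kept in strand orientation and the coordinate map runs
#' backwards accordingly.
#'
#' @param path MAF file.
#' @param species labels for the two genomes (defaults taken from the
#'   first block's sequence names).
#' @return a [alignment_blocks()] object.
#' @export
read_maf_pairwise <- function(path, species = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  s_idx <- grep("^s\\s", lines)
  a_idx <- grep("^a", lines)
  if (!length(a_idx)) stop_g4("no alignment blocks in %s", path)
  parse_s <- function(line) {
    f <- strsplit(trimws(line), "\\s+")[[1L]]
    list(src = f[2L], start = as.integer(f[3L]), size = as.integer(f[4L]),
         strand = f[5L], src_size = as.integer(f[6L]), text = f[7L])
  }
  rows <- list()
  for (a in a_idx) {
    nxt <- c(a_idx[a_idx > a], length(lines) + 1L)[1L]
    ss <- s_idx[s_idx > a & s_idx < nxt]
    if (length(ss) != 2L) stop_g4("MAF block at line %d is not pairwise", a)
    src <- parse_s(lines[ss[1L]])
    tgt <- parse_s(lines[ss[2L]])
    if (src$strand != "+") stop_g4("source rows must be forward strand")
    tgt_fwd_start <- if (tgt$strand == "+") tgt$start else tgt$src_size - tgt$start - tgt$size
    rows[[length(rows) + 1L]] <- data.frame(
      src_chrom = src$src, src_start = src$start, src_end = src$start + src$size,
      tgt_chrom = tgt$src, tgt_start = tgt_fwd_start,
      tgt_end = tgt_fwd_start + tgt$size,
      tgt_strand = tgt$strand,
      src_aln = src$text, tgt_aln = tgt$text,
      stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, rows)
  if (is.null(species)) species <- c(blocks$src_chrom[1L], blocks$tgt_chrom[1L])
  alignment_blocks(blocks, species)
}

#' Read ungapped alignment blocks from a TSV
#'
#' Fixture-friendly simplified format: a header line and the six block
#' columns of [alignment_blocks()].
#' @param path TSV file.
#' @param species genome labels.
#' @export
read_alignment_tsv <- function(path, species = c("A", "B")) {
  alignment_blocks(read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE), species)
}

# Per-block position map: source offsets (0-based, within genome) of
# aligned columns where BOTH rows are non-gap, and the matching target
# offsets. Handles "-" strand targets by counting from the block end.
block_map <- function(block) {
  if (is.na(block$src_aln)) {
    n <- block$src_end - block$src_start
    return(list(src = block$src_start + seq_len(n) - 1L,
                tgt = block$tgt_start + seq_len(n) - 1L))
  }
  sa <- strsplit(block$src_aln, "")[[1L]]
  ta <- strsplit(block$tgt_aln, "")[[1L]]
  s_off <- cumsum(sa != "-")
  t_off <- cumsum(ta != "-")
  both <- sa != "-" & ta != "-"
  src_pos <- block$src_start + s_off[both] - 1L
  strand <- block$tgt_strand %||% "+"
  if (is.na(strand)) strand <- "+"
  tgt_pos <- if (strand == "-") {
    block$tgt_end - t_off[both]
  } else {
    block$tgt_start + t_off[both] - 1L
  }
  list(src = src_pos, tgt = tgt_pos)
}

#' Map a source interval through alignment blocks
#'
#' Returns the target-genome intervals covered by the alignment of the
#' input (possibly split across blocks or by gaps); an empty track if the
#' interval is unaligned.
#'
#' @param aln a [alignment_blocks()] object.
#' @param chrom,start,end source interval, 0-based half-open.
#' @return track data.frame of target intervals.
#' @export
map_interval <- function(aln, chrom, start, end) {
  b <- aln$blocks
  hit <- which(b$src_chrom == chrom & b$src_start < end & start < b$src_end)
  out <- list()
  for (i in hit) {
    m <- block_map(b[i, ])
    keep <- m$src >= start & m$src < end
    tp <- sort(m$tgt[keep])
    if (!length(tp)) next
    brk <- c(TRUE, diff(tp) != 1L)
    grp <- cumsum(brk)
    st <- tapply(tp, grp, min)
    en <- tapply(tp, grp, max) + 1L
    out[[length(out) + 1L]] <- data.frame(
      chrom = b$tgt_chrom[i], start = as.integer(st), end = as.integer(en),
      strand = "*", stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-species conservation of motifs
#'
#' A motif of the source species is conserved iff the aligned portion of
#' the target genome (its [map_interval()] image) strictly overlaps any
#' motif of the target species. One-directional by definition; overlap of
#' the mapped region suffices, sequence identity is not required.
#'
#' @param motifs_a source-species motif track.
#' @param motifs_b target-species motif track.
#' @param aln alignment blocks from A to B.
#' @return list(count, conserved): total and per-motif logical.
#' @export
conserved_motifs <- function(motifs_a, motifs_b, aln) {
  prep <- prepare_subjects(motifs_b, window = 0)
  conserved <- vapply(seq_len(nrow(motifs_a)), function(i) {
    img <- map_interval(aln, motifs_a$chrom[i], motifs_a$start[i], motifs_a$end[i])
    nrow(img) > 0L && any(hits_any(prep, img$chrom, img$start, img$end))
  }, NA)
  list(count = sum(conserved), conserved = conserved)
}

#' Fraction of a genome covered by alignment blocks
#'
#' @param aln a [alignment_blocks()] object.
#' @param genome_size source genome size in bp.
#' @return total aligned source bp / genome_size.
#' @export
aligned_fraction <- function(aln, genome_size) {
  if (genome_size <= 0) stop_g4("genome_size must be > 0")
  sum(aln$blocks$src_end - aln$blocks$src_start) / genome_size
}
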