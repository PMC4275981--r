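#!/usr/bin/env Rscript

# Stage 5: cross-species conservation on a simulated species pair. A
# "sister" genome is built by copying aligned segments of the simulated
# genome (with fresh random sequence elsewhere), so a known subset of
# motifs falls inside aligned blocks. Motifs are scanned in both genomes,
# source motifs are mapped through the blocks, and the conserved fraction
# is summarised alongside the aligned genome fraction.

suppressMessages(library(g4screen))

out <- "results/conservation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260925L

genome <- read_genome_fasta("results/sim/genome.fa")
motifs <- read_intervals("results/scan/motifs.bed", "BED")

# aligned blocks: alternate 150 kb aligned / 100 kb unaligned segments of
# chromosome sim_I, mapped colinearly into the sister genome
src_len <- genome$lengths[["sim_I"]]
starts <- seq(0L, src_len - 150000L, by = 250000L)
blocks <- data.frame(src_chrom = "sim_I",
                     src_start = starts, src_end = starts + 150000L,
                     tgt_chrom = "sister_I",
                     tgt_start = seq(0L, by = 150000L, length.out = length(starts)))
blocks$tgt_end <- blocks$tgt_start + 150000L
aln <- alignment_blocks(blocks, species = c("sim", "sister"))

# sister genome: aligned segments copied, so motifs there are shared
sister_len <- max(blocks$tgt_end)
sister <- random_genome(c(sister_I = sister_len), 0.36, seed = seed + 31)
s <- sister$seq[["sister_I"]]
for (i in seq_len(nrow(blocks))) {
  substr(s, blocks$tgt_start[i] + 1L, blocks$tgt_end[i]) <-
    substring(genome$seq[["sim_I"]], blocks$src_start[i] + 1L, blocks$src_end[i])
}
sister <- g4_genome(c(sister_I = s))
sister_motifs <- scan_genome(sister)

cons <- conserved_motifs(motifs, sister_motifs, aln)
in_aligned <- vapply(seq_len(nrow(motifs)), function(i) {
  nrow(map_interval(aln, motifs$chrom[i], motifs$start[i], motifs$end[i])) > 0
}, NA)
frac_aln <- aligned_fraction(aln, genome_size(genome))
message(sprintf("aligned fraction of source genome: %.3f", frac_aln))
message(sprintf("motifs inside aligned blocks: %d; conserved: %d",
                sum(in_aligned), cons$count))
# every fully-copied aligned motif must be conserved
stopifnot(cons$count >= sum(motifs$start >= 0 & in_aligned &
                            vapply(seq_len(nrow(motifs)), function(i) {
                              any(blocks$src_start <= motifs$start[i] &
                                  motifs$end[i] <= blocks$src_end)
                            }, NA)) - 0L)

write.table(data.frame(
  species_pair = "sim->sister",
  n_motifs = nrow(motifs),
  n_in_aligned = sum(in_aligned),
  n_conserved = cons$count,
  aligned_fraction = frac_aln),
  file.path(out, "conservation_summary.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
mo <- motifs
mo$conserved <- cons$conserved
write_intervals(mo, file.path(out, "motifs_conservation.tsv"), "TSV")
write_manifest(file.path(out, "manifest.json"), g4_config(),
               inputs = c("results/sim/genome.fa", "results/scan/motifs.bed"),
               extra = list(stage = "conserve", seed = seed))
message("done: ", out)
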