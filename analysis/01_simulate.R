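#!/usr/bin/env Rscript

# Stage 1: build the synthetic study. A 2 Mb, two-chromosome genome at
# GC 0.36 receives 150 planted G4 motifs (both strands); around them we lay
# stranded gene models with expression ranks, promoters enriched for
# motifs, neutral background tracks, and five ChIP-style peak sets (one
# per factor x condition) with a planted Class I/II/III structure plus
# uniform background peaks. Everything is written to results/sim/ as
# FASTA / BED6 / GFF3-free TSV / narrowPeak plus truth tables, so the
# later stages run purely from files.

suppressMessages(library(g4screen))

seed <- 20260925L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- g4_config(seed = seed)

message("simulating genome ...")
g <- random_genome(c(sim_I = 1200000L, sim_II = 800000L), gc = 0.36,
                   seed = seed)
pl <- plant_motifs(g, 150, seed = seed + 1, min_spacing = 1500L)
genome <- pl$genome
truth <- pl$truth
message(sprintf("planted %d motifs (%d background motifs pre-existing)",
                nrow(truth), nrow(pl$background)))

message("simulating annotation tracks ...")
feats <- synth_features(genome, truth, seed = seed + 2, classes = list(
  list(name = "promoters", n = 180, length = 500, colocate = 0.35),
  list(name = "genes", n = 300, length = 1500, stranded = TRUE,
       colocate = 0.30, expression = TRUE, template_strand = TRUE),
  list(name = "ndr", n = 150, length = 300, colocate = 0.25),
  list(name = "dsb_hotspots", n = 60, length = 2000, colocate = 0.20),
  list(name = "ltr", n = 40, length = 400, colocate = 0),
  list(name = "trna", n = 50, length = 90, colocate = 0)))

message("simulating peak sets with a planted class structure ...")
# Helicase-bound motifs are deliberately over-represented among the
# pausing sets (the dependence the stratified 2x2 tables measure), and the
# damage set grows sharply on depletion with the WT damage sites nested in
# it. Set sizes are one third of the real genome's counts (150 vs 446
# motifs), keeping the published per-stratum rates.
set.seed(seed + 3)
ids <- sample(seq_len(nrow(truth)))
pfh1_ids <- sort(ids[1:30])       # helicase-bound in WT (Class I)
others <- ids[31:150]
cdc20_wt_ids <- sort(c(pfh1_ids[1:12], others[1:5]))
cdc20_dep_ids <- sort(c(pfh1_ids[1:13], others[1:13]))
# WT damage barely overlaps WT pausing; depleted damage hits most of the
# depleted pausing sites (the Pfh1-dependent breakage signal)
gh2a_wt_ids <- sort(c(cdc20_wt_ids[1:4], others[20:41]))
gh2a_dep_ids <- sort(unique(c(gh2a_wt_ids, cdc20_dep_ids[1:16],
                              others[42:70])))
peaks <- list(
  pfh1_wt = synth_peaks(genome, truth, peaked_ids = pfh1_ids,
                        background_per_mb = 3, factor = "Pfh1",
                        condition = "wt", seed = seed + 4),
  cdc20_wt = synth_peaks(genome, truth, peaked_ids = cdc20_wt_ids,
                         background_per_mb = 3, factor = "Cdc20",
                         condition = "wt", seed = seed + 5),
  cdc20_dep = synth_peaks(genome, truth, peaked_ids = cdc20_dep_ids,
                          background_per_mb = 3, factor = "Cdc20",
                          condition = "dep", seed = seed + 6),
  gh2a_wt = synth_peaks(genome, truth, peaked_ids = gh2a_wt_ids,
                        background_per_mb = 2, signal_signif = 10,
                        factor = "gH2A", condition = "wt", seed = seed + 7),
  gh2a_dep = synth_peaks(genome, truth, peaked_ids = gh2a_dep_ids,
                         background_per_mb = 2, signal_signif = 25,
                         factor = "gH2A", condition = "dep", seed = seed + 8))
# planted classes follow from the definitions applied to the planted sets
instab_wt <- union(cdc20_wt_ids, gh2a_wt_ids)
instab_dep <- union(cdc20_dep_ids, gh2a_dep_ids)
ii_ids <- sort(setdiff(instab_dep, instab_wt))
iii_ids <- sort(intersect(instab_wt, instab_dep))

message("writing results/sim ...")
write_genome_fasta(genome, file.path(out, "genome.fa"))
write_intervals(truth, file.path(out, "truth_motifs.bed"), "BED6")
for (nm in names(feats)) {
  write_intervals(feats[[nm]], file.path(out, paste0(nm, ".tsv")), "TSV")
}
for (nm in names(peaks)) {
  write_narrowpeak(peaks[[nm]], file.path(out, paste0(nm, ".narrowPeak")))
}
write.table(data.frame(class = c("I", "II", "III"),
                       motif_ids = c(paste(pfh1_ids, collapse = ","),
                                     paste(ii_ids, collapse = ","),
                                     paste(iii_ids, collapse = ","))),
            file.path(out, "truth_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_manifest(file.path(out, "manifest.json"), cfg,
               inputs = character(),
               extra = list(stage = "simulate", seed = seed,
                            n_planted = nrow(truth)))
message("done: ", out)
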