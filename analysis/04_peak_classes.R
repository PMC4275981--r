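#!/usr/bin/env Rscript

# Stage 4: ChIP-peak association and helicase-dependence classes. Reads
# the five simulated peak sets, associates them with the motif track at
# the per-factor windows (300 bp for helicase/polymerase, 5 kb for the
# damage mark), classifies motifs into Class I/II/III, reconstructs the
# stratified 2x2 tables with Fisher P-values, compares recovered classes
# with the planted truth, and runs the paired peak-significance test
# between damage conditions.

suppressMessages(library(g4screen))

sim <- "results/sim"
out <- "results/classes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- g4_config()

motifs <- read_intervals("results/scan/motifs.bed", "BED")
peak_names <- c("pfh1_wt", "cdc20_wt", "cdc20_dep", "gh2a_wt", "gh2a_dep")
peaks <- lapply(peak_names, function(nm) {
  read_intervals(file.path(sim, paste0(nm, ".narrowPeak")), "narrowPeak")
})
names(peaks) <- peak_names
windows <- c(pfh1_wt = cfg$windows[["pfh1"]],
             cdc20_wt = cfg$windows[["cdc20"]],
             cdc20_dep = cfg$windows[["cdc20"]],
             gh2a_wt = cfg$windows[["gh2a"]],
             gh2a_dep = cfg$windows[["gh2a"]])

assoc <- build_association_matrix(motifs, peaks, windows)
for (nm in peak_names) {
  message(sprintf("%-10s %4d peaks, %3d motifs associated (window %g bp)",
                  nm, nrow(peaks[[nm]]), sum(assoc[[nm]]), windows[[nm]]))
}

cl <- classify_motifs(assoc)
message(sprintf("classes: I=%d II=%d III=%d unassigned=%d",
                sum(cl$class_I), sum(cl$class_II), sum(cl$class_III),
                sum(cl$label == "none")))
stopifnot(!any(cl$class_II & cl$class_III))

assoc_out <- cbind(assoc, cl[, c("class_I", "class_II", "class_III", "label")],
                   motifs[, c("chrom", "start", "end", "strand")])
write.table(assoc_out, file.path(out, "association_matrix.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# stratified contingency tables, one-sided enrichment Fisher tests
tables <- list(
  c("pfh1_wt", "cdc20_wt"), c("pfh1_wt", "cdc20_dep"),
  c("cdc20_wt", "gh2a_wt"), c("cdc20_dep", "gh2a_dep"))
tab_rows <- do.call(rbind, lapply(tables, function(tt) {
  bt <- build_table(assoc, tt[1], tt[2])
  tb <- unclass(bt$table)
  data.frame(stratum = tt[1], outcome = tt[2],
             a = tb[1, 1], b = tb[1, 2], c = tb[2, 1], d = tb[2, 2],
             pct_stratum = round(bt$row_percent[1], 1),
             pct_rest = round(bt$row_percent[2], 1),
             fisher_p = fisher_exact_2x2(bt$table, "greater"))
}))
print(tab_rows, row.names = FALSE)
write.table(tab_rows, file.path(out, "contingency_tables.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# recovery against the planted truth
truth_cl <- read.table(file.path(sim, "truth_classes.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
planted <- lapply(strsplit(truth_cl$motif_ids, ","), as.integer)
names(planted) <- truth_cl$class
truth_motifs <- read_intervals(file.path(sim, "truth_motifs.bed"), "BED")
key <- function(df) paste(df$chrom, df$start, df$end, df$strand)
m_of_truth <- match(key(truth_motifs), key(motifs))
recov <- vapply(c("I", "II", "III"), function(lab) {
  got <- which(cl[[paste0("class_", lab)]])
  want <- sort(m_of_truth[planted[[lab]]])
  length(intersect(got, want)) / length(want)
}, 0)
message(sprintf("planted-class sensitivity: I=%.2f II=%.2f III=%.2f",
                recov["I"], recov["II"], recov["III"]))
write.table(data.frame(class = names(recov), sensitivity = recov),
            file.path(out, "class_recovery.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# paired damage significance: depleted vs expressing
pp <- paired_peak_significance_comparison(motifs, peaks$gh2a_wt,
                                          peaks$gh2a_dep,
                                          window = cfg$windows[["gh2a"]])
message(sprintf("mean damage peak P at motifs: %.3g (wt) vs %.3g (depleted); Wilcoxon P = %.3g",
                pp$mean_pA, pp$mean_pB, pp$wilcoxon_p))
write.table(data.frame(mean_p_wt = pp$mean_pA, mean_p_dep = pp$mean_pB,
                       wilcoxon_p = pp$wilcoxon_p, n_nonzero = pp$n_nonzero),
            file.path(out, "paired_damage_significance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

write_manifest(file.path(out, "manifest.json"), cfg,
               inputs = c("results/scan/motifs.bed",
                          file.path(sim, paste0(peak_names, ".narrowPeak"))),
               extra = list(stage = "classify"))
message("done: ", out)
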