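---
title: "G4 motif discovery and matched-control enrichment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{G4 motif discovery and matched-control enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4screen)
options(g4screen.verbose = FALSE)
```

## The problem

Guanine-rich DNA can fold into intramolecular G-quadruplexes (G4), four-
stranded structures that stall replication forks unless a specialised
helicase — in fission yeast, the Pif1-family helicase Pfh1 — unwinds them.
`g4screen` implements the computational side of a genome-wide study of
such motifs: find every sequence with G4-forming potential, decide which
genomic features they associate with more (or less) often than chance,
relate them to ChIP-seq evidence of helicase binding, fork pausing
(polymerase-ε/Cdc20 occupancy) and DNA damage (γ-H2A), and ask whether
motifs are conserved across related genomes. Every stage is exercisable
end-to-end on synthetic genomes with planted ground truth; the `analysis/`
scripts in the source repository run exactly that study.

## Motif model and scanner

A G4 motif is a match to `(G≥3 N1–25)3 G≥3`: at least `min_islands = 4`
G-islands — maximal runs of `min_g_run = 3` or more consecutive guanines —
separated by loops of 1 to `max_loop = 25` bases. The scanner lists
maximal G-runs (a fast regular-expression pass), then chains consecutive
runs whose gaps are at most `max_loop`. Each maximal chain with at least
four islands is **one** motif spanning first island start to last island
end; a region with five or more islands is still a single motif, never
several overlapping ones. Minus-strand motifs are found by chaining C-runs
on the reference with identical rules and are reported in reference
coordinates with strand `-`; this is equivalent to scanning the reverse
complement (a tested invariant). Consequences of the maximal-run reading:

* loops have length ≥ 1 by construction and may contain G-runs *shorter*
  than `min_g_run`, but never an island;
* `N` is legal loop content and never island content (anything outside
  `{A,C,G,T,N}` becomes `N` on input, with a logged count);
* a gap longer than `max_loop` splits a chain, and each side qualifies on
  its own if it keeps four islands;
* same-strand motifs never overlap; a cross-strand overlap is two motifs,
  because intramolecular folding is strand-specific;
* tightening `max_loop` or `min_g_run` can only remove motifs (tested
  monotonicity).

```{r scanner}
scan_plus_strand("GGGTGGGTGGGTGGG")[, c("start", "end", "n_islands", "loop_lengths")]
```

All coordinates everywhere in the package are 0-based half-open (the BED
convention); GFF3 input is converted at the boundary by subtracting 1 from
starts. Chromosome names that differ between a genome and a track are hard
errors, not warnings — a silent misjoin would quietly corrupt every count
downstream.

## The matched-control null

Whether motifs "overlap promoters more than expected" depends on motif
length, chromosome placement and base composition, so the null is built by
resampling: `n_sets = 1000` control sets, each containing one random
region per observed motif constrained to the same chromosome, the same
length and the same GC content. Because lengths match, "same GC content"
is implemented as the same G+C **count**, which avoids floating-point
tolerance questions. Regions are drawn by rejection sampling with a cumsum
GC index (O(1) per candidate); if `max_attempts = 50000` candidates fail,
the tolerance widens one GC count at a time, and every widening is logged
and recorded per region. Control regions may overlap each other or real
motifs — no exclusion is applied, because none is part of the method's
definition. Set *i* uses a child RNG stream derived from `(seed, i)`, so a
collection is bit-for-bit reproducible and order-independent.

The test statistic is the number of motifs associated with ≥ 1 feature
interval (each motif counted once). Association at window 0 is strict
overlap; at window *w* > 0 it also admits an edge-to-edge gap of at most
*w* bases. Defaults: 0 bp for annotation tracks, 300 bp (the ChIP shearing
size) for helicase and polymerase peaks, 5,000 bp for γ-H2A, which spreads
kilobases around a break; 0/500 bp robustness presets are in
`g4_config()`.

The empirical P-value for the reported direction is `(b + 1) / (n + 1)`,
where `b` counts null sets at least as extreme as the observation (ties
extreme on both sides, so enrichment and depletion P-values sum to ≥ 1).
The add-one estimator is the default because the observation is itself one
more draw under the null and the estimator then never returns 0; the
`paper-literal` mode `b/n` is available for comparison with analyses that
report zero-exceedance results as bounds (e.g. "q < 0.003" from 1,000
sets). Super-uniformity of the default estimator under the null is a
tested acceptance property.

## Multiple testing

q-values use the Storey procedure: the null proportion π₀ is estimated on
the λ grid 0, 0.05, …, 0.90 as `mean(p > λ)/(1 − λ)`, smoothed with a
cubic spline (df = 3) and read off at λ = 0.90, clamped to (0, 1]; the
step-up rule `q_i = min{π₀ · n · p_j / rank_j : p_j ≥ p_i}` then yields
monotone q-values. With fewer than 20 tests, or when the spline fit fails,
π₀ falls back to 1, which is exactly Benjamini–Hochberg (the identity is a
tested oracle). One-sided P-values (in the reported direction) enter the
FDR step, and associations with q < 0.05 are called significant.

## Strand bias and expression

A motif overlapping a stranded gene lies on the *transcribed* (template)
strand iff its strand differs from the gene's coding strand — such a motif
never appears in the mRNA. The null of no bias is a two-sided exact
binomial test at 0.5. A motif overlapping several genes is assigned to the
gene with the largest overlap, ties to the first gene in (chrom, start)
order; both events are logged because the choice is this package's, not
part of the original method. `select_top_expressed()` takes the top-*n*
genes by an `expression` attribute (500 canonical, 100 as a robustness
check), breaking cutoff ties by gene id (logged).

## Peak association and motif classes

ChIP-seq peaks enter as called intervals with −log10 P scores (narrowPeak
column 8); calling is upstream and out of scope. Motifs are classified by
helicase dependence: **Class I** = bound by the helicase in wild-type
cells; per condition, *instability* = polymerase **or** damage-mark
association; **Class II** = unstable only after helicase depletion;
**Class III** = unstable in both conditions. Classes II and III are
disjoint by construction (verified over all 2⁵ association patterns);
Class I may intersect either. Stratified 2×2 tables are tested with
Fisher's exact test. The two-sided point-probability rule is the default
of `fisher_exact_2x2()`, but the published fork-pausing and damage tables
print the one-sided enrichment values (reconstructing their counts
reproduces all four printed P-values only under `alternative =
"greater"`), so the table-level drivers use that convention and say so.
The paired damage comparison takes, per motif and condition, the most
significant overlapping peak within the window (P = 1 when none), and
applies the two-sided Wilcoxon signed-rank test to the paired vector with
zero differences dropped; if every difference is zero the test is
degenerate and reported as P = 1 with a warning. Comparability of peak
scores across conditions assumes equal-depth read sets upstream — the
function documents rather than enforces this.

## Conservation

Pairwise alignment blocks (a MAF subset, or an ungapped-block TSV for
fixtures) map source intervals to target coordinates through per-column
maps that skip gap positions and run backwards across minus-strand
targets. A motif is conserved iff the aligned image of its interval
strictly overlaps any motif of the other species — overlap, not sequence
identity, and one-directional by definition.

## The synthetic-data generator

`random_genome()` draws i.i.d. bases with P(G) = P(C) = gc/2 — the
simplest "random sequence of the same GC content" model. Published
expected-density figures depend on the (unstated) composition model behind
them, so they are treated as model-sensitive observations, not targets;
`expected_density_by_simulation()` reports this package's own expectation
with a Monte-Carlo standard error. `plant_motifs()` writes template copies
(default `GGGTGGGTGGGTGGG`, fixed 1-bp loops for unambiguous detection) at
uniform positions, accepting a site only if a local scan returns exactly
the planted interval and strand, and keeping plants at least `max_loop +
1` bp apart so two plants can never merge; fixtures that need each peak to
touch exactly one motif raise `min_spacing`. Feature and peak generators
place a controlled fraction of elements on randomly chosen truth motifs
(the rest uniformly), with log-normal expression ranks for gene classes
and MACS-like peak geometry (mean 1,838 bp, sd 983 bp, −log10 P floored at
the caller cutoff 5).

What the generator does *not* emulate: chromatin-driven clustering of
features, GC isochores and repeats (the i.i.d. genome makes GC-rich
windows rarer than in real genomes, which *strengthens* the pile-up of
GC-matched controls on planted motifs), read-level noise, and peak-calling
artifacts. Passing tests therefore demonstrate correctness of the
machinery and calibration of the null on composition-neutral features, not
biological conclusions about real genomes.

## Problem sizes and numerical choices

The bundled study (`analysis/`) uses a 2 Mb, two-chromosome genome at GC
0.36 with 150 planted motifs and 1,000 control sets — large enough that
every published effect direction is visible, small enough to re-run in
minutes. The acceptance checks use: 200 random 2-kb sequences across GC
0.30–0.50 for scanner/oracle equivalence; 2,000 replicates at n_sets = 100
for P-value calibration; a 5 Mb genome and 100 sets for the matching
contract; and 50 + 50 replicates of a 400-kb genome (GC 0.44, 100 motifs,
promoters on 5% of the genome, co-location calibrated to ~3× the
matched-null association rate) at n_sets = 200 for planted-signal
recovery. GC 0.44 — the top of the range spanned by the fission-yeast
genomes — is used there because at lower i.i.d. GC the eligible GC-matched
positions concentrate on the planted motifs themselves and the matched
null absorbs most of the planted signal; the vignette section above
explains why that artifact is specific to i.i.d. backgrounds.

Other fixed choices: exact GC-count matching with logged ±1 relaxation
rather than a genome-wide eligible-position index (simple, memory-light,
exact in the common case, and auditable); Fisher tie handling at relative
tolerance 1e-7 (the underlying hypergeometric enumeration is exact);
child seeds from a multiplicative hash kept below 2³¹.

## Known limitations

* The scanner does not score thermodynamic stability (no G4Hunter-style
  scores) and ignores inter-strand or RNA quadruplexes.
* Absolute motif counts on real assemblies depend on the assembly version;
  counts reported for one build are not comparable across builds.
* The conservation mapper handles pairwise blocks only; multiple
  alignments must be reduced to pairs upstream.
* With `paper-literal` empirical P-values, zero-exceedance tests return
  P = 0, which downstream q-value estimation rejects; use the add-one
  default when feeding `qvalues()`.
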