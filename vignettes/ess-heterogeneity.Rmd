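---
title: "Quantifying exon-skipping splicing heterogeneity and RNA structure similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying exon-skipping splicing heterogeneity and RNA structure similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(essplice)
library(dplyr)
```

## The problem

In cleavage-stage mouse embryos, individual blastomeres differ in how often
internal exons of skipping-prone pre-mRNAs (the motivating case is *Carm1*
exons 3–6) are spliced out.  Because each exon-skipping isoform removes a
different amount of sequence, raw read counts from a targeted amplicon
assay (SPAR-seq style: one primer pair spanning the full exon panel,
deep paired-end sequencing of the amplicons) are not directly comparable
across isoforms: shorter amplicons are not informative over the same
sequence length as longer ones.  This package implements the complete
desk-side analysis for such assays:

1. **Read classification** — merge paired-end reads, route unmergeable
   long-amplicon pairs, and assign each read to an isoform of a declared
   catalog.
2. **Splicing statistics** — length-normalized exon-skipping percentages,
   simple alternative/canonical ratios, spike-in normalisation, per-embryo
   relative levels, and spatial-group hypothesis tests.
3. **Structure similarity** — an RNA secondary-structure comparison between
   two transcripts via overlapping fragments, bracket-tree edit distance
   and an empirical null threshold.
4. **Synthetic data** — generators that emulate the full study design so
   every stage can be validated statistically without any external data.

## The percentage model

For the six-category exon-skipping model (canonical `noS` plus `E3S`,
`E5S`, `E6S`, `E56S`, `E3456S`), each category's read count $R$ is
converted to a read *density* by dividing by the summed length $L$ of the
exons that uniquely evidence that category: the full exon chain for `noS`,
and the two exons flanking the skipped block for each skipping isoform
(e.g. $L(\mathrm{E2}+\mathrm{E4})$ for exon-3 skipping,
$L(\mathrm{E4}+\mathrm{E7})$ for skipping of exons 5–6,
$L(\mathrm{E2}+\mathrm{E7})$ for skipping of exons 3–6).  The reported
percentage is the density's share of the summed densities:

$$
P(\mathrm{iso}) \;=\;
\frac{R(\mathrm{iso})/L(\mathrm{iso})}
     {\sum_{j} R(j)/L(j)} .
$$

These percentages sum to one, are invariant to uniform count scaling, and
respond monotonically to single-count perturbations — all three properties
are enforced by the test suite on thousands of random fixtures.
Isoforms observed by the classifier but outside the six-category model
(`E4S`, `E34S`, `E345S`, the long-exon-4 variant `E3a`) are reported
alongside with their raw counts and excluded from the normalisation.
A profile whose six model counts are all zero is *undefined* and
propagates as missing values, never as zeros.

For two-way events (one alternative form against the canonical form) the
percentages are plain count ratios,
$P(\mathrm{AS}) = R(\mathrm{AS}) / (R(\mathrm{noAS}) + R(\mathrm{AS}))$,
implemented by `as_percentage()`.

The flanking-exon denominators are derived from the catalog's exon chains
(`ess_denominators()`), not hard-coded, so any analogous skipping panel
works unchanged.

## Read classification

**Merging.**  `merge_read_pairs()` is an explicit overlap-consensus
merger: it scans all candidate overlaps of at least `min_overlap` (default
10 nt) between the forward read and the reverse-complemented reverse read
and accepts the longest whose mismatch fraction is at most
`max_mismatch_frac` (default 0.1).  A pair from an amplicon longer than
$2 \cdot \mathrm{read\_len} - \mathrm{min\_overlap}$ can never merge; with
300 nt mates this boundary is 590 nt, which is why amplicons above
~600 nt (the canonical `noS` and the long-exon-4 `E3a`) travel a separate
route.  Quality scores are ignored by default; with
`use_quality = TRUE` overlap conflicts take the higher-quality base.

**Merged-read classification.**  `classify_reads()` computes the global
Levenshtein distance (unit-cost substitutions and gaps) from each read to
every reference — all isoforms plus the spike-in — and assigns the unique
best reference when the distance is at most `max_edit_frac` (default 0.1)
of the reference length *and* the runner-up is at least `min_margin`
(default 2) edits worse.  Ties and sub-margin wins are reported
`unclassified`, never broken at random.  We use the plain global distance
rather than a free-end-gap variant because SPAR amplicon reads are
full-length by construction; free end gaps would let short references
(e.g. the two-exon `E3456S`) spuriously match inside longer reads.  The
distance kernel is a banded dynamic program capped just above the largest
admissible distance plus the margin, which provably leaves every
assignment identical to the full distance matrix while making 10^5-read
panels cheap; the test suite verifies exact agreement with an independent
full-matrix implementation (`utils::adist`).  Full-length single-molecule
(CCS-style) reads enter this same path unchanged.

**Unmerged pairs.**  Pairs that fail to merge are long-amplicon evidence.
The forward mate is matched against the shared 5′ prefix of the long
isoform references and the reverse-complemented reverse mate against
their 3′ suffixes (each within `max_edit_frac` of the mate length).  The
two long isoforms are then separated by the *diagnostic junction
signature* of the exon-4 extension: the 2k-mer spanning the E4/E4ext and
E4ext/E5 junctions occurs in exactly one reference
(`junction_signatures()` marks such signatures).  The signature search is
edit-tolerant (up to `floor(max_edit_frac * 2k)` edits): with a 1 %
per-base error rate an exact 24-mer match would fail on roughly a fifth
of true extension pairs and silently misroute them to the canonical
isoform.  Pairs matching no long-isoform end are `unclassified`.
`count_sample()` ties the routes together and conserves the read total
exactly: every input read lands in exactly one of isoform counts,
`spike_in`, or `unclassified`.

## Heterogeneity statistics

Each blastomere receives the same nominal amount of a synthetic spike-in
RNA; `spike_in_normalize()` computes per-cell scale factors
$s_c = \mathrm{expected} / \mathrm{observed}_c$.  Percentages are ratio
statistics and are unchanged by this scaling; the scale factors matter
for *expression* comparisons.  Cells with zero recovered spike-in reads
cannot be calibrated and are excluded with a warning.

The scalar used for heterogeneity displays and tests is the total
exon-skipping fraction $1 - P(\mathrm{noS})$.  Within each embryo,
`relative_levels_within_embryo()` divides every cell's metric by the
embryo maximum, giving relative levels in $[0, 1]$ with the top cell at
exactly 1.  Max-normalisation (rather than z-scoring) was chosen because
the quantity of interest is "which blastomere leads within its embryo"
on a bounded colour scale; an embryo whose cells are all zero yields
missing relative levels.

Spatial groups (blastomeres attached / not attached to the second polar
body in two-cell embryos, near / far in tetrahedral four-cell embryos)
are compared with the classical equal-variance two-sample Student's
*t*-test (`compare_spatial_groups()`; Welch's correction is deliberately
not applied, matching the named test), and occupancy categories with a
Pearson $\chi^2$ test without continuity correction
(`occupancy_test()`; the 3×2 occupancy-by-group design has
$\mathrm{df} = 2$).  Degenerate zero-variance inputs return $t = 0,
p = 1$ when the means agree instead of erroring.

## Structure similarity

Two RNAs are compared fragment-wise: `split_into_fragments()` cuts
500 nt windows advancing 400 nt (adjacent fragments overlap by 100 nt),
with one extra end-anchored fragment when the final window would overrun
— a stated convention that guarantees full coverage without emitting
short tails.  Each fragment is folded and the dissimilarity $f$ between
two fragments is the ordered tree edit distance (unit-cost insert,
delete, relabel; Zhang–Shasha algorithm) between their bracket trees:
one internal `P` node per base pair, one `U` leaf per unpaired base,
under a virtual root.  $f$ is a true metric; the suite property-tests
the axioms on 10,000 random tree pairs and verifies exactness against a
brute-force forest-edit search on all small trees.

Because the numeric scale of $f$ depends on the folder and the cost
model, a fixed threshold is *not* portable.  Significance is instead
empirical: `build_null()` takes $f$ values from comparing the reference
fragments against a pool of random mRNA-like fragments and sets the
threshold at the left-tail $\lceil \alpha n \rceil$-th order statistic
($\alpha = 0.025$ by default, mirroring a left-2.5 % boundary); fewer
than a fraction $\alpha$ of null values lie strictly below it.
`find_similar_fragments()` reports fragment pairs with $f$ strictly
below the threshold.

The built-in folder (`fold()`) maximizes Watson–Crick plus GU-wobble
pairs subject to hairpin loops of at least 3 unpaired bases, with a
deterministic traceback (prefer unpaired, then the leftmost partner).
A maximum-pairing objective was chosen over a thermodynamic one so that
the whole pipeline is self-contained, deterministic and exactly testable
(the suite checks optimality against exhaustive enumeration for all
short sequences); any external thermodynamic predictor can be plugged in
through the `folder` argument of `pairwise_f_matrix()` / `run_struct()`
as a function from sequence to dot-bracket, *provided the null is
rebuilt with the same folder*.

## The synthetic data generator

`simulate_cell_reads()` emulates the assay's data-generating process:
isoforms drawn by mixture proportions, a spike-in fraction, full
amplicons cut into 300 nt paired-end mates (reverse mate
reverse-complemented), and independent per-base substitution errors
(1 % default — amplicon Illumina error is substitution-dominated, and a
substitution-only model keeps the simulation truth exact for oracles).
The bundled gene model (`default_gene_model()`) uses synthetic exons of
140/130/120/80/70/70 nt plus a 60 nt exon-4 extension: the canonical
amplicon (610 nt) and the extension variant (670 nt) exceed the 600 nt
merge limit, while the extension and both of its junctions fall inside
the reverse mate — the same geometry that makes the real assay's long
isoforms separable from unmerged pairs.  Default mixture: the canonical
isoform dominates (45 %) and skipping of exons 5+6 is the most frequent
skipping event (15 %), with the remaining variants minor.

`simulate_embryo_panel()` plants spatial heterogeneity: per-cell
total-ESS truths are drawn normally around group means separated by
`ess_effect` (default 0.2, polar-body-proximal group lower) with
between-cell dispersion 0.15, then converted to read proportions by
inverting the length normalisation
($\pi_i \propto P_i L_i$, `ess_to_read_proportions()`), so that planted
truths live on the same percentage scale the pipeline estimates.
`simulate_rna_sources()` plants one identical 500 nt fragment on the
fragmentation grid of two otherwise random RNAs (its $f$ is exactly 0)
plus a pool of random null fragments.

All generators are pure functions of a root seed: per-unit substreams
are derived by hashing the unit labels (`derive_seed()`), so panels are
reproducible cell-by-cell and independent of generation order.

## What the tests do and do not show

The validation suite establishes, on synthetic data: exact fidelity of
the percentage formulas (10^-12), exact classifier agreement with a
brute-force oracle, nominal binomial coverage of planted mixtures at
2,000 reads/cell, exact merge geometry at the 590 nt boundary, exactness
and metric axioms of the tree edit distance, folder optimality on all
short sequences, convergence of the empirical null threshold, and
agreement of the detection power for planted heterogeneity with the
closed-form two-sample *t* power.  Problem sizes used by the suite and
the acceptance script — up to 200 simulated cells at 2,000 reads each,
10,000-value nulls, 500-replicate power runs — were chosen as the
smallest sizes at which the statistical checks are sharp.

Synthetic reads do not model per-cycle quality profiles, indels
(available optionally in the error model contract but off by default),
PCR duplicates, chimeric amplicons or barcode cross-talk; passing tests
therefore demonstrate correctness of the *computations*, not robustness
to every artefact of real libraries.  Real-data users must supply the
actual exon boundary coordinates of their panel (the bundled model is a
synthetic stand-in) and should treat any published absolute $f$
threshold as a reference point only — the null, and hence the
threshold, must be recomputed whenever the folder, cost model or
fragment pool changes.

## Worked example

```{r example}
gm <- default_gene_model()
panel <- simulate_embryo_panel(gm, n_embryos = 4, n_reads = 400,
                               seed = 42, emit_reads = TRUE)
counts <- bind_rows(lapply(panel$sample_sheet$cell_id, function(cell) {
  count_sample(panel$reads[panel$reads$cell_id == cell, ], gm,
               sample_id = cell)
}))
profiles <- ess_percentages(counts, gm)
head(filter(profiles, in_model), 12)

ess <- profiles |>
  filter(isoform == "noS", in_model) |>
  mutate(ess = 1 - percentage) |>
  left_join(panel$sample_sheet, by = c(sample_id = "cell_id"))
compare_spatial_groups(ess$ess[ess$spatial_label == "pB"],
                       ess$ess[ess$spatial_label == "npB"],
                       labels = c("pB", "npB"))
```

```{r structure-example}
src <- simulate_rna_sources(seed = 42, lengths = c(1300, 1700), n_null = 40)
res <- run_struct(setNames(src$sources$sequence[1], "query"),
                  setNames(src$sources$sequence[2], "reference"),
                  src$null_fragments, out_dir = tempfile("struct"))
glance(res$null)
head(res$hits)
```
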