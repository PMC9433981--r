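---
title: "Methods: bait-centred discovery of candidate transcription-factor targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bait-centred discovery of candidate transcription-factor targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baitrank)
```

## The problem

A MADS-box transcription factor expressed in the developing seed coat is a
strong causal candidate for seedlessness in table grape: seeded (SD)
varieties show a sharp expression peak at the pea-size stage (S3 of the
four sampled stages S1--S4, pre-bloom to veraison), while stenospermocarpic
seedless (SL) varieties stay low and flat. `baitrank` implements the
analysis path that turns that observation into a ranked list of candidate
target genes: per-stage differential expression between SD and SL classes,
short time-series clustering of DEG trajectories, bait-centred
co-expression across several datasets combined into a single composite
score, and a scan of candidate promoters for the CArG box — the canonical
MADS-protein binding site with consensus `CC[A/T]{6-8}GG`.

Every stage is exercised on synthetic data with planted ground truth, so
the whole pipeline is testable offline and its operating characteristics
(recall of planted targets, type-I error, permutation calibration) are
measured rather than assumed.

## Normalization and differential expression

Input matrices are linear-scale intensities (gene x sample). Processing
follows standard single-channel microarray practice:

1. **Negative-signal filtering.** Non-positive intensities are measurement
   noise: individual values are set to missing, genes non-positive
   everywhere are removed. Missing is kept distinct from zero throughout.
2. **75th-percentile normalization.** Each sample is rescaled so that its
   0.75 quantile (linear-interpolation quantile, `stats::quantile`
   type 7) equals a common target (default 100). The invariant is exact:
   rescaling commutes with linear interpolation, so the recomputed
   quantile equals the target to machine precision.
3. **Per-gene t-test on log2 values.** The default is Welch's
   unequal-variance test; the original study only states "a t-test", and
   Welch is the safer default when the software's pooling behaviour is
   unknown (a pooled-variance option is exposed in `deg_config()`). Fold
   changes are reported on the linear scale as `sign(log2fc) * 2^|log2fc|`;
   a gene is called up when `p <= 0.05` and `log2fc >= 1` (i.e. `|FC| > 2`),
   symmetrically down. No multiple-testing correction is applied by
   default because the headline DEG counts this mirrors are raw-p counts;
   Benjamini-Hochberg is available behind a flag. Genes with fewer than two
   non-missing values in a group are reported untestable, never silently
   dropped; zero-variance genes with equal means get p = 1 (and p = 0 when
   means differ), avoiding 0/0 without inventing significance.

Contrasts come in two flavours, matching the study design: stage-wise
SD vs SL pooling the two varieties of each class (replicates as
independent samples), and an explicit single-variety pair (e.g. the
highest- vs lowest-expressing variety) at one stage. `venn_partition()`
provides the exclusive-region set algebra used to define "commonly
up-regulated" genes between the two contrasts; region sizes always sum to
the union.

## Short time-series profile clustering

Stage trajectories are short (T = 4), so clustering follows the
model-profile approach of the Short Time-series Expression Miner: profiles
are pre-enumerated rather than learned.

* **Candidates.** All integer trajectories anchored at 0 with successive
  changes bounded by `c` units: `(2c + 1)^(T-1)` of them. The default
  `c = 1` (the original tool's choice is unstated; it is a config value).
* **Selection.** `m = 15` representatives (the number used in the study's
  figure) picked greedily: starting from the flat profile, repeatedly add
  the candidate maximizing the minimum distance to the selected set.
  Distance is `1 - Pearson correlation`; correlation is undefined against
  the flat anchor, so any pair involving a zero-variance trajectory falls
  back to Euclidean distance. Ties break by lexicographic trajectory
  order, making selection fully deterministic.
* **Assignment.** Each gene's trajectory (mean log2 per stage minus the
  stage-1 mean, per variety) goes to the non-flat profile with maximal
  Pearson correlation; zero-variance trajectories stay unassigned; exact
  ties go to the lowest profile ID.
* **Significance.** With T = 4 all 4! = 24 stage orderings are enumerated
  exactly (no sampling): trajectories are re-ordered, re-anchored and
  re-assigned; a profile's expected count is its mean count over the
  permutations, and its p-value is the binomial tail
  `P(X >= observed)`, `X ~ Binomial(n_assigned, E/n)`, Bonferroni-corrected
  over the m profiles. The binomial (rather than Poisson) tail respects
  the fact that counts are bounded by n. Larger T is refused beyond 8!
  permutations rather than silently approximated.

### A calibration subtlety worth knowing

When genes are independent, the procedure is well calibrated: on null
data (i.i.d. noise genes) no profile is Bonferroni-significant in 20/20
simulation runs. Per-sample percentile normalization, however, estimates
each scale factor from the same finite matrix; on the log2 scale this adds
a small offset *shared by every gene in a sample*. That coherent shift
moves all trajectories together, over-disperses profile counts relative to
the binomial model, and makes the permutation p-values measurably
anti-conservative (at 1000 null genes, roughly a quarter of runs flag at
least one profile). The package therefore evaluates calibration on
trajectories taken without the rescaling step — legitimate for a null
matrix whose samples already share a scale — and users should read
profile significance on normalized real data as an enrichment heuristic,
as it is in the original tool, not as an exact test.

## Bait-centred co-expression and the composite score

Candidate targets are genes that track the bait across several independent
expression resources. Two association measures are supported per dataset:

* **Pearson correlation** `r` of log2 values with the bait over all of a
  dataset's samples;
* **HRR (highest reciprocal rank)**, the network measure used by plant
  co-expression databases: `HRR(g) = max(rank_bait(g), rank_g(bait))`
  where each rank is the position in the other gene's
  correlation-sorted neighbour list (self excluded, best = 1). Lower is
  stronger; ties break by gene ID so results are deterministic.

Each gene then receives three components, multiplied into the final score
`s = a * b * c`:

| component | meaning | definition |
|---|---|---|
| `a` | concordance between data sources | fraction of datasets where the gene passes membership (`r >= 0.6` for Pearson, `HRR <= 100` for HRR, defaults) |
| `b` | intensity of correlation | product over datasets where the gene is measured of `|r|` (Pearson) or `1/HRR` (HRR) |
| `c` | expression level in the target tissue | rank fraction of the gene's mean normalized intensity in the primary ovule/seed matrix (highest gene = 1, average ranks for ties) |

Genes with `a = 0` are not co-expressed anywhere and leave the listed set;
the bait itself is excluded by ID. Sorting is by descending `s`, ties by
higher `b` then gene ID, and the top `K = 100` genes form the candidate
list.

Design choices made where the source material is silent: "concordance" is
taken as fraction-of-datasets-passing (an integer count would be
rank-equivalent for a fixed number of datasets); HRR ranks are mapped to
`1/HRR` so they are bounded in (0, 1] and multiplicable with correlations;
`c` is a rank fraction rather than a raw intensity so the product is
dimensionless and invariant to global rescaling; and positive and negative
co-expression are ranked separately (`sign_mode`) because a signed product
across datasets is ill-defined. An optional filter
(`require_down_in_sl`) demotes genes that are not down-regulated in
seedless varieties — internally computed as log2fc(SD - SL) > 0 at two or
more of stages S2-S4 — replacing an external study table with the same
logic.

## CArG-box scanning

The scanner reports **every** match of `CC[A/T]{6-8}GG`: all three widths
(10/11/12 bp), all anchors, overlaps included, via a per-width sliding
window (a single greedy regex pass would undercount nested matches). `N`
never matches. Because the A/T degeneracy is self-complementary and the
reverse complement of `CC W{k} GG` is again `CC W{k} GG`, the minus-strand
hit set maps exactly onto the plus-strand set; the scanner verifies this
identity internally on every sequence and collapses the pair to one `+`
hit by default (a flag emits both, for mirroring naive two-strand counts).
Coordinates are 1-based inclusive with position 1 the 5'-most base of the
supplied promoter; BED output (0-based half-open) is emitted alongside to
avoid convention confusion.

## The synthetic experiment generator

`generate_experiment()` emulates the statistical structure of the study
design — not its biology — so that planted signals are exactly known:

* **Design:** 2 SD + 2 SL varieties x stages S1-S4 x 3 replicates;
  log-normal intensities (Gaussian noise, sd 0.5, on log2), gene baselines
  `N(8, 1.5)`.
* **Bait:** log2 stage means `(6, 6, 12, 9)` in SD (sharp S3 peak, S4
  decline) and `(5, 5, 6, 5)` in SL. The source study reports the shape
  but no effect sizes; these values are the package's own choices, fixed
  once.
* **Targets (default 50):** generated as
  `baseline + 1.5 * (rho * z + sqrt(1 - rho^2) * eps)` on log2, with `z`
  the standardized bait trajectory of the same dataset and `rho = 0.9`,
  jointly over the primary SD samples and every auxiliary dataset — so
  cross-dataset concordance is non-trivial, as the composite score
  requires. Targets are additionally shifted down by `deg_log2fc / 2` in
  SL at S2-S4 (seedless down-regulation).
* **Extra DEGs (default 200):** `+2` log2 units in SD at S3 only.
* **Auxiliary datasets (default 2 x 30 samples):** same gene IDs, fresh
  noise, same planted bait-target correlation; no design metadata, like a
  public expression atlas.
* **Promoters:** 2 kb i.i.d. uniform A/C/G/T; target promoters receive
  planted CArG boxes at recorded coordinates (the generator verifies the
  planted set is exactly what a scan finds); all other promoters are
  rejection-sampled to be motif-free. Exact ground truth is deliberately
  preferred over realistic base composition.

What passing tests on this generator do **not** show: robustness to probe-
level artefacts, dye or batch effects, heavy-tailed noise, realistic
promoter composition, or correlated non-target gene modules. The generator
is a test harness for the machinery, not a simulator of grapevine.

`generate_null()` produces the matched no-signal dataset used for
type-I-error and profile-significance calibration.

## Reference problem sizes

The packaged acceptance analyses use: 5000 genes / 50 targets / 10 seeds
for target recovery (mean top-100 recall and precision), 10 000 genes /
5 seeds for t-test calibration, 1000 genes / 20 seeds for profile
significance calibration and power, 100 random 50-gene matrices for the
HRR oracle, and 1000 random 2 kb sequences for the scanner oracle. These
sizes give Monte-Carlo error comfortably below the decision margins while
keeping a full run in the low minutes on one core.

## Running the pipeline

```{r, eval = FALSE}
cfg <- run_config(out_dir = "run1", seed = 7,
                  sim = sim_params(n_genes = 2000, n_targets = 30))
report <- run_pipeline(cfg)
```

All thresholds live in the configuration (never hard-coded):
`p < 0.05`, `|FC| > 2`, 75th percentile, 15 profiles, 5% Bonferroni,
top-100. A single run seed drives the one stochastic stage (simulation),
so identical configurations reproduce byte-identical outputs; the run
report additionally records the seed, per-stage counts and wall time (the
one field that legitimately differs between reruns). The same stages are
available from a shell via `inst/cli/baitrank.R`
(`simulate | deg | profiles | rank | scan | all`).

## Known limitations

* Profile significance on normalized data is an enrichment heuristic (see
  the calibration note above).
* The t-test operates per gene with no variance moderation; with 3
  replicates per variety-stage it is noisy, exactly as in the emulated
  analysis. Moderated alternatives (limma) are out of scope by design.
* HRR requires the full gene-gene correlation matrix; memory grows
  quadratically in gene count (about 200 MB at 5000 genes).
* The scanner is consensus-based; no PWM scoring or motif discovery.
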