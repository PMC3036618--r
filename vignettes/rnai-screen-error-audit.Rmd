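---
title: "Auditing false negatives and false positives in multi-reagent RNAi screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing false negatives and false positives in multi-reagent RNAi screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaiqc)
```

## The problem

Cell-based RNAi screens call a gene a "hit" when its knockdown reagent
shifts an assay readout.  Two reagent-level failure modes corrupt the gene
list: a reagent can silence unintended transcripts (an off-target effect,
producing a false positive) or it can fail to silence its own target (an
ineffective reagent, producing a false negative).  When a library carries
several independently tested reagents per gene — as the focused
*Drosophila* dsRNA sub-libraries do, with two to four dsRNAs per gene —
disagreement between sibling reagents becomes an observable signal from
which both failure rates can be estimated, and a principled rule is needed
to turn several possibly conflicting reagent calls into one gene call.
`rnaiqc` implements that audit end to end on a fully synthetic, seeded
test bed.

## Plate normalization

Raw well readouts are normalized per plate as $Z = (x - \mu)/\sigma$.
Both $\mu$ and $\sigma$ are computed over the plate's *sample* wells only:
the outer perimeter of a focused-library plate is deliberately left empty
to buffer edge effects, and empty or control wells would otherwise drag
the plate statistics.  $\sigma$ is the sample ($n-1$) standard deviation —
with that convention three wells at 10/20/30 score exactly $-1, 0, +1$,
and the estimate is unbiased; `sd_type = "population"` switches to the
$n$ divisor, and `include_controls = TRUE` pulls control wells into the
statistics for platforms that normalize against the whole plate.  A plate
with fewer than three sample wells or zero spread is a hard error, never a
silent `NaN`.  Missing profile entries propagate; they are never imputed.

Two invariants pin the implementation down: per-plate sample-well Z-scores
have mean 0 and SD 1 to $10^{-9}$, and Z is invariant under any affine
transform $a x + b$ ($a > 0$) of the raw values.

## Cross-screen signatures and the concordance audit

Reagents targeting members of a constitutively required complex (the
cytosolic ribosome, the proteasome) score in many unrelated screens, so
their per-screen Z profiles correlate.  `cluster_profiles()` clusters
profile rows with distance $1 - r$ (Pearson, pairwise-complete over shared
screens, at least 3 shared values) and average linkage; the merge heights
are checked in the test suite against an independent brute-force UPGMA
recomputation.  Rows that cannot be correlated with the rest are excluded
with a warning rather than poisoning the distance matrix.

The dendrogram is cut at a correlation distance of 0.5 ($r = 0.5$) by
default.  No published cut rule exists for this kind of figure; 0.5 is the
point where profiles stop sharing most of their variance, and it recovers
planted two-block structure in simulation.  A reagent counts as *in* a
signature cluster when it is a member **and** correlates with the
cluster's consensus signature (the per-screen mean Z over members) at
$r \ge 0.5$; both thresholds are exposed as parameters.

For each gene with two or more reagents in the matrix the audit asks
whether its reagents agree.  Discordant genes are attributed by
annotation: when the gene's curated set label matches the cluster's
majority label, the *out* reagent is the failure (a false negative due to
an ineffective reagent); when it does not, the *in* reagent is the
spurious one (an off-target false positive); unannotated genes are
ambiguous.  The reagent-level false-negative rate is then the number of
attributed-FN out-reagents over all reagents of the audited genes.  The
audited denominator is restricted to annotated genes with at least one
in-cluster reagent — the audit emulates a curated-gene-set analysis, so an
unannotated gene dragged into a cluster by an off-target reagent is out of
scope, while an annotated gene from the *wrong* set that intrudes into the
cluster stays in the denominator (it is the false-positive case).  The
set-level companion estimate, `pooled_nonsignature_rate()`, pools genes
that never showed their set's signature at all and is therefore an upper
bound that also absorbs mis-annotation and redundancy.

## Hit categories and the transcriptome filter

Within one screen, a reagent is a hit when $|Z| \ge 2$ in every replicate
*and* all replicates agree in sign.  The sign requirement is our reading
of "an absolute Z of 2 or more across both replicates": a reagent scoring
$+2.5$ and $-2.5$ has reproduced nothing.  Genes are then binned:
category 1 — all reagents scored; category 2 — at least two scored and at
least one failed; category 3 — exactly one scored; `none` — nothing
scored (kept in the output so false-negative analyses can see them).  For
the corner case of a single-reagent gene whose reagent scores, "all
scored" takes precedence and the gene is category 1; the published scheme
only ever shows multi-reagent genes, so the corner is ours to define.

Category-3 genes are unconfirmed single-reagent calls and are treated as
presumptive false positives; category-1/2 genes are confirmed, and their
non-scoring reagents are presumptive false negatives.  This gives three
screen-level rates: category-3 genes over the library size (the
false-positive rate *per reagent screened*), category-3 genes over all
hit genes (the same errors as a fraction of the *hit list* — a much
larger number, which is the practical point), and non-scoring reagents
over category-1/2 reagents.

Expression filtering marks a gene expressed at FPKM $\ge 1$ and elevated
at FPKM $\ge 5$ in the queried cell line.  Published descriptions of the
FPKM-1 cutoff disagree on whether the boundary value passes, so the
comparator is configurable (`">="` default, `">"` available).  A gene
missing from the table is `NA` — unknown, never counted as unexpressed.

## The m-of-k disambiguation model

With $k$ independently tested reagents per gene, per-reagent failure
probabilities $R_{FN}$ (a reagent on a true hit fails) and $R_{FP}$ (a
reagent on a non-hit scores), and independent reagents, a rule that calls
a gene when at least $m$ of its $k$ reagents score gives

$$E[\mathrm{FN}] = P\!\left(\mathrm{Bin}(k, 1 - R_{FN}) < m\right) H,
\qquad
E[\mathrm{FP}] = P\!\left(\mathrm{Bin}(k, R_{FP}) \ge m\right) N,$$

for $H$ true-hit and $N$ non-hit genes.  The named rules are lenient
($m = 1$), stringent ($m = k$) and majority ($m = \lfloor k/2 \rfloor +
1$); for $k = 2$ majority and stringent coincide.  `rule_polynomial()`
carries the same probabilities as literally expanded polynomials for
$k \le 3$ (e.g. $3r - 3r^2 + r^3$ for "any of three"), which the test
suite compares against the binomial form over a $21 \times 21$ rate grid
to $10^{-12}$ — two independent derivations of one model.
`simulate_disambiguation()` verifies both by Monte-Carlo at the reagent
level, and `rule_frontier()` enumerates every $(m, k)$ rule to exhibit
the trade-off: at $R_{FN} = 0.10$, $R_{FP} = 0.01$, requiring 2 of 3
reagents yields fewer expected misses than single-reagent screening *and*
fewer expected false alarms than lenient-of-3.  An RNAi mini-pool counts
as one reagent throughout; only independently tested reagents increase
$k$.  $N$ defaults to the library size minus $H$.

## What the generator emulates

`generate_library()` / `generate_screen_plates()` build 384-well plates
(16 × 24, empty perimeter, interior filled row-major) for a library of
`n_genes` genes with 1–4 reagents each.  Ground truth is drawn once:
`n_true_hits` hit genes, each reagent ineffective with probability
`reagent_fn_rate` and off-target active with probability
`reagent_fp_rate`, independently.  A reagent is *active* if (its gene is
a hit and it is effective) or it is off-target; activity is a property of
the reagent, fixed across screens, because off-target effects are
sequence-intrinsic — per-well Gaussian noise is the only per-screen
stochastic term.

A screen's response to the planted signature is bimodal: with probability
`screen_responsive_prob` (default 0.6) the screen is responsive and
weights the effect by $w_s \sim \mathrm{Uniform}(1 \pm 0.3)$; otherwise
it is nearly silent ($w_s \sim \mathrm{Uniform}(0, 0.1)$).  This is the
structure real screen panels show — a consensus signature is strong in
roughly half to two-thirds of assays and absent in the rest — and it is
what makes correlation clustering work at all: per-plate Z-scoring
cancels any response component common to all screens (active wells
inflate the plate SD, so a uniformly strong effect normalizes to the same
Z everywhere), leaving only the responsive/silent *contrast* as
clusterable signal.  With these defaults, effective sibling reagents
correlate at $r \approx 0.8$, comfortably inside the default cut.

In the exactly noiseless limit the cancellation is total: every profile
is constant across screens and Pearson correlation is undefined.  The
pipeline therefore switches to a magnitude route in that regime
(`magnitude_concordance()`: a reagent shows the signature when
$|Z| \ge 2$ in at least half its screens), under which recovery of the
planted inefficacy fraction is exact.

Features of real data the generator does **not** model: graded reagent
efficacy (efficacy is a binary flag — nothing in the audited quantities
constrains a strength distribution for "weak" reagents), spatial edge
gradients within plates (the perimeter is simply empty), correlated
off-target behaviour between sibling reagents, and cell-line-dependent
phenotypes.  Passing tests therefore demonstrate estimator correctness
under the stated generative model, not robustness to artefacts outside
it.

`generate_expression_table()` draws each gene expressed per cell line
with probability `expressed_fraction` (default 0.53, a typical expressed
fraction for cultured-cell transcriptomes); expressed genes get
log-normal FPKM (`meanlog` 3, `sdlog` 1.5 — median ≈ 20, a long right
tail) and unexpressed genes uniform FPKM below 1.

## Numerical and design choices

* Correlations require ≥ 3 shared screens and nonzero variance; failures
  are errors at the single-pair level and warned exclusions at the
  matrix level.
* Linkage ties resolve deterministically through `stats::hclust` given a
  fixed row order; all generators are seeded, and one pipeline seed
  derives every stage seed, so reports are byte-identical across reruns.
* Cluster labels come from the majority annotation of member genes, ties
  broken lexicographically.
* Unknown configuration keys are rejected rather than ignored.
* All randomness flows from a single integer seed per object; identical
  parameters and seed give bit-identical files.

## Problem sizes

The shipped tests and the acceptance script run the recovery study at 16
screens over a 1,000-gene two-reagent library with 50 planted signature
genes and 8% planted inefficacy, repeated over 10 seeds (about two
seconds per run), and verify the disambiguation model with $10^4$
Monte-Carlo replicates against a 13,735-gene scenario.  These sizes give
binomial standard errors a factor of several below the effects being
measured; scaling them up changes nothing structurally.

## Known limitations

The concordance estimator conditions on genes with at least one
in-cluster reagent, so a gene whose reagents are *all* ineffective never
enters the denominator; the estimated rate is $R_{FN}/(1 + R_{FN})$-biased
at two reagents per gene (about 0.074 for a planted 0.08), well inside a
103-reagent confidence interval but visible asymptotically.  The same
conditioning is inherent to the published analysis this audit mirrors.
The set-level pooled rate conflates inefficacy with mis-annotation and
genuine biological redundancy, and is reported as an upper bound, not an
estimate of reagent failure.
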