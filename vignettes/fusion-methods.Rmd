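---
title: "Methods: fusing RNAi-screen and transcriptome gene lists for pathway analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusing RNAi-screen and transcriptome gene lists for pathway analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenfuse)
```

## The problem

A genome-wide RNAi survival screen (the *phenome*) and a replicated
expression time course (the *transcriptome*) interrogate the same biology
from two sides: which genes a cell *needs* to survive a stimulus, and
which genes it *re-expresses* in response to it.  Empirically these two
gene sets barely overlap — master regulators are controlled
post-translationally and never change transcript level, while many
induced transcripts are individually dispensable.  Comparing the two
assays gene by gene is therefore uninformative, and testing each list
separately for pathway enrichment splits a pathway's signal across two
underpowered tests.

`screenfuse` implements the *fusion* strategy: take the set union of the
RNAi hit list and the (by default up-regulated) differentially expressed
gene (DEG) list *before* pathway enrichment analysis (PEA).  A pathway
whose essential members and whose induced members are different genes
then contributes both groups to a single Fisher test, which is exactly
the situation where fusion beats either platform alone.

## Models and statistics

### DEG rule

Per gene and timepoint, control vs treated arms are compared with a
Welch (unequal-variance) two-sample *t*-test on `log2(value + pseudo)`,
two-sided, combined with a signed fold change computed on the linear
group means, `f = (treated + pseudo)/(control + pseudo)` reported as `f`
or `-1/f` so that `|fold|` is always at least 1.  A gene is a DEG iff
`p < 0.05` and `|fold| > 2` at one or more timepoints; timepoint lists
are pooled by union.  Genes below a linear abundance floor (RPKM 2) in
*both* conditions at every timepoint are removed first.  Design notes:

* the source protocol says only "T-test"; Welch is the safer default for
  quadruplicate array groups and is configurable only through the code,
  deliberately — the rule is the contract;
* fold changes on linear means with the same pseudo-count (default 0.1),
  since the protocol does not state the scale; both choices are explicit
  deviations recorded here;
* zero-variance genes with equal means get `p = 1` (deterministic null),
  not `NaN`;
* no multiple-testing correction at the DEG stage (none is applied in
  the replicated protocol); a gene can legitimately appear in both the
  up and down lists across timepoints and is flagged.

### Enrichment

PEA is the right-tailed Fisher exact test: for a term with `K` members
inside the universe, a list of `n` universe genes hitting it `k` times,
`p = P(X >= k)`, `X ~ Hypergeom(N, K, n)`.  Benjamini–Hochberg step-up
FDR is applied across all terms of one collection per run (the FDR
procedure is unnamed in the replicated protocol; BH is the standard
default of the tools it used), with significance at `p < 0.05` and
`FDR < 10%`.  The universe is always explicit — proprietary tool
universes are not reconstructable, so the package defaults to the
platform-detected gene set and logs it.  Term-name blocklists
(case-insensitive substrings or anchored globs) reproduce the manual
exclusion of uninformative disease/cell-line terms.

### Platform comparison

For each pathway of `T` genes detected by several platforms, the
genes-in-pathway proportions are compared with a one-tailed Fisher test
on `[[k_fusion, T - k_fusion], [k_other, T - k_other]]`, alternative:
fusion proportion greater.  Pathways not detected by a platform enter
with `k = 0` and an `nd_comparison` flag.  This construction reproduces
the published both-detected comparison p-values to (one unit in) their
printed precision, except the degenerate three-gene pathway row, which
is recomputed but excluded from acceptance by design.  Gene-level list
overlaps are tested with the upper hypergeometric tail in an explicit
universe; for the published counts (overlap 78 between lists of 1011
and 957 within 12,363 detected genes) this gives p ≈ 0.53, consistent
with the published non-significance bound p ≤ 0.73.  The published
figures are ambiguous between the 12,363 detected genes and the 13,826
screened ORFs as universe; both satisfy the bound, and the detected set
is the package default.

### Expression landscapes

The original landscape tool distributes expression signal over a network
layout but does not document its interpolation.  The package defines its
own, with conservation as the contract: every node deposits a Gaussian
kernel (bandwidth = fraction of the unit layout extent, default 0.05)
carrying its mean replicate expression; kernels are renormalized after
truncation to the grid so no mass is lost at boundaries; optionally each
edge deposits `confidence * (mass_u + mass_v)/2` spread along 16 sample
points.  The grid total therefore equals the deposited mass to within
floating-point error, landscapes are linear in the masses, and
mirror-symmetric inputs give mirror-symmetric grids — all tested
properties rather than visual claims.  Layouts are Fruchterman–Reingold
per connected component under a fixed seed with canonical vertex
ordering, so they are reproducible and independent of input order.
STRING networks are read at combined-score thresholds 0.400 (medium) or
0.700 (high), scores divided by 1000, duplicate pairs resolved by
maximum.

## The synthetic world

No raw arrays or screen plates ship with the package; instead
`make_universe()` + `simulate_study()` generate a paired study with
known truth, scaled to the replicated designs:

* 12,000 genes (scaled to the 12,363 array-detected set), 150 pathways
  with log-uniform sizes 10–300 and 20% membership overlap;
* expression: baseline log2 abundance ~ Normal(4, 2), quadruplicate
  control/treated arms at 8/24/72 h, planted log2 effect 2.0 on half of
  each planted pathway's members, log2 noise sd 0.5, 10% of genes drawn
  below the RPKM-2 floor to exercise filtering.  Effect magnitude and
  noise are invented (the source states none); they give per-gene power
  ≈ 1 at effect/sd = 4 with n = 4, which makes recovery tests sharp
  rather than flaky;
* screen: sensitivity 0.5 over planted essential genes and genome-wide
  false-positive rate 0.03 — on the default universe this yields a hit
  list of several hundred to ~1,000 genes with roughly 40% false
  positives, matching the reported screen scale and error rate;
* `disjointness` d controls signal separation: with probability d a
  planted gene follows one global role (responsive XOR essential, shared
  across pathways), otherwise roles are drawn independently per pathway.
  At d = 1 (the default, mirroring the observed biology) the DEG and hit
  lists share planted genes only through noise, so their overlap sits at
  chance while fusion still concentrates both halves of each planted
  pathway.

What a green synthetic test establishes: the pipeline's statistics and
bookkeeping behave as specified under a lognormal, homoscedastic,
uncorrelated-gene model.  What it does not establish: robustness to
array probe effects, RNA-seq count overdispersion, correlated co-
expression modules, or batch structure — none of which the generator
emulates.

## Numerical choices

* Hypergeometric tails use `stats::phyper`; tests verify them against an
  independent sequential-draw dynamic program for every table with
  N ≤ 25 and against exhaustive draw enumeration for small N.
* BH-FDR is implemented directly (step-up with `cummin`) and verified
  against the literal definition and `stats::p.adjust`.
* Enrichment rows are sorted by p ascending with lexicographic term-id
  tie-break; all writers emit UTF-8/LF; reports carry no timestamps, so
  identical inputs give byte-identical outputs.
* Landscape conservation tolerance is 1e-6 relative; symmetry holds to
  1e-9 on even grids.
* The pipeline config is a JSON file (no YAML parser is available in
  the target environment); CLI flags override config fields and the
  effective config is echoed into the output directory.

## Known limitations

* The comparison-table construction does not reproduce the published
  p = 0.04 for the three-gene glutathione-biosynthesis pathway
  (it computes 0.20); the cell is excluded from acceptance and flagged,
  not chased.
* Published pathway-overlap significance values (p = 0.007 / 0.004)
  lack a stated universe of testable pathways and are not recomputed;
  only the overlap fractions are.
* Replicating the exact published pathway term sets would require the
  proprietary IPA/DAVID knowledgebases; the package only promises the
  statistics given user-supplied GMT collections.
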