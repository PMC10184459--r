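---
title: "Genome-skimming SNP phylogenomics and Mk ancestral states: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-skimming SNP phylogenomics and Mk ancestral states: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloskim)
```

phyloskim implements a reference-based genome-skimming SNP workflow —
ortholog selection, a genotype filter cascade, missing-data-gradient
supermatrix assembly, tree post-processing — together with
maximum-likelihood ancestral state reconstruction of discrete
morphological characters under Mk models. This vignette explains the
models and procedures, the parameters that matter, the synthetic-data
generator that stands in for real sequencing data, and the design choices
made where the methodology was genuinely open.

## The workflow and its assumptions

The workflow's input boundary is a *genotype table*: diploid calls at
variable sites on single-copy gene CDS regions, each call carrying a read
depth and a phred-like quality. Everything upstream (read QC, mapping,
pileup calling) is out of scope; the table's structure is what the
synthetic generator emulates. Samples of unknown ploidy are treated as
diploids throughout — a standard simplification for low-coverage data
whose main cost is allele dropout in polyploids, not topological bias.

### Ortholog selection

One-to-one orthologs between two CDS sets are selected by reciprocal best
hit (RBH) on tabular similarity searches. A pair $(a, b)$ is accepted when
$b$ is $a$'s best surviving hit in one direction and $a$ is $b$'s best in
the other, after discarding hits with e-value $\ge 10^{-10}$ (the
threshold is strict). "Best" is the lowest e-value; because tabular
outputs routinely contain ties and multiple HSPs, ties break by higher
bitscore and then lexicographically smaller subject id, and multiple HSPs
per (query, subject) pair collapse to their minimum-e-value row before
bests are determined. These conventions make the operation deterministic
and symmetric; the output is one-to-one by construction.

### The filter cascade

Three stages run in a fixed order, each only ever discarding information:

1. **Coverage window and quality.** For each sample, the median depth of
   its calls is computed over loci present in *strictly more than* half
   the samples (poorly occupied loci would bias the median downward); a
   median over an even count is the mean of the two middle values. A call
   survives only if its depth lies within $[0.5\,m, 2\,m]$ of its own
   sample's median $m$ — both boundaries inclusive, since the rule is
   stated as a range without strictness — and its quality is at least 20.
   The upper bound removes reads from repetitive or organellar regions;
   the lower bound removes barely covered calls. Failing calls become
   absent; loci losing all calls are dropped.
2. **Biallelic restriction.** Only loci with exactly two alleles observed
   across surviving calls are kept. Loci monomorphic after stage 1 are no
   longer SNPs and are removed for the same reason.
3. **Minor-allele sharing.** SNPs whose minor allele was observed fewer
   than three times are discarded as likely products of sequencing error
   at low coverage. The count is an allele-*copy* count (heterozygote = 1,
   homozygote = 2), the semantics of the standard minor-allele-count
   filter in VCF tooling. The alternative reading — counting carrier
   samples — was considered and rejected: it removes every
   two-sample clade (cherry) signal from the data outright, since a
   cherry mutation has exactly two carriers, and therefore makes
   topological recovery from the filtered matrix impossible at small
   sample sizes. Under copy counting a cherry contributes four copies and
   survives, while genuine singletons (one or two copies) are still
   removed.

Each stage appends a row to an audit trail (loci in/out, calls removed),
which `plot_filter_audit()` displays and the pipeline writes as TSV.

### Missing-data gradients and supermatrices

A SNP's missing fraction is its absent calls divided by the *total* number
of samples. The gradient scan counts, for each threshold
$m \in \{10, 20, \dots, 90\}$ percent, the SNPs with missing fraction
strictly below $m/100$ — so "a maximum of $m\,\%$ missing data" admits
loci below the threshold, and the nine counts are nested and
non-decreasing. The supermatrix at threshold $m$ concatenates exactly
those SNPs, one column each, ordered by gene then position: homozygous
calls become the base, heterozygotes the two-base IUPAC code (information
is kept rather than collapsed to a major allele, since the upstream
consensus caller's behaviour is not specifiable), absent calls `N`. By
construction the supermatrix width equals the gradient count at the same
threshold, which the pipeline asserts as an internal cross-check.

Per-gene matrices are emitted for genes with at least 150 retained
columns whose calls cover at least half the samples (both bounds
inclusive). "Length" here means retained alignment columns, the only
available notion of length for SNP data. A parsimony-informative column
has at least two non-`N` states each present in at least two samples;
ambiguity codes other than `N` count as their own state, a deliberate
conservative choice that avoids crediting a heterozygote to either
homozygote class.

### Trees

Branches with bootstrap support at or below 20 are contracted into
polytomies (the threshold is inclusive, as in the `nw_ed`-style
convention); tip edges and retained internal edges keep their lengths,
the contracted edge's length is discarded as a purely topological
operation. Supports are read from internal-node labels; labels that all
lie in $[0, 1]$ are auto-scaled to $[0, 100]$ with a warning, since both
dialects occur in the wild.

Topologies are compared by the unweighted Robinson–Foulds distance on
non-trivial unrooted bipartitions; rooted inputs are compared as unrooted,
matching how trees from differently rooting programs are compared in
practice, and raw (not normalized) counts are reported. A representative
topology among near-equivalent analyses is the one minimizing the summed
RF distance to all others, ties broken by lowest index.

Full ML tree search is out of scope; at desk scale the package builds
neighbour-joining trees from p-distances with pairwise deletion (columns
where either sequence is `N` are skipped per pair; a pair sharing no
called column is a hard error rather than a silent zero). NJ is
consistent for additive distances, and clade-indicator SNP columns yield
an additive split metric, which is the basis of the topology-recovery
tests.

## Mk ancestral state reconstruction

Discrete characters evolve under a $k$-state continuous-time Markov
model with rate matrix $Q$: equal rates (ER, all off-diagonals $q$) by
default, all-rates-different (ARD) behind a flag. ER is the default
because it is the common default of the R toolchain used for this kind of
reconstruction and the character matrices involved are small; the root
prior is uniform, exposed as a parameter. Transition kernels are
$P(t) = e^{Qt}$; for ER the closed form
$P_{ii}(t) = \tfrac1k + (1 - \tfrac1k)e^{-kqt}$,
$P_{ij}(t) = \tfrac1k(1 - e^{-kqt})$ is used, for ARD a
scaling-and-squaring matrix exponential implemented in-package (the
truncated Taylor series on $Q t / 2^s$ with $\|Qt\|_1/2^s \le 0.25$,
squared back $s$ times; accurate to ~$10^{-12}$ at these matrix sizes).
An eigendecomposition-based shortcut was deliberately not used for ARD:
general rate matrices can be defective, and the scaling-and-squaring
route is uniformly robust.

Likelihoods use Felsenstein pruning in post-order with per-node
rescaling, so underflow cannot occur on large trees. Unknown tips enter
as all-ones partial likelihoods; polymorphic tips (e.g. "panicle, rarely
raceme") as indicator vectors — how to code real polymorphic taxa is left
to the user. Polytomies are handled natively by the recursion, with no
arbitrary resolution. Marginal ancestral states use the standard up–down
algorithm: the posterior at a node combines the conditional likelihood of
the subtree below with the information above under the root prior, and
each node's vector is normalized to sum to one.

The ER rate is fitted by bounded one-dimensional optimisation of the log
rate over $[10^{-8}, 10^3]$ (tolerance $10^{-8}$); ARD by L-BFGS-B on log
rates started from $1/\bar d$ with $\bar d$ the mean root-to-tip depth.
Only the product $q \cdot t$ is identified, so doubling all branch
lengths halves the estimate — asserted numerically in the tests. When all
observed tips share one state the likelihood increases monotonically as
$q \to 0$; the estimate is reported at the lower bound with an explicit
boundary warning rather than a spurious interior value.

Leaf size is discretised by the field's rule: area approximated as
length $\times$ width $\times$ 3/4 (mm²), with classes small
($< 225$), medium ($[225, 2025)$) and large ($\ge 2025$); the lower
boundary of each class is inclusive, so a 30 mm × 10 mm leaf (area
exactly 225) is medium. The package ships the six-character scheme used
for *Artemisia* (pollen type, synflorescence type, capitulum type, life
form, basal leaf morphology, basal leaf size) as a validated alphabet for
character matrices; characters are reconstructed independently, with no
correlation model.

## The synthetic-data generator

The generator produces data with the statistical structure the analysis
assumes, not a sequencing simulator (no reads, no mapping error; those
belong upstream of the package's input boundary).

* **Trees** are pure-birth (Yule) with branch lengths treated as
  expected-substitution units — sufficient because the analysis never
  conditions on the true generating process.
* **SNPs** arise infinite-sites style: each site mutates once on a
  uniformly chosen edge; tips below the edge carry the alternate allele,
  as heterozygotes when the mutation falls on their own terminal edge (a
  recent mutation) and alternate homozygotes otherwise.
* **Depth** is negative-binomial around a per-sample lognormal expected
  depth (dispersion parameter `depth_dispersion`, size $= 1/$dispersion),
  truncated at 1. The default expected depth of 4 reflects the low
  nuclear coverage genome skimming actually yields, which is what makes
  the median-relative coverage window consequential.
* **Quality** is Gaussian (default mean 35, sd 10), clipped to $[1, 99]$,
  putting roughly 7 % of calls below the quality-20 cut.
* **Missingness** is Bernoulli per call with logit-normal per-sample
  (sd 1.0) and per-gene (sd 0.8) effects; the intercept is calibrated
  numerically (by root finding on the realized effect grid) so the
  marginal missing rate equals `missing_rate` exactly. The default rate
  of 0.365 and the sample-effect spread reproduce the regime reported
  for real genome-skimming data sets, where per-sample missing rates
  span roughly 10–90 % around a mean near 37 %.

With these defaults the *post-filter* per-locus missingness sits almost
entirely above 40 %, because the coverage window and quality cut convert
low-depth and low-quality calls into additional absence. That reproduces
the qualitative gradient behaviour observed on real skimming data — no
SNPs retained at thresholds of 10–40 %, counts rising steeply through
50–90 % — and the acceptance tests assert exactly that shape. The
generator does *not* emulate reference bias, paralogy leakage,
mapping-quality covariance between neighbouring sites, or
allele-dropout structure in polyploids; passing tests therefore validate
the pipeline's logic and statistics, not robustness to those real-data
pathologies.

All generators are deterministic under a seed; the pipeline derives
per-stage sub-seeds from one root seed by a fixed affine rule, so stages
can be re-run independently yet reproducibly.

## Problem sizes and experiment regimes

Two synthetic regimes are used deliberately:

* a **harsh skimming regime** (depth 4, `missing_rate` 0.365,
  heterogeneity sds 1.0/0.8) for the gradient-shape experiment, run at
  60 samples × 2400 SNPs — the regime where the missing-data behaviour
  of real data lives;
* a **well-covered regime** (depth 20, `missing_rate` 0.1, dispersion
  0.25, heterogeneity sds 0.5) for the topology-recovery experiment at
  10 samples × 2000 SNPs — a consistency check of the filter + NJ
  estimator, which asks whether the true topology is recovered when the
  data are informative, not whether NJ survives starvation. At 10
  samples the sharing filter removes all singleton sites by design, so
  the harsh regime would leave too few columns to test the estimator
  rather than the regime.

Mk parameter recovery uses 200 replicate three-state characters on a
100-tip tree at $q = 0.5$ (tree depth $\approx 5$, so $q\,t$ is order
one — the identifiable regime); the median estimate is required to land
in $[0.4, 0.6]$. Exhaustive-enumeration oracles check the pruning
likelihood and marginals on *all* rooted binary topologies of 4–6 tips
($15 + 105 + 945$) for $k = 2\ldots4$, against an independent
matrix-exponential; these sizes keep the whole suite near one minute.

## Numerical choices and degenerate inputs

* Missing fractions are computed as integer ratios so strict threshold
  comparisons are exact at boundaries like $1/10$ vs $10/100$.
* Medians over even counts are the mean of the two middle values (the
  upstream convention is unknowable; this is R's and the common one).
* A sample with no qualifying calls for the median is a typed error, not
  a zero — a zero median would make the coverage window degenerate.
* An empty supermatrix is a typed warning plus an explicit empty object,
  never silent success.
* Pairwise deletion with zero shared columns is a typed error naming the
  offending pair.
* Marginal posteriors are normalized per node; vectors sum to 1 within
  $10^{-9}$ and the root marginal is invariant to re-rooting under the
  reversible ER model (asserted in the tests).
* RBH, NJ, collapsing and representative selection are all deterministic,
  with documented tie-breaks.

## Known limitations

SNP-only supermatrices carry ascertainment bias (no invariant sites); no
correction is applied, matching the workflow being implemented. The NJ
builder is a desk-scale stand-in, not a substitute for ML tree search
with model selection or coalescent methods on gene trees. Branch-support
estimation, dating, correlated-character models and biogeographic range
reconstruction are out of scope. The six-character scheme is fixed to the
*Artemisia* study system; other schemes can be supplied as a custom
`scheme` tibble.
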