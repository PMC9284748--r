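---
title: "Methods: codon usage bias, Ka/Ks and branch/site selection tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias, Ka/Ks and branch/site selection tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonevol)
```

`codonevol` compares the molecular evolution of coding-sequence gene
families between a *foreground* species group (e.g. species carrying a
trait of interest, such as sorbitol as the major photosynthetic
transport sugar) and a *background* group.  It covers four layers:
codon-usage bias, pairwise Ka/Ks, likelihood-based branch and site
models of the nonsynonymous/synonymous rate ratio omega, and group-level
summaries — plus a simulator that generates every input with known
ground truth.  This vignette describes the models, the tunable
parameters, the numerical choices, and what the validation suite does
and does not demonstrate.

## Codon usage bias

**Effective number of codons (Nc).**  For every synonymous codon family
the codon homozygosity is estimated from the within-family frequencies
$\hat p_i$ as either the plug-in $\hat S = \sum_i \hat p_i^2$ or
Wright's small-sample correction
$\hat F = (n\hat S - 1)/(n - 1)$, where $n$ is the family's usage in
the gene.  Averaging $\hat F$ over families of equal degeneracy $k$
gives $\bar F_k$, and

$$N_c = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} + \frac{5}{\bar F_4}
      + \frac{3}{\bar F_6},$$

with the three six-fold families (Leu, Ser, Arg) kept whole.  Nc is 20
for a gene that uses a single codon per amino acid and 61 for a gene
using all synonymous codons equally; the upper limit is exact only
under the plug-in estimator, which is why both are exposed
(`homozygosity = "corrected"` is the default, the plug-in is a flag).
When the single 3-fold family (Ile) is unobserved, $\bar F_3$ is
imputed as $(\bar F_2 + \bar F_4)/2$; if any other class is entirely
unobserved its term is dropped and the result rescaled by the
represented family count (both events are logged).  Nc is capped at 61;
values below 20 can occur for the corrected estimator on short genes
and are reported uncapped, with genes under 50 codons flagged.

**Optimal codons and Fop.**  Following the classic correlation
approach, each codon's within-family relative frequency is
Spearman-correlated with Nc across genes; the family's optimal codon is
the codon with the strongest *negative* correlation among those
significant at $0.05/n$ ($n$ = family size; a Bonferroni-style rule).
Genes shorter than 50 codons are removed, and a gene contributes a
family's frequencies only when it uses the family at least 10 times.
We read that usage filter *per gene* because the per-gene frequency is
the correlated quantity; a dataset-wide reading is available via
`family_filter = "dataset"`.  Ties use midranks; exact p-values are
used below 10 genes and the large-sample approximation otherwise.
Fop is the fraction of optimal-codon occurrences among codons of
families that *have* a defined optimal codon (the classic convention;
the literal all-codon denominator is a flag, since the defining ratio
does not disambiguate).  One-fold families (Met, Trp) never
participate.

A caveat worth knowing: with 18 multi-codon families each tested at
$0.05/n$, a fully null gene set still yields a false optimal codon in
roughly one run in three — and more when gene lengths vary, because
length jointly inflates the noise of Nc and of the frequencies.  The
detector inherits this from the published decision rule; treat isolated
detections without a frequency gradient with suspicion.

## Pairwise Ka/Ks

Two counting estimators are provided on pre-aligned, gap-masked codon
pairs.

**NG86.**  Synonymous sites per codon are the per-position fractions of
non-stop single-nucleotide neighbors that are synonymous (summed over
the three positions, averaged over the two sequences); differences at
multi-hit codons are averaged over all minimal mutational pathways with
equal weights, excluding pathways through stop codons (if every pathway
is blocked, the full set is used); proportions are corrected with
Jukes-Cantor, $d = -\tfrac34\ln(1 - \tfrac43 p)$.  Saturated
proportions ($p \ge 3/4$) are flagged rather than returned as numbers,
and `ks = 0` yields a flagged undefined ratio, never an infinity.

**YN-style.**  A kappa- and frequency-aware variant in the spirit of
Yang and Nielsen's approximate method: kappa is estimated from
fourfold-degenerate and nondegenerate positions via Kimura's
two-parameter model; site counting weights each neighbor by
$\kappa^{[\mathrm{ts}]}\,\pi_{\text{target codon}}$ with F3x4
frequencies estimated from the pair; pathways are weighted by the
frequencies of their intermediate codons; and synonymous/nonsynonymous
differences, split into transitions and transversions, are corrected
with the two-parameter formula.  With $\kappa = 1$ and uniform
frequencies the site counts reduce exactly to NG86 — a limit the test
suite asserts.  Because the kappa estimate is closed-form, the site
count fixed-point loop converges immediately; the loop and an NG86
fallback are retained defensively.  This is the approximate counting
method, not the full maximum-likelihood pairwise model; the likelihood
engine below provides the ML machinery where it matters (branch and
site tests).

## The codon likelihood engine

The substitution model is MG94xHKY over the 61 sense codons:
$q_{ij} \propto \pi\text{-factor} \times \kappa^{[\mathrm{transition}]}
\times \omega^{[\mathrm{nonsynonymous}]}$ for single-nucleotide
changes, zero otherwise, scaled to one expected substitution per codon
per unit time.  When the equilibrium frequencies are supplied as a
4 x 3 position-nucleotide matrix (the F3x4 default, estimated from the
alignment) the pi-factor is the target *nucleotide* frequency (MG94);
when an arbitrary 61-vector is supplied the pi-factor is the target
*codon* frequency.  The reason for the split: the target-nucleotide
factor is reversible with stationary distribution equal to the
normalized F3x4 product measure, but cannot realize an arbitrary codon
simplex, whereas the target-codon factor is reversible for any
frequency vector.  Both choices therefore keep detailed balance — which
the package exploits by diagonalizing the generator in the
pi-symmetrized basis (a real spectrum is guaranteed), giving fast, exact
matrix exponentials with no scaling-and-squaring loop.

Likelihoods are computed by Felsenstein pruning over site patterns with
per-pattern rescaling, implemented in C++ (RcppArmadillo), with gap
codons entering as missing data (partial likelihood one over all sense
codons).  The likelihood is evaluated at the tree's root under
stationarity; by reversibility it is invariant to root placement, which
the tests assert by re-rooting.  An exhaustive summation over all
internal-node codon assignments serves as the oracle on small trees.

## Branch models, site models, tests

Branch models assign one omega per *branch class* carried on the tree
(`#k` Newick suffix labels; class 0 is the background).  The one-ratio
model shares a single omega tree-wide; the two-ratio model frees the
foreground; multiple-ratio models free each labeled clade.  Fits
maximize over all class omegas, a shared kappa, and every branch length
(input lengths are initial values), using L-BFGS-B on log-scale
parameters with three seeded restarts.  Branch-length gradients are
analytic (an up/down pruning pass); kappa/omega derivatives use central
differences that rebuild only the affected rate matrix.  Multi-class
fits are initialized from the one-ratio optimum, which both speeds
convergence and guarantees the nesting inequality
$\ln L_1 \ge \ln L_0$ up to optimizer tolerance.  Bounds are
$\omega \in [10^{-4}, 20]$, $\kappa \in [0.1, 20]$; estimates at a
bound are flagged.

The discrete site-class model (M3) mixes `k_classes` omega classes with
softmax-parameterized proportions; the extra-class variant is simply
`k_classes = 4`.  (The published analysis used a lineage-switching
extension of the site model; we implement the standard static M3 — a
deliberate simplification, since switching models are a different
machine.)  Site posteriors follow by Bayes' rule (naive empirical
Bayes), and positive sites are the 1-based codon columns whose
posterior for omega > 1 classes exceeds 0.5 (configurable; the
published site lists state no cutoff).  Mixture branch-length gradients
use Fisher's identity (posterior-weighted per-class gradients).

Likelihood ratio tests compare nested fits with
$2\Delta\ln L \sim \chi^2_{df}$, df from parameter counting (two-ratio
vs one-ratio: 1; three-ratio: 2; four-ratio: 3).  Boundary-case mixture
corrections are deliberately not applied; for class-count tests the
chi-square reference is approximate and the p-values should be read
accordingly.  Small negative statistics from optimizer tolerance are
clamped to zero.

A property learned from the validation runs and worth stating: with few
taxa the M3 likelihood surface has a flat ridge trading the positive
class's proportion against its omega, and the MLE may merge weakly
separated purifying classes (it can exceed the likelihood of the
generating truth).  Site-class resolution is driven by taxon sampling
more than by alignment length, which is why the site-model validation
studies use 12 taxa, and deeper trees for positive-site recovery.

## The simulator

`simulate_codon_alignment()` draws root codons from the stationary
distribution and evolves each branch by sampling child states from the
rows of $P(t) = e^{Qt}$ under the branch class's omega (or per-site
omegas when site classes are given) — exact under the model, since only
endpoint states are consumed.  `simulate_biased_gene_set()` plants the
statistical structure the optimal-codon procedure assumes: each gene
carries a bias level $b \in [0,1]$, and within every designated family
the optimal codon's probability rises linearly from the uniform $1/k$
at $b = 0$ to 0.9 at $b = 1$ while other families stay uniform.
Drawing on family simplices guarantees stop-free coding sequences by
construction.  Defaults: 200 genes, lengths uniform on 200-500 codons
(comfortably above the 50-codon filter and giving typical family usages
well past the 10-count filter), all 18 multi-codon families designated
with their alphabetically first codon.  `make_toy_study()` emits a
miniature foreground/background study — 3 families, 7 pseudo-species
(4 foreground), 300 codons per family (the order of the real gene
families emulated), one family with foreground omega 0.5 against
background 0.15, kappa 2 — sized so the full pipeline runs in minutes.

What the simulations do *not* emulate: real data violate the generator
in known ways — selection on codon usage interacts with GC-biased gene
conversion, omega varies continuously rather than in discrete classes,
alignments contain errors and the trees are estimated, and codon
frequencies drift across lineages.  Passing the recovery tests
therefore shows the estimators are correct *under their own model*, not
that the model is adequate for any particular genome.

## Validation study designs

The test suite fixes these problem sizes (all seeds hard-coded):
LRT null calibration uses 200 one-ratio replicates of 150 codons on an
8-taxon tree with a labeled foreground clade, asserting a rejection
rate at the 5% level inside [0.01, 0.10]; two-ratio recovery uses 20
replicates of 300 codons (background 0.15, foreground 0.5) asserting
ordering and 50%-relative accuracy; the NG86 estimator is checked
against an exhaustive-pathway oracle on 100,000 random pairs (the
Jukes-Cantor correction is compared away from its pole at $p = 3/4$,
where roundoff in otherwise-matching counts is amplified without
bound); pruning is checked against brute-force state summation on 4-
and 5-tip toys; neutral (omega = 1) simulations are required to give a
mean NG86 ratio within 10% of one over 100 replicates of 1,000 codons.
The planted-gradient detector must recover at least 90% of designated
optimal codons; the companion all-null assertion (no detections in 90%
of seeds) is retained verbatim even though, as discussed above, the
published threshold rule cannot satisfy it — the test documents that
property rather than hiding it.

## Known limitations

Plain Nc only (no background-composition-corrected Nc-prime); no CAI,
tAI or RSCU; no gamma rate variation, branch-site Model A, Bayes
empirical Bayes, or covarion/switching site models; no gamma-corrected
or model-averaged Ka/Ks; pairwise alignment is out of scope (inputs are
pre-aligned); duplication-type classification and expression analysis
are out of scope.  Frequency parameters (F3x4) are estimated once and
held fixed, not profiled, and are not counted as free parameters in the
LRTs (they cancel between nested fits).
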