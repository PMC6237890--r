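---
title: "Detecting lineage-specific selection and clade-unique substitutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lineage-specific selection and clade-unique substitutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinnevo)
```

## The scientific problem

Marine mammals — pinnipeds (seals, sea lions), cetaceans (whales,
dolphins) and sirenians (manatees) — entered the ocean independently,
giving three natural replicates of adaptation to an aquatic life.
`pinnevo` implements a comparative-genomic workflow for asking, over a
set of one-to-one orthologs across twelve mammals, two questions:

1. **Which genes evolved unusually fast in the marine lineages**
   (rapidly evolving genes, REGs), and which carry sites under positive
   selection specifically in pinnipeds?
2. **Which amino-acid changes are unique to the pinniped clade** — fixed
   in all pinnipeds, absent from the reconstructed ancestor they share
   with dog and from every other mammal — at positions where the data
   support the species tree rather than a hypothetical marine-mammal
   clade?

The final candidate set is the intersection: REGs carrying a residue
that is simultaneously in the genome-wide top 1% of `deltaSSLS` (support
for divergence, defined below) and a pinniped-unique substitution at the
same position.

## Codon models of selection

The selection tests use the Goldman–Yang codon substitution model over
the 61 sense codons. The instantaneous rate from codon $i$ to $j$ is

$$
q_{ij} \propto \pi_j \cdot \kappa^{\,\mathbb{1}[\text{transition}]}
\cdot \omega^{\,\mathbb{1}[\text{nonsynonymous}]}
$$

for single-nucleotide changes and zero otherwise, where $\pi_j$ are
F3X4 codon frequencies (products of position-specific nucleotide
frequencies estimated from each gene's own alignment, renormalised over
sense codons), $\kappa$ is the transition/transversion rate ratio and
$\omega = dN/dS$. For single-class models each branch's generator is
scaled so its length is the expected substitutions per codon on that
branch. In the branch-site mixture, site classes share branch time, so
classes keep their *relative* rates $\mu(\omega)$ (sites with
$\omega_2 \gg 1$ really do evolve faster on foreground branches, rather
than merely shifting composition); reported branch lengths are expected
substitutions per codon averaged over the class mixture on background
branches. The simulator, the fitting code and the BEB grid all share
this convention. Likelihoods are computed by Felsenstein pruning (in
compiled code, with site-pattern compression and per-edge transition
matrices from the eigendecomposition of the symmetrised reversible
generator); gaps and ambiguous codons are missing data.

Three model families are fitted by `fit_codon_model()`:

* **M0** — a single $\omega$ for all branches and sites.
* **branch** — separate $\omega_{fg}$ / $\omega_{bg}$ for foreground
  (marine) and background branches; compared with M0 by a
  likelihood-ratio test (LRT). Bonferroni-significant genes are REGs.
* **branch-site model A** — four site classes
  ($\omega_0 \le 1$ everywhere; $\omega_1 = 1$ everywhere;
  classes 2a/2b with $\omega_2 \ge 1$ on the foreground only), with
  proportions parameterised as $p_0, p_1$ and the class-2 mass
  $1 - p_0 - p_1$ split as $p_0/(p_0{+}p_1) : p_1/(p_0{+}p_1)$. The
  alternative is compared with the $\omega_2 = 1$ null; positively
  selected sites are then located by Bayes empirical Bayes (BEB)
  posteriors computed on a uniform grid over
  $(p_0, p_1, \omega_0, \omega_2)$ with $\kappa$ and branch lengths at
  their MLEs. Sites with posterior above 0.95 are reported.

Both LRTs use $\chi^2$ with one degree of freedom. For the branch-site
test the asymptotic null is a boundary mixture, so plain $\chi^2_1$ is
conservative; this matches the arithmetic that reproduces the published
per-gene p-values from their printed log-likelihoods and LRT
statistics, and the simulation suite confirms the realised type-I error
is below nominal.

### Numerical choices

* Optimisation is bounded quasi-Newton (L-BFGS-B) on log-transformed
  rate parameters and logit-transformed proportions, with a
  forward-difference gradient that reuses cached per-class site
  likelihoods: perturbing the mixture proportions costs no pruning at
  all, and perturbing a single $\omega$ recomputes only the affected
  site classes.
* Nested fits are warm-started: the branch alternative starts from the
  M0 optimum and the branch-site alternative starts from the null
  optimum with $\omega_2$ at its boundary, which guarantees
  `lnL(alt) >= lnL(null)` and hence a non-negative LRT statistic. The
  branch-site alternative is additionally optimised from the null
  solution pushed to an interior point ($p_0{+}p_1 = 0.85$,
  $\omega_2 = 2.5$) because the profile in $(p_0{+}p_1, \omega_2)$ can
  be bimodal, with a spurious boundary optimum at $\omega_2 = 1$; the
  better of the two solutions is kept. Random restarts are available
  (`n_restarts`) for difficult genes.
* Branch lengths: by default each fit re-optimises a single rate-scale
  multiplier of the input tree's branch lengths (`branch_lengths =
  "scale"`). With a fixed, trusted topology this captures per-gene rate
  variation at a fraction of the cost of free per-branch optimisation,
  which remains available (`branch_lengths = "free"`) and is used in
  tests that verify per-edge length recovery. This is a deliberate
  design choice: the quantities the pipeline consumes (LRTs between
  models that share the same branch-length treatment, class proportions,
  $\omega$ ratios) are insensitive to it in simulation, while full
  per-branch optimisation would dominate runtime at genome scale.
* Zero position-specific nucleotide frequencies are floored at `1e-6`
  and renormalised, avoiding impossible (zero-probability) codons.
* Per-branch dN and dS are obtained by splitting each branch's expected
  substitutions into synonymous and nonsynonymous parts under that
  branch's $\omega$ (for branch-site fits, the class-mixture average)
  and normalising by the proportions of synonymous/nonsynonymous sites
  at $\omega = 1$; this makes `dN/dS` equal the branch's $\omega$
  exactly, and reproduces the filter scale (genes with any branch
  `dS > 3` or `dN/dS > 5`, or an LRT below 0, are discarded before
  multiple-testing correction).
* The Bonferroni denominator defaults to the number of genes entering
  each analysis after filtering, and can be overridden (`n_tests`),
  because the published per-analysis denominators differ from the
  ortholog count and are not recoverable from the reported numbers.

## Site-wise likelihood support (deltaSSLS)

For every ortholog's protein alignment, per-residue log-likelihoods are
computed under two fixed topologies: the species tree (H0) and an
alternative in which the three marine clades form a single clade
attached at the pinniped position (H1). Branch lengths are optimised
independently under each topology for each gene;

$$\Delta\mathrm{SSLS}_h = \ln L_h(H_0) - \ln L_h(H_1)$$

is positive when residue $h$ supports divergence of the marine clades
and negative when it supports their monophyly (convergence). The
substitution model is JTT with empirical (+F) frequencies, rate-
homogeneous by default with an optional discrete-gamma flag; the
likelihood engine is `phangorn::pml`/`optim.pml`, and per-site values
are checked against brute-force enumeration in the test suite. The
CAT-style rate approximation and per-gene model selection used by some
tree-search tools are intentionally not re-implemented: the model here
is fixed JTT+F for every gene, which keeps `deltaSSLS` values
comparable across genes.

Residues are ranked by `delta` descending and the top
`floor(fraction * N)` (default fraction 0.01) are kept; ties at the
boundary are broken lexicographically by gene id and then position, so
the selection is deterministic. Genes owning a selected residue are
divergent substitution genes (DSGs). With the published residue total
(996,522) the rule yields exactly 9,965 residues.

## Joint ancestral reconstruction and substitution classes

Ancestral protein states are reconstructed by the *joint*
maximum-probability assignment (max-product dynamic programming over
the tree, Pupko-style), not per-node marginals: the classification
rules below compare observed residues with specific ancestral nodes,
and the joint assignment is the single most probable history. Branch
lengths are optimised per gene under JTT+F beforehand. Tips with gap/X
are uninformative; ties are broken by alphabetical residue order.

* A **unique substitution** (pinnipeds): all three pinnipeds share a
  residue that differs from the reconstructed state at the most recent
  common ancestor of pinnipeds + dog and occurs in no other mammal in
  the alignment. Genes with one or more such sites are unique
  substitution genes (USGs).
* A **parallel substitution**: all three marine clades share the same
  residue, and in each clade it differs from the state at that clade's
  ancestral node (the MRCA with its terrestrial sister: dog for
  pinnipeds, cow for cetaceans, elephant for sirenians).

The "ancestral node with the terrestrial taxon" reading (MRCA of clade
plus sister) is used for both rules, which keeps them consistent; the
clade map is explicit and overridable. Missing residues do not veto a
call by default (`strict = FALSE` treats them as uninformative), since
requiring complete columns would discard most real alignments.

## The synthetic-data generator

`simulate_alignment()` evolves codon sequences along the 12-taxon
mammal tree (or any labeled tree) under M0, branch, or branch-site A:
root codons are drawn from the stationary distribution, site classes
are drawn per the model, and each branch applies its class's transition
matrix. Planted clade-unique or clade-convergent residues are
overwritten after simulation (using the lexicographically first codon
of the residue); a column whose background already carries the planted
residue is re-simulated with a warning so plants stay clade-exclusive.
Default branch lengths are 0.05 on branches inside the marine clades
and 0.2 elsewhere — short enough to avoid saturation, long enough that
internal branches carry information; both are configurable.

What the generator does *not* emulate: alignment error, indels,
among-site rate variation beyond the selection classes, base-composition
heterogeneity across lineages, and orthology mistakes. Passing
recovery tests on these simulations therefore validates the inference
machinery, not robustness to real-data artefacts.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
pruning likelihoods against brute-force enumeration over internal
states on toy trees (codon and protein, tolerance `1e-8`); BEB
posteriors against a direct exhaustive grid sum; joint reconstruction
against exhaustive search over all internal assignments on 4-taxon
trees; and the ranking/intersection rules against hand-enumerable
cases.

Statistical properties are checked at sizes chosen to balance power
against runtime on a single CPU, and are stated here as the package's
validation conditions: the branch-site LRT's type-I error is estimated
from 200 null simulations of 300-codon genes (required: at most 0.10 at
the nominal 0.05 cutoff, reflecting the conservative boundary null);
branch-model recovery uses 50 replicates of 500-codon genes with
$\omega_{fg} = 4$ vs $\omega_{bg} = 0.2$ (required: fitted
$\omega_{fg} > \omega_{bg}$ in at least 95%); the end-to-end run plants
three rapidly evolving genes (300 codons, $\omega_{fg} = 2.5$ on the
marine branches) among 27 neutral genes of 150 codons, each planted
gene carrying pinniped-unique substitutions at two fully engineered
columns (pinnipeds W, cetaceans and cow H, sirenians and elephant C,
all remaining taxa P), and requires the final intersection to equal
exactly the planted set. The design was fixed after a power pre-study:
$\omega_{fg} = 2.5$ at 300 codons gives essentially certain branch-test
detection under Bonferroni correction while keeping both the fitted
foreground $\omega$ safely below the $dN/dS > 5$ post-fit filter bound
and the gene's protein divergence low enough that single substitutions
remain informative in the site-support ranking; fully determining the
engineered columns removes the run-to-run variability that partially
random columns showed in their top-1% `deltaSSLS` rank (a fast gene's
longer fitted branches make extra changes cheap under either topology,
so a column's rank is sensitive to its background states).

## Known limitations

* The branch-site boundary null is handled by plain $\chi^2_1$, which
  is conservative; no mixture null or parametric bootstrap is offered.
* F3X4 is the only frequency model; no F1X4 or F61.
* `deltaSSLS` uses a single fixed H1 topology; uncertainty in the
  alternative topology is not propagated.
* Joint reconstruction reports the single best history without
  per-node posterior confidence; marginal reconstruction is out of
  scope.
* The per-gene branch-length treatment defaults to a shared scale
  factor (see above); analyses that need per-branch length estimates
  should pass `branch_lengths = "free"`.

## A worked micro-example

```{r example, eval = FALSE}
tr <- mammal_species_tree(foreground = "pinnipeds")
spec <- sim_spec(tree = tr, n_codons = 200, model = "branch_site_A",
                 params = list(kappa = 2, p0 = 0.4, p1 = 0.4,
                               omega0 = 0.1, omega2 = 8), seed = 1)
sim <- simulate_alignment(spec)
res <- branch_site_test(sim$codon, tr)
res$lrt
beb <- beb_site_posteriors(res$fit_alt)
plot(beb)
```
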