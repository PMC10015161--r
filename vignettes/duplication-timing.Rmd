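---
title: "Dating gene duplications by exhaustive constrained topology testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating gene duplications by exhaustive constrained topology testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topotest)
```

## The question and the method

When a gene family contains two paralogs in each of two major lineages
(here: vitellogenin-like genes VTG1 and VTG2 in bony and cartilaginous
vertebrates), two evolutionary histories compete. Either each lineage
duplicated its gene independently *after* the lineages split — then the
two paralogs of each lineage are each other's closest relatives — or one
duplication happened *before* the split, and each paralog group contains
both lineages. A gene tree can in principle discriminate between the two,
but a single maximum-likelihood (ML) tree with bootstrap values often
cannot: the relevant internal branches are short and the ML tree is only
marginally better than many alternatives.

The approach implemented here makes that uncertainty explicit. Instead of
one estimated tree, *every* tree is evaluated:

1. The sequences are partitioned into a small number of operational
   taxonomic units (OTUs) whose internal relationships are uncontroversial
   (they follow the accepted species phylogeny) and are therefore frozen.
   With six OTUs there are exactly $(2k-5)!! = 105$ unrooted binary
   topologies to consider — few enough to fit all of them.
2. Each OTU-level topology is expanded to a full tree by grafting the fixed
   within-OTU subtrees, and its branch lengths and rate parameters are
   optimized by ML under an empirical amino-acid model with invariant sites
   and discrete-gamma rate heterogeneity (JTT+I+G4).
3. Topologies are compared by the log-likelihood deficit
   $\Delta\log L_i = \log L_{ML} - \log L_i$ and its per-site standard
   error, and ranked by $\Delta\log L_i / SE_i$. Topologies with a ratio
   at most 1 are "within 1 SE" of the ML tree.
4. Resampling of estimated log-likelihoods (RELL) — bootstrap over site
   patterns without re-optimization — drives three hypothesis tests per
   topology: the one-sided Kishino–Hasegawa (KH) test, the
   Shimodaira–Hasegawa (SH) test (its null takes the maximum over all
   candidates, making it conservative), and the approximately unbiased
   (AU) test, which fits bootstrap proportions across resampling scales
   (multiscale bootstrap) to correct the selection bias that affects naive
   bootstrap proportions.
5. Each topology is classified into a duplication-timing scenario by
   declarative clade rules, and support is aggregated per scenario: a
   scenario is "not rejected" at level $\alpha$ if its best AU p-value is
   at least $\alpha$.

The package's central function, `topo_test()`, chains steps 1–5 and
returns a ranked table (one row per topology) together with the
per-topology ML fits.

## The likelihood model

Site likelihoods are computed with the pruning algorithm under a
reversible model $Q_{ij} = s_{ij}\pi_j$ ($i \ne j$), scaled so the
expected substitution rate at equilibrium is 1; branch lengths are in
expected substitutions per site. Two exchangeability sets are built in:
the classical Jones–Taylor–Thornton (JTT) empirical matrix in its standard
integer digitization, and a Poisson model (equal rates and frequencies)
kept because it admits closed-form transition probabilities
($P_{aa}(t) = \tfrac{1}{20} + \tfrac{19}{20}e^{-20t/19}$), which the test
suite exploits.

Rate heterogeneity follows the standard discretization: $k$ categories at
the means of the equal-probability bins of a Gamma$(\alpha,\alpha)$
distribution ($k = 4$ by default, the "+G4" convention). With an invariant
fraction $p_{inv}$, the per-site likelihood is

$$ L = p_{inv}\,L_0 + \frac{1-p_{inv}}{k}\sum_{c=1}^{k}
       L\!\left(\text{rate } r_c/(1-p_{inv})\right), $$

where $L_0$ is the equilibrium frequency of the constant state (summed
over all compatible states when gaps or `X` make the column ambiguous; an
all-gap column gives $L_0 = 1$). Dividing the category rates by
$(1-p_{inv})$ keeps the mixture's mean rate at 1 — the common convention,
stated explicitly here because different programs disagree silently.
Gaps and `X` contribute a partial-likelihood vector of ones (standard
missing-data treatment). The same mixture definition drives the sequence
simulator, so simulation and inference share one model object and
parameter-recovery tests are exact in distribution.

## Optimization

Each topology keeps its own free parameters. Branch lengths are fitted by
one-dimensional Brent searches on each edge, organized in preorder
traversals that keep all partial likelihoods current, so every
one-dimensional problem is the exact profile likelihood of that edge and
the total log-likelihood is non-decreasing across sweeps. Per edge, the
inner and outer partials are projected once onto the eigenbasis of $Q$,
after which each trial length costs only an exponential re-weighting.
$\alpha$ (log scale, bounds $[0.02, 100]$) and $p_{inv}$ (bounds
$[0, 0.99]$) are profiled by bounded scalar optimization interleaved with
branch sweeps; branch lengths live in $[10^{-8}, 10]$. Iteration stops
when a full cycle improves the log-likelihood by less than `tol`
($10^{-4}$ by default); if the budget (`max_rounds`, `outer_rounds`) runs
out first, the best-so-far fit is returned with `converged = FALSE`
rather than an error.

Whether $\alpha$ and $p_{inv}$ should be re-optimized for all 105
topologies or fitted once and shared is not dictated by the method; both
are defensible and the package exposes the choice (`share_rates`,
default: re-optimize per topology). Shared rates are several-fold faster
and, in every fixture we simulate, leave the ranking unchanged — the rate
parameters are tied to the data far more than to the topology.

Numerical safeguards: partial likelihoods are rescaled per node when they
fall below $10^{-240}$ (relevant only for much larger trees than the
six-OTU problem); transition matrices clamp the tiny negative entries that
eigendecomposition can produce at very short branches; ties for the ML
tree are broken deterministically by the lexicographically smallest
canonical topology string.

## Topology space

Unrooted trees are stored rooted at an arbitrary trifurcation, matching
the printed style `(X,Y,OG);`; under a reversible model the position of
that display root carries no likelihood meaning. The canonical form roots
at the internal vertex adjacent to the lexicographically smallest leaf and
sorts children by smallest descendant label — cheap, deterministic, and
invariant under re-rooting, which the tests verify exhaustively.
Enumeration proceeds by stepwise leaf addition onto every edge, which
generates each unrooted topology exactly once; the double-factorial counts
(1, 3, 15, 105, 945 for $k = 3\ldots7$) and canonical-form uniqueness are
both asserted.

## The synthetic generator

`gene_family_fixture()` builds the six-OTU test bed: osteichthyan VTG1 and
VTG2, chondrichthyan VTG1 and VTG2, a cyclostome group and an outgroup,
with a configurable number of leaves per OTU (default 2, keeping
fixtures at desk scale) and ladder subtrees within OTUs. Default
branch lengths — terminal 0.2, speciation-scale internal 0.1, duplication
branches 0.15 substitutions/site — are chosen as realistic for an
old vertebrate gene family in which deep internal branches are short
relative to terminal ones; the default alignment length is 1,195 columns,
typical of a trimmed single-gene protein alignment, with JTT, $\alpha = 1$,
$p_{inv} = 0.2$. The generator draws a root state per column from the
equilibrium frequencies, marks columns invariant with probability
$p_{inv}$, assigns gamma categories uniformly otherwise, and evolves
states edge by edge through the exact transition kernels.

What the simulator does *not* emulate: indels and alignment error (no gaps
are ever simulated; gap handling is inference-side only), compositional
heterogeneity across lineages, site-specific profiles, and gene
conversion. Passing tests therefore show that the machinery is correct
under its own model class, not that the model class is adequate for any
particular real alignment.

## The resampling tests

RELL replicates draw `round(scale * n)` sites (pattern indices,
probability proportional to multiplicity); the same draws are shared by
all trees within a replicate, and per-scale seeds are derived from one
configuration seed by a fixed offset so that adding a tree or a scale
never changes existing replicates. Defaults follow the classic multiscale
implementation: ten scales $0.5, 0.6, \ldots, 1.4$ and $B = 10{,}000$
replicates per scale.

KH centers each tree's replicate deficit distribution on its own mean and
reports the one-sided exceedance probability of the observed deficit; a
normal-approximation variant (deficit against $N(0, SE^2)$) is available
as an option. SH compares the observed deficit against the replicate
distribution of $\max_j S_{jb} - S_{ib}$, where $S$ are the per-tree
centered replicate totals; this form makes $p_{SH} = 1$ for the ML tree
and guarantees $p_{SH} \ge p_{KH}$ replicate-set-wise, both asserted on
every run. The AU test probit-transforms the bootstrap proportions
$BP_r$, fits $z_r = d\sqrt r + c/\sqrt r$ by weighted least squares with
binomial weights, and reports $1 - \Phi(d - c)$. Proportions are clamped
to $[1/(B{+}1), 1 - 1/(B{+}1)]$ before the probit; a tree with fewer than
two scales strictly inside $(0,1)$ is reported as 0 or 1 by the side its
degenerate proportions fall on, and flagged.

A point worth stating about calibration: the AU test's unbiasedness is a
statement about *least-favorable* configurations — data-generating
distributions on the boundary between the attraction regions of competing
topologies. When data are simulated under a well-resolved tree the test is
strongly conservative for the true topology (it is almost never rejected),
and when a contested internal branch is exactly zero the competing
topologies can imitate each other perfectly, which compresses the p-value
distribution toward its center rather than spreading it uniformly. The
calibration study in the acceptance suite therefore simulates under short
but non-zero contested branches with the full candidate set, the regime in
which the selection bias that AU corrects is actually active, and checks
the rejection rate of the true topology at $\alpha = 0.05$ against its
binomial band.

## Scenario classification

Scenario rules are data, not code: each rule names required clades (under
rooting on the outgroup OTU) and whether all or any must be present; rules
are tried in priority order. The shipped default encodes the two timings:
`post_split` requires both within-lineage pairs
($\{$Cho-1, Cho-2$\}$ *and* $\{$Ost-1, Ost-2$\}$); `pre_split` requires at
least one cross-lineage orthology clade ($\{$Cho-1, Ost-1$\}$ *or*
$\{$Cho-2, Ost-2$\}$) — a single such clade already forces the duplication
before the split, which is why "any" is the right connective. Everything
else is `other`. Over the 105 six-OTU topologies the default rules give
3 `post_split`, 27 `pre_split` and 75 `other`; both counts follow from
collapsing the required pair to a single unit (trees on 5 units: 15 per
pair, minus the 3 four-unit trees counted twice). Clade membership under
outgroup rooting is implemented as a bipartition test on the unrooted
tree, and an independent rooted implementation cross-checks it in the
tests.

## Problem sizes used by the test suite

The suite verifies correctness at small exact scales (brute-force
likelihood sums on trees with up to four leaves at $10^{-10}$ relative
tolerance; full pattern-space normalization for up to three leaves) and
behaviour at simulation scales chosen to keep the whole suite in the
tens of minutes on one CPU: scenario recovery uses 50 replicates per
scenario of 2,000-site single-leaf-per-OTU fixtures over all 105
topologies with shared rate parameters and a relaxed sweep budget;
AU calibration uses 200 one-thousand-site datasets with $B = 1{,}000$;
parameter recovery uses 2,000-site alignments. The acceptance script runs
the full default pipeline (12 leaves, 1,195 sites, $B = 10{,}000$) once.

## Known limitations

* Candidate evaluation is exhaustive enumeration or a user list — there is
  no heuristic tree search, by design: the method's point is evaluating
  *all* constrained topologies.
* Protein models only (JTT, Poisson); no partitioned or codon models.
* The AU fit uses the two-parameter $d\sqrt r + c/\sqrt r$ model without
  higher-order curvature terms; with very small $B$ the weighted fit can
  be noisy, which is why $B \ge 100$ is enforced and $10^4$ is the
  default.
* Within-OTU subtrees are frozen; misspecifying them biases all 105
  likelihoods, though comparisons among topologies are affected far less
  than absolute likelihoods.
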