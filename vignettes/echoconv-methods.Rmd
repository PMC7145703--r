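---
title: "Models and methods behind echoconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind echoconv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`echoconv` implements, as one tested pipeline, the comparative
molecular-evolution analysis applied to cochlear genes of echolocating
mammals: branch-site scans for positive selection with Bayes empirical
Bayes (BEB) identification of selected sites, ancestral-reconstruction
based detection of parallel and convergent amino-acid substitutions
between echolocating lineages, a neutral-excess test for those counts,
and the matched phylogenetic-control comparison that asks whether
echolocator pairs show more convergence than equally distant
nonecholocating pairs. This vignette records the models, the defaults,
and the design decisions a maintainer would want explained.

## The study system

Nineteen mammals anchor every analysis: three constant-frequency (CF)
bats, four frequency-modulated (FM) bats, two tongue-click bats, two
nonecholocating bats, two echolocating toothed whales, one baleen whale
and five outgroup mammals. `make_study_fixture()` returns a rooted
binary 19-taxon tree consistent with the accepted species phylogeny for
these groups; since no branch lengths are published for this tree,
lengths are synthetic by necessity, drawn reproducibly from a seed
(gamma distributed, mean 0.05 expected substitutions per site, an
unexceptional magnitude for mammalian orthologs) and rescalable through
`scale` when an analysis calls for lower divergence.

The seven foreground configurations of the selection scan (`CF`, `FM`,
`CLICK`, `TW` and the combinations `CF+FM`, `CF+FM+CLICK`,
`CF+FM+CLICK+TW`) tag the terminal branches of the member lineages via
`mark_foreground()`. PAML-style `#1` marks in Newick input are read as
the same tags.

## Branch-site model and its test

Codon evolution follows the GY94 model: the instantaneous rate from
codon $i$ to $j$ is nonzero only for single-nucleotide changes and
equals $\pi_j$, times $\kappa$ for transitions, times $\omega$ for
nonsynonymous changes. The branch-site "model A" mixture has four site
classes with proportions $(p_0, p_1, p_{2a}, p_{2b})$, where classes
2a/2b share $1-p_0-p_1$ in ratio $p_0\!:\!p_1$: class 0 evolves with
$\omega_0<1$ everywhere, class 1 neutrally, and classes 2a/2b switch to
$\omega_2 \ge 1$ on foreground branches. The null fixes $\omega_2=1$;
twice the log-likelihood difference is referred to $\chi^2_1$, the
conservative reference recommended for this test (the 50:50 mixture
reference is available as a flag in `lrt()`).

Numerical choices:

* **Codon frequencies** are F3x4 from the alignment by default
  (uniform-61 optional), with a half-count guard per nucleotide so a
  degenerate position cannot zero out a codon.
* **Rate normalization.** The four class generators share one scale
  factor, the proportion-weighted mean background rate, so branch
  lengths read as expected substitutions per codon under the background
  process. The simulator and the fitter use the identical convention,
  which is what makes parameter-recovery tests meaningful.
* **Branch lengths** are re-estimated once per gene under the
  single-$\omega$ (M0) model and then fixed for the null and
  alternative fits (`branch_lengths = "m0"`), which stabilizes the
  mixture optimization; `"fixed"` uses the input tree as-is. The
  simulation studies shipped with the package use `"fixed"` with the
  generating tree, isolating the mixture machinery from length
  estimation error; M0 re-estimation is exercised separately at small
  scale.
* **Optimization** is quasi-Newton (`nlminb`) on transformed parameters
  (softmax for the proportions, logit for $\omega_0$, $\log(\omega_2-1)$,
  $\log\kappa$), relative tolerance $10^{-8}$ in the log-likelihood.
  The default restart budget is deliberately small: up to two
  deterministic starts for a stand-alone fit, and the alternative, when
  chained after the null (`init =`), always starts from the null
  optimum — guaranteeing the nesting inequality
  $\ell_{\mathrm{alt}} \ge \ell_{\mathrm{null}}$ — plus one exploratory
  start at $\omega_2=3$. The shipped calibration studies (a hundred null
  fits and dozens of selection fits) show nominal null rejection rates
  and accurate $\omega_2$ recovery under this budget; `n_starts` raises
  it where a user wants more insurance.
* **Site patterns** are compressed before fitting; the pruning kernel
  (shared with the protein side) is compiled and rescales partial
  likelihoods per column, so alignments of at least 10,000 sites by 50
  taxa are safe from underflow.

**BEB.** Site-level identification averages the posterior probability
of membership in classes 2a/2b over a uniform $10^4$-point grid on
$(p_0+p_1,\; p_0/(p_0+p_1),\; \omega_0,\; \omega_2)$ with $\omega_0$ on
(0,1) and $\omega_2$ on (1,11), the standard construction at the
standard resolution (`grid_points` is configurable). $\kappa$, branch
lengths, and the mixture rate-normalization factor are held at their
maximum-likelihood values across the grid — the construction fixes the
"other parameters" at their estimates, and the scale factor is treated
as one of them. Sites with posterior above 0.90 are flagged, and
Benjamini–Hochberg correction is applied across genes within each
foreground configuration (the narrowest defensible family; a global
family is a one-line change at the call site of `fdr_adjust()`).

## Ancestral reconstruction

Parallel/convergent detection consumes amino-acid states, so
reconstruction operates on the protein alphabet (the cited
nucleotide-program provenance of the original ancestors is not
reproducible as described; residues are what the classification
criteria are defined on). `reconstruct_marginal()` computes, for every
internal node and site, the marginal empirical-Bayes posterior over the
20 residues by a down-pass/up-pass around Felsenstein pruning, with
parameters fixed at their estimates. The default model is Poisson
(equal exchangeabilities) with uniform frequencies; any symmetric
empirical exchangeability matrix can be supplied (the test suite
cross-checks the WAG configuration against an independent
implementation). Discrete-gamma rate heterogeneity (4 categories) is
available and off by default. Exact posterior ties break toward the
alphabetically first residue and are flagged rather than silently
resolved. Gap or ambiguity characters contribute unit partial
likelihoods; sites missing at a node needed by a downstream comparison
are skipped there, not guessed.

Per-gene branch lengths for reconstruction come from
`fit_branch_lengths()`, coordinate-wise Brent optimization of each edge
with fresh partials per edge, which makes every accepted update a
likelihood improvement; the fit is flagged, never silent, if the sweep
budget is exhausted. Under a reversible model the root placement is
unidentifiable (only the sum of the two root-adjacent lengths is
determined), which is why recovery tests compare unrooted trees.

## Convergence criteria, the excess test, and the matched controls

For a pair of tested terminal branches (internal branches are supported
but the study design compares extant species), a site is called when
the two extant residues are identical and each differs from the residue
reconstructed at its own most recent ancestral node; the call is
*parallel* when the two ancestral residues are equal and *convergent*
otherwise. `summarize_pairs()` counts genes once per comparison however
many sites are called, mirroring the dual gene (site) reporting of the
study; core parallel genes are those with a parallel call in **all six**
echolocator comparisons, the strict reading of "parallel among all four
lineages" (sites may differ between comparisons).

The excess (neutrality) test conditions on the observed substitutions:
parent states stay as reconstructed, and each observed derived state is
redrawn in proportion to the model's replacement rate from that parent,
excluding the parent itself. Summing per-site coincidence probabilities
over the sites substituted on both branches gives expected parallel and
convergent counts, and one-sided P values come from the Poisson upper
tail at the observed counts. The published description of the original
tool does not print its null construction; this Poisson form is this
package's decision, pinned by a Monte-Carlo oracle in the tests rather
than by the historical binary. Zero substitutions on either branch is a
degenerate result (expectation 0, P = 1), not an error.

The matched-control analysis pairs each echolocator comparison with a
comparison of the same echolocating lineage against a nonecholocating
lineage at equal phylogenetic distance. `paired_t_test()` is the
classical two-sided paired t on the seven published rows — all seven,
including the two rows where the convergent-count direction reverses
(the published "except" clause describes direction, not exclusion; the
reported P values confirm this reading). Reported P values are rounded
to two decimals only in the report layer. `adaptive_overlap()`
intersects BEB-flagged sites with parallel calls per gene and site,
reproducing the analysis that singled out jointly selected-and-parallel
sites.

## The simulator and what passing tests mean

`simulate_codon_alignment()` and `simulate_protein_alignment()` use
exact stochastic (Gillespie) simulation per branch and site — not
matrix-exponential endpoint draws — because the full event history is
the package's ground truth: tests replay every event chain to the
leaves, count synonymous against nonsynonymous events, and check class
proportions and stationarity. `inject_convergence()` plants parallel or
convergent substitutions on a chosen branch pair with consistent
descendant states and returns the truth table. One root seed drives
everything; per-gene streams derive from it by a fixed affine counter
(`substream_seed()`), so any gene can be regenerated in isolation.

Defaults for the simulation studies (`p0 = p1 = 0.45`, $\omega_0=0.1$,
$\kappa=2$, uniform codon frequencies) are configuration values chosen
for testability. The generator emulates single-copy ortholog alignments
already cleaned by the upstream steps: no indels (the column filter is
tested with a separate gap-injection utility), no alignment error, no
assembly artifacts, no among-gene tree discordance. Passing tests
therefore demonstrate that the statistical machinery recovers truth
under its own model at the stated sizes — not that real cochlear
transcriptome data meet those assumptions.

Reference problem sizes used by the shipped studies (chosen as the
package's standing benchmark): 100 null genes of 300 codons on an
8-taxon CF-foreground subtree for LRT calibration; 20 replicates of
1,000 codons on the full tree for $\omega_2$ recovery; 20 low-divergence
(height $\le$ 0.3) replicates for injected-parallel recall; 10
replicates of 500 codons under $\omega_2=8$ on the all-echolocator
foreground — the configuration with enough foreground branch length for
site-level identification to be informative — for BEB operating
characteristics. The BEB power figure is meaningful only when the
foreground carries appreciable length; a three-branch foreground
totalling ~0.17 substitutions cannot push any site past a 0.90
posterior, whatever the method.

## Filters and coordinates

The alignment filter drops every codon column containing a gap or
ambiguity in any taxon — the strictest reading of the original
codon-based trimming, chosen because downstream site classification
requires fully resolved columns — then discards genes shorter than 150
nt. All site numbers reported anywhere in the package are 1-based codon
(= amino-acid) positions in the *original* alignment coordinates,
carried through the filter's coordinate map, so results remain
addressable against the unfiltered gene.

## Known limitations

* The branch-site fitter and BEB are exact to their definitions but
  R/BLAS-bound; genome-scale scans (thousands of genes) are feasible
  but not instant.
* No codon-level ancestral reconstruction, no joint (as opposed to
  marginal) reconstruction, and no site models beyond model A.
* The excess test's null is this package's Poisson construction
  (validated by simulation), not a re-implementation of the historical
  tool's unpublished internals.
* Matched-control designs assume one representative taxon per lineage
  per comparison, as in the study design shipped in `study_design()`.
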