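---
title: "Modelling the phylogenetic dynamics of rDNA clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the phylogenetic dynamics of rDNA clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnaevol)
```

## The scientific problem

Ribosomal DNA (rDNA) clusters — tandem arrays of the 18S–5.8S–28S rRNA gene
unit — sit on one to many chromosome pairs per species, usually right next to
a centromere or a telomere. In karyotypically volatile groups such as the
genus *Mus*, their chromosomal distribution differs even between sister
species, which raises two comparative questions this package is built to
answer:

1. **Where were the clusters in the past?** Given a reference phylogeny and
   per-species FISH observations coded on a common set of orthologous
   chromosomal segments, reconstruct the probability that each ancestral
   node carried a cluster (and in which position), and read off insertion
   and deletion events along branches.
2. **Do clusters and centromeres evolve together?** For each segment, test
   whether the presence/absence dynamics of the rDNA cluster depend on the
   presence of a centromere, using the classic dependent-vs-independent
   comparison for paired binary traits.

A third, descriptive stage asks how often chromosomal **breakpoints**
(fission, fusion, translocation, inversion sites) coincide with clusters and
centromeres at the moment the rearrangement happened.

## Characters and coding rules

The unit of analysis is one of 30 orthologous segments of the ancestral
karyotype. Each species × segment cell takes a state:

* `0` — no cluster on the segment,
* `1` — cluster on the proximal (pericentromeric) region,
* `2` — cluster at the distal (subtelomeric) end,
* `?` — missing/undetermined homology.

`encode_matrix()` applies the conventions used when transcribing karyotype
tables: a pericentromeric cluster lands on the chromosome's proximal
segment; a subtelomeric cluster on its distal segment; a Robertsonian
metacentric `"a.b"` contributes a pericentromeric cluster to both arms
(`expand_metacentric()`); clusters reported between the centromere and the
telomere are coded proximal (`interstitial_state = 1`) by default because
the state space only distinguishes proximal from distal — a switch codes
them distal instead. Sex-chromosome clusters are recorded in the karyotype
table but excluded from the matrix: the orthologous-segment set is
autosomal. Sites are counted as two per cluster-bearing pair (one per
homolog), so `cluster_summary()` reports `n_sites = 2 * n_pairs`.

## The model

Characters evolve by a continuous-time Markov chain along the rooted
reference tree. For the three-state character we fit the all-rates-different
(ARD) generator: six free instantaneous rates
$q_{01}, q_{02}, q_{10}, q_{12}, q_{20}, q_{21}$ (per unit branch length),
diagonal equal to minus the row sum. Branch transition probabilities are
$P(t) = e^{Qt}$; tip data enter as observation vectors (a unit vector for an
observed state, all ones for `?`), and the likelihood is computed by
Felsenstein's pruning algorithm with per-node rescaling. The root state is
integrated over a prior — uniform by default, with the stationary
distribution of $Q$ or a fixed vector available through `root_prior()`. The
uniform default keeps the nested model comparison below well defined and
matches common ancestral-reconstruction practice.

Numerically, $e^{Qt}$ uses an eigendecomposition fast path whose
reconstruction residual is checked before use (an ARD generator need not be
diagonalisable), falling back to a dense Padé scaling-and-squaring routine.
Rows of $P(t)$ are clamped at zero and renormalised to absorb round-off.
Likelihood maximisation is bounded quasi-Newton (`L-BFGS-B`) on log-rates,
run on a copy of the tree scaled to unit height with rate bounds
$[10^{-8}, 100]$ on that scale, from a moderate default start plus seeded
random restarts — ARD surfaces are multimodal for sparse characters.
Reported rates are per unit of the original branch-length scale.

**Ancestral states.** `marginal_probs()` returns true marginal
(empirical-Bayes) posteriors from the two-pass up/down algorithm — not the
scaled conditional likelihoods some historical implementations report, which
differ at non-root nodes. The correctness anchor is exhaustive enumeration
over all internal-node state assignments on small trees, which the test
suite checks to $10^{-8}$. `classify_states()` turns posteriors into calls
with an inclusive threshold: state $s$ is called iff $P(s) \ge$ 0.75 by
default; anything else is `unknown`. The threshold lives in $(0.5, 1]$ so at
most one state can be called.

**Events.** `call_events()` scans ancestor–descendant pairs whose presence
status (state 1 or 2 = present) is determinate on both ends: absent →
present is an insertion, present → absent a deletion. When a node's parent
is `unknown`, the node is compared with its nearest determinate ancestor, so
the event is noted on the deepest node at which the new state holds
(`adjacent_only = TRUE` restricts to adjacent pairs). The supporting
probability reported is the posterior of the new presence status at the
reporting node. Events into tips are `terminal`, the rest `deep`.

A degenerate case worth knowing about: for an invariant character under a
uniform root prior the ML surface has a ridge where rates *into* the
observed state grow without bound — unobserved states decay instantly, the
likelihood tends to 1, and the root marginal stays at the prior while every
other node is reconstructed in the observed state. This is a property of
the model, not a failure of the optimiser; rates out of the observed state
still go to the lower bound, and calls at non-root nodes are unaffected.

## The correlated-evolution test

For each segment, cluster presence (states 1 and 2 collapsed; `?` stays
missing) is paired with centromere presence from the annotation table. Two
nested CTMCs on the combined state space
$\{(0,0), (0,1), (1,0), (1,1)\}$ are fitted by ML:

* **independent** — 4 parameters: each trait's gain and loss rate is the
  same whatever the other trait's state; simultaneous double transitions
  have rate 0. Its log-likelihood equals the sum of the two single-trait
  2-state log-likelihoods (checked numerically in the suite).
* **dependent** — 8 parameters: every single-trait rate is conditioned on
  the other trait's current state; double transitions stay at 0.

The likelihood-ratio statistic $2(\ell_{dep} - \ell_{indep})$ is referred to
$\chi^2_4$ (upper tail; for df = 4 this equals $e^{-x/2}(1 + x/2)$). The
dependent optimisation warm-starts from the independent MLE mapped into the
8-rate space, which enforces nesting ($\ell_{dep} \ge \ell_{indep}$) by
construction; a violation beyond $10^{-6}$ is reported as optimizer failure
rather than silently clamped. `run_all_segments()` excludes segments with no
cluster anywhere or with clusters only at the telomeric position (they carry
no signal for the pericentromeric association being tested), fits the
remaining segments, and reports raw p-values at $\alpha = 0.05$ — matching
the original analysis, which applied no multiple-testing correction across
segments; `run_config(holm = TRUE)` adds Holm-adjusted values for users who
want them.

## The packaged study fixture

`mus_study_fixture()` assembles a complete 23-taxon dataset (21 *Mus* taxa
plus two murid outgroups) from plain-text files under `inst/extdata/`:

* a reference tree honouring the published topological constraints (the
  shrew-mouse subgenus branching first, then the pygmy mice as sister to the
  spiny-mouse + house-mouse clade; the Cyprus mouse sister to the Macedonian
  mouse). Because the source study never published its ML branch lengths,
  the fixture tree is ultrametric with node depths proportional to clade
  nesting — **synthetic lengths**, so node-level probabilities computed on
  it are fixture-specific and are never asserted against the original
  study's values;
* the transcribed per-species karyotype table and a homology map. Taxa
  scored in house-mouse nomenclature map directly; for the other
  nomenclatures the published cross-species maps are not machine-readable,
  so the shipped map is a synthetic stand-in constructed to preserve every
  segment-level fact the analysis depends on (which segments ever carry
  clusters, the never-clustered segment, the telomeric-only segment, the
  outgroup cells with undetermined homology);
* a rule-based synthetic centromere annotation (proximal-type segments
  centromeric throughout; distal-type segments only in the highly fissioned
  shrew mouse; one segment gaining its centromere only within the
  house-mouse subgenus, mirroring the study's neocentromere example);
* 42 breakpoint records with transcribed context columns (cluster and
  centromere state at the time of each rearrangement), reproducing the
  published classification counts: 9 undetermined, 13 involving neither
  structure, 8 flanking both a cluster and a centromere (2 at the distal
  end of the cluster, 6 between centromere and cluster, 4 of those followed
  by centromere reacquisition), 12 in explicit remainder categories.

Consequently the fixture supports exact reproduction of the *structural*
results (30 segment columns, 29 reconstructable segments, 28 screened
segments, the 24% flanking share, per-taxon site counts) but not of
branch-length-dependent quantities (per-node probabilities, per-segment
p-values, global node-classification fractions).

## What the simulators emulate — and what they do not

`simulate_tree()` draws pure-birth (Yule) trees; `simulate_character()`
evolves a discrete character by exact CTMC sampling (exponential waiting
times, with node states and per-branch jump counts retained for auditing);
`simulate_pair()` runs the combined 4-state chain and splits it into the two
binary traits. All are bit-reproducible given `seed`; every function derives
its own sub-stream from (seed, operation name) so stages can be reordered
without interference.

The simulators generate exactly what the inference assumes: a single
character evolving independently on a known tree. They do **not** emulate
correlated evolution across segments, rate variation through time,
ascertainment of segments through observed clusters, or errors in homology
assignment — so passing calibration and recovery tests demonstrates
correctness of the machinery under the model, not robustness of the model
on real karyotype data.

## Study conditions used by the statistical tests

Chosen once, as the package's canonical simulation conditions, and sized to
keep the default test run tractable on a single CPU:

* **Oracle equivalence** — 200 random draws of trees (3–6 tips), state
  counts $k \in \{2,3,4\}$ and generators, compared with exhaustive
  enumeration; agreement to $10^{-8}$ for both likelihoods and marginals.
* **Factorisation** — 100 random independent-pair datasets; joint lnL equals
  the sum of single-trait lnLs within $10^{-6}$.
* **Parameter recovery** — 50 characters simulated on one 200-tip Yule tree
  under a homogeneous ARD generator with all rates 0.2 (about two expected
  changes per root-to-tip path: frequent enough to inform every rate,
  sparse enough not to saturate branches). The median relative error of
  each recovered rate stays below 50%. This precision is condition
  dependent: strongly asymmetric generators leave some states rarely
  visited and inflate the error of the corresponding rates for any ML
  estimator — a limitation of single-character data, not of the
  implementation (the suite separately verifies our MLEs coincide with an
  independent implementation on identical data).
* **Type-I error / power** — 200 independent-model simulations on a 100-tip
  tree (all four rates 0.5) give a rejection rate at $\alpha = 0.05$ inside
  [0.005, 0.10]; a band, not a point, is asserted because the $\chi^2_4$
  reference is only asymptotic — conservative when true rates sit at a
  boundary, and in our experiments mildly anticonservative at this sample
  size (empirical rates around 0.06–0.11 across seed streams, with
  identical log-likelihoods to an independent implementation, so the
  inflation belongs to the reference distribution, not the code). Treat
  p-values near 0.05 on trees of this size accordingly. Power is probed
  with a generator in which the cluster can only be gained while the
  centromere is present and is rapidly lost without it — the regime the
  test exists to detect — and exceeds 0.8 over 25 replicates.

## Known limitations

* Branch lengths drive everything downstream of the likelihood; with the
  synthetic fixture lengths, per-node output on the packaged data is
  illustrative, not a reproduction of the original study's node values.
* The 4-state pair model inherits the usual caveats of the
  dependent-vs-independent LRT: modest power on small trees, sensitivity to
  trait prevalence, and a boundary-affected null distribution.
* Single-character ARD rate estimates are intrinsically noisy; treat fitted
  rates as nuisance parameters behind the ancestral reconstruction rather
  than as quantities of direct interest.
* The breakpoint stage classifies and counts; it does not infer
  rearrangement scenarios from karyotypes, and the packaged breakpoint
  contexts are transcriptions, not recomputations.
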