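---
title: "Methods: network-based concordance scoring of drug targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based concordance scoring of drug targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugcipher)
```

## The model

The package scores every protein of a protein–protein interaction (PPI)
network for concordance with a query drug. It rests on three assumptions:

1. therapeutically similar drugs tend to act on functionally related
   proteins;
2. structurally similar drugs tend to bind related proteins;
3. functional relatedness of proteins is reflected in PPI-network
   proximity.

Two similarity measures span the *pharmacological space*. Therapeutic
similarity (TS) compares drugs through their ATC codes. The ATC
classification is a five-level hierarchy encoded in a 7-character string
(level prefixes of lengths 1, 3, 4, 5, 7). Every prefix is assigned the
fraction of drug–code assignments in the reference corpus that carry it,
i.e. an empirical prior probability, monotone non-increasing from root to
leaf. Two codes are compared by the information-content ratio

$$sim(i,j) = \frac{2\,\log p(\mathrm{prefix}(i,j))}{\log p(i) + \log p(j)},$$

which is 0 when only the (probability-1) root is shared and 1 for
identical codes; between drugs, TS is the maximum of $sim$ over their code
pairs. Chemical similarity (CS) is the Tanimoto coefficient on binary
fingerprints; the package takes explicit bit vectors so that no chemistry
toolkit is required, and any fingerprinting backend can feed it.

The *genomic space* is the PPI network. The closeness of protein $p$ to
drug $d$ sums a distance-decay transfer over the drug's known targets,

$$\phi_{pd} = \sum_{k} e^{-L^2_{p p_k}},$$

with $L$ the unweighted shortest-path distance and $e^{-\infty^2} = 0$ for
disconnected pairs. The Gaussian decay keeps the self term at 1, direct
neighbours at $e^{-1} \approx 0.37$, and distance-2 proteins at
$e^{-4} \approx 0.02$, so closeness is dominated by a target's immediate
neighbourhood; the transfer is a pluggable pure function
(`transfer_function()`) should a different decay be wanted. Drug genomic
relatedness (GR) averages the same transfer over all cross pairs of two
drugs' target sets.

For query drug $d$, each protein $p$ has a closeness vector
$\Phi_p = (\phi_{p d_1}, \ldots, \phi_{p d_n})$ over the $n$ reference
drugs, and $d$ has similarity vectors $TS_d$ and $CS_d$ over the same
drugs. The three concordance models are:

- **TS**: Pearson correlation of $TS_d$ with $\Phi_p$;
- **CS**: Pearson correlation of $CS_d$ with $\Phi_p$;
- **MS**: least-squares regression
  $\Phi_p \approx a' \, TS_d + b' \, CS_d + c$, with the concordance
  defined as the correlation between $\Phi_p$ and the fitted combination.

Proteins are ranked by descending concordance, ties broken
lexicographically by protein identifier so that rankings are
deterministic. The query drug's own entries ($TS_{dd} = CS_{dd} = 1$,
$\phi_{pd}$) stay in the vectors: the vectors are defined over all
reference drugs.

### Why the MS coefficients are constrained non-negative

The regression constants in the MS model are contribution weights of
non-negative quantities — similarities and closenesses — so a negative
weight has no model interpretation. The constraint also matters
numerically: the correlation between a response and its *unconstrained*
least-squares fit is sign-blind (it equals the multiple correlation $R$,
which is never negative), so an unconstrained MS score would promote
proteins whose closeness profile is strongly *anti*-correlated with the
drug's similarity vectors — proteins that the single models correctly
push to the bottom. With two predictors the constrained solution is
closed-form: the ordinary fit when its similarity coefficients are already
non-negative, otherwise the better single-predictor fit among those with a
positive marginal correlation, otherwise the intercept alone (score 0).
The nesting property that motivates the combined model is preserved where
it is meaningful: whenever both single-model concordances are
non-negative, the MS concordance is at least their maximum.

### Numerical conventions

- Any correlation involving a zero-variance vector is defined as 0, not
  `NA`: constant profiles (e.g. proteins disconnected from everything)
  rank last instead of poisoning the ranking.
- Two all-zero fingerprints have Tanimoto 0 (with a warning), and a zero
  biological-fingerprint vector has cosine resemblance 0.
- ATC input is case-normalized; leaf codes unseen in the probability
  corpus fall back to a pseudo-count of one assignment (logged), so query
  drugs with novel codes remain scoreable.
- Collinear TS/CS predictors (after centering) reduce the MS fit to the
  single better predictor, flagged in the fit object.
- Matrix TSV output serializes with 17 significant digits so write–read
  round-trips are exact.
- The leave-one-out closeness adjustment subtracts the removed targets'
  transfer terms, which equals rebuilding the column from the reduced
  target set; residues below $10^{-15}$ are clamped to zero.

## Validation machinery

Leave-one-out validation follows the standard protocol for this model
family: for each known drug–target pair, all *other* targets of the drug
are removed from its closeness column, 19 negative-control proteins are
drawn uniformly from the network, and the 20 candidates are scored; a
success requires the held-out target to rank strictly first (ties count as
failures, a conservative choice). Negatives exclude the drug's known
targets to avoid mislabelled "negatives". Under a uniformly random scorer
each pair is an independent 1-in-20 event, giving the analytic null
precision of 0.05 that the test suite checks.

The pooled rank-threshold ROC treats each (drug, protein) pair as one
instance: at threshold $r$, sensitivity is the fraction of gold pairs
ranked within $r$ and specificity is computed over all non-gold pairs;
the AUC is trapezoidal and, for a single drug, equals the Mann–Whitney
statistic (checked against a pair-counting oracle). Rank enrichment uses
the worst target rank $r_{max}$ as cutoff, reports the fold
$N / r_{max}$, and a one-sided hypergeometric tail for observing all $k$
targets within the top $r_{max}$ of $N$.

Biological fingerprints are the drugs × proteins matrix of MS scores.
Proteins with near-constant score profiles across drugs ("unspecific",
typically proteins far from every target) are dropped; the criterion is a
quantile on the across-drug standard deviation, default 0.034, chosen so
that a dispersion-homogeneous score matrix retains about 96.6 % of
proteins. Activity resemblance is the cosine between fingerprint rows; its
significance threshold is always recomputed from a null distribution
(default: the empirical distribution of all pair resemblances; optionally
a within-row protein-label permutation null), never hard-coded, because it
is a property of the dataset at hand. "Unexpected" drug relations are
pairs at or above the threshold whose ATC first-level letter sets are
disjoint across all codes of each drug.

## The synthetic world

`generate_world()` builds the test bed: a planted-partition PPI graph
(default 300 proteins, 6 modules, within-module edge probability 0.45,
between 0.01, 3 % isolated nodes — modules emulate dense
complexes/families in a sparse interactome), 60 drugs each assigned a home
module, target sets of 3–6 proteins drawn mostly (90 %) from the home
module, and 5 % of drugs with no targets (mirroring reference sets in
which some drugs lack curated targets).

The pharmacological indexes are built to be *complementary*, the regime
the combined model assumes. Each module owns **two ATC branches**
(distinct first-level letters) and **two fingerprint chemotype
prototypes**; every drug independently picks one branch and one chemotype.
A drug's TS neighbourhood (its branch-mates) and CS neighbourhood (its
chemotype-mates) are therefore two different subsets of the same
target-sharing drug population, so each index alone explains only part of
a target's closeness profile while their combination explains most of it
— the synthetic analogue of similarity matrices whose high-relatedness
blocks are matched sometimes by TS, sometimes by CS, and only jointly by
both. The coupling strengths (defaults 0.8) set the probability that a
drug's index is informative at all: an uninformative drug receives an ATC
class of its own or a background-noise fingerprint, so the two indexes
fail on independent ~20 % subsets of drugs. At zero coupling both
similarities are independent of the network, which the permutation test in
the suite confirms.

What the generator does **not** emulate: realistic interactome degree
distributions (hubs, scale-free tails), graded target affinities,
multi-module drug polypharmacology, correlated failures of the two
indexes, and ATC codes shared across modules at intermediate hierarchy
levels. Passing tests on this world therefore demonstrate internal
consistency of the machinery and the expected qualitative model ordering
under the stated generative assumptions — not performance on real
interactome data.

## Evaluating the three models

On synthetic worlds the discriminating benchmark is **held-out
interaction recovery** (`heldout_model_auc()`): one target of every
multi-target drug is held out, the closeness matrix is rebuilt from the
remaining interactions, and the pooled ROC is computed over the held-out
pairs (3 random splits averaged). A held-out target contributes nothing to
its drug's closeness column, so recovery must come from the similarity
structure — which is exactly where the models differ. The training-set
ROC, by contrast, is dominated at this scale (60 drugs) by each target's
own transfer(0) term and saturates near 0.96 for every model; with
hundreds of drugs that term is one coordinate among many and the
training ROC regains discriminating power, but at desk scale the held-out
variant is the informative one. The suite checks, averaged over five
seeded worlds at generator defaults, that the MS model's held-out AUC
exceeds both single-model AUCs and 0.85.

Problem sizes throughout the suite (worlds of 60×300 with 6 modules for
model comparison, 12×60 for unit-level integration, 2000 trials for the
random-scorer null, 1000 label shuffles for correlation significance)
were chosen as the smallest instances at which the checked effects are
stable across seeds.

## Known limitations

- Closeness uses unweighted shortest paths; confidence-weighted edges or
  diffusion kernels are out of scope.
- The concordance functionals are correlation-based; other fitness
  functionals (e.g. standardized regression contributions) would slot in
  behind the same interfaces but are not implemented.
- Proteins absent from the PPI network can only be scored as isolated
  nodes (their closeness column is driven entirely by self terms).
- The unspecific-protein criterion and the resemblance null model are
  explicit, configurable stand-ins; analyses of real data should examine
  their sensitivity.
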