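---
title: "Coevolutionary scoring and mutational design of hybrid repressors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coevolutionary scoring and mutational design of hybrid repressors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevdesign)
```

## The problem

LacI-family transcription repressors are two-module proteins: a ~47-residue
N-terminal DNA-binding module (DBM) and a large C-terminal ligand-binding
module (LBM). Fusing the DBM of one family member to the LBM of another
yields a hybrid repressor that couples a new inducer to a new operator, but
hybrids are frequently crippled because residue pairs that coevolved across
the module interface no longer match. `coevdesign` predicts small sets of
LBM point mutations that restore native-like inter-module couplings, using
only the statistics of the family alignment plus one reference crystal
structure.

## Model and assumptions

The family is modelled by a global Potts distribution over aligned
sequences,

$$P(S) = \frac{1}{Z}\exp\Big\{\sum_{i<j} e_{ij}(A_i,A_j) + \sum_i h_i(A_i)\Big\},$$

with $q = 21$ states per column (20 amino acids and a single gap state;
ambiguous letters X/B/Z/J/U/O collapse onto the gap so $q$ stays fixed).
The central assumption is that functionally required inter-module contacts
leave a coevolutionary signature — strong direct couplings $e_{ij}$
between DBM and LBM columns — that survives the family's phylogenetic
history once redundancy is corrected for.

Parameters are inferred by mean-field DCA:

1. **Reweighting.** Each sequence gets weight $1/n_m$ where $n_m$ counts
   sequences (itself included) at $\ge$ 80% identity; the identity is
   computed over all $L$ columns with gap=gap counting as a match — the
   simplest convention that is exactly reproducible. $M_\mathrm{eff}=\sum_m w_m$.
2. **Frequencies.** Weighted single and pair frequencies are blended with a
   uniform prior at relative pseudocount $\lambda$ (default 0.5), the
   standard mfDCA regularisation; $\lambda > 0$ is required for the
   inversion below to exist.
3. **Inversion.** The connected-correlation matrix
   $C_{(i,A),(j,B)} = f_{ij}(A,B) - f_i(A)f_j(B)$ is built over $q-1$
   states per column (the gap is the dropped reference state) and
   $e_{ij}(A,B) = -(C^{-1})_{(i,A),(j,B)}$ for $i \ne j$. Fields are
   recovered self-consistently from the single-site frequencies; they enter
   the Hamiltonian and the sampler but not the design scores.
4. **Gauge.** Potts parameters are only defined up to a gauge. All scores
   are reported in the zero-sum gauge (every coupling block has zero row
   and column means), enforced by `to_zero_sum_gauge()` and asserted by the
   scoring functions, because the two design scores are *sums of coupling
   entries* and would otherwise be arbitrary as absolute numbers. The
   conversion provably leaves every likelihood ratio — and hence the whole
   Boltzmann distribution — unchanged, which the test suite verifies by
   exhaustive enumeration.

## The two design scores

$$C(S) = -\sum_{i}^{\mathrm{DBM}}\sum_{j}^{\mathrm{LBM}} e_{ij}(A_i,A_j)
\qquad
SF(S) = -\sum_{(i,j)}^{\mathrm{contacts}} e_{ij}(A_i,A_j)$$

$C(S)$ runs over the top-$K$ coevolving inter-module pairs (default
$K = 1500$, the value used for the LacI family); pairs are ranked by
**direct information** by default — the mutual information of the two-site
distribution induced by the pair's coupling block with marginals matched to
the empirical single-site frequencies, computed by iterative proportional
fitting — with the APC-corrected Frobenius norm as the alternative metric.
The published pipeline does not name its ranking metric; DI matches the
mfDCA method the model descends from, so it is the default, and both are
exposed.

$SF(S)$ runs over residue pairs closer than 10 Å in the reference
structure. The distance definition is not fixed by the 10 Å rule alone; the
default here is the most permissive standard one (minimum over heavy-atom
pairs, `min_heavy_atom`), with `c_alpha` and `c_beta` rules available, and
a minimum sequence separation of 1 (adjacent residues retained, since the
score sums over *all* structural contacts). An optional flag drops contacts
spanning the module boundary; it is off by default because the score's
definition sums over all contacts, and the two modules make very few
physical contacts in any case.

Sign conventions follow the scores' definitions: **more negative is
better** for both, and candidates are judged by deltas relative to the
original hybrid.

## The design loop

`scan_single()` proposes every substitution at every LBM column (19 non-gap
alternatives; wild-type-gap columns are skipped — deletion design is out of
scope; DBM columns are always excluded, and `build_pocket_mask()` can also
exclude ligand-contacting columns). Because $C(S)$ contains only DBM×LBM
terms, the $\Delta C$ of a set of LBM mutations at distinct columns is
*exactly* the sum of the singles' $\Delta C$; `scan_multi()` exploits this
to build double and triple candidates from the top `beam` singles (default
50) without approximation — the optimum over k-sets is reached as long as
the best k distinct-column singles are inside the beam, and the equality of
the additive path with full rescoring is property-tested. $\Delta SF$, in
contrast, is non-additive whenever two mutated columns are themselves in
contact, so it is always recomputed exactly on the mutated sequence.
`select_candidates()` applies the gray-region rule — keep candidates with
`sf_score <= reference_sf` — then truncates by $\Delta C$. Ties in every
ranking break lexicographically by label, making scans byte-reproducible.

## Synthetic data: what it emulates and what it does not

`sample_potts()` draws alignments by single-site heat-bath Gibbs sampling
(burn-in 1000 sweeps, thinning 10, chosen for reliable per-sweep mixing at
the coupling strengths used here; both exposed). Sampling uses R's RNG, so
a seed fixes the alignment byte-for-byte.

`make_planted_scenario()` is the offline stand-in for the family data: a
sparse model whose planted inter-module pairs encode two mutually exclusive
compatible state combinations — DBM state X with LBM state a, DBM state Y
with LBM state b, cross-combinations penalised — plus fields that
concentrate probability on the active states so sampled alignments actually
exercise the couplings. Its defaults (L = 60 with 12 DBM columns, 5 planted
pairs at strength 2, 5000 sequences) are the scale at which the package's
recovery and rescue claims are validated; they are small enough to fit a
model in seconds yet large enough that mean-field inference recovers the
planted pairs essentially perfectly. What the scenario deliberately does
*not* emulate: phylogenetic correlation between sequences (real families
are tree-structured; reweighting mitigates but does not remove this),
indels, multi-state compatibility networks, and the sheer scale of the real
family (74k homologs, ~22k effective sequences). Passing the planted tests
therefore demonstrates correctness of the machinery, not field performance
on any particular family.

`make_toy_structure()` writes minimal PDB chains with residues on a line,
realizing banded contact sets exactly; arbitrary contact graphs are instead
constructed directly as `contact_map` objects.

## Numerical choices

* Pseudocount $\lambda=0.5$ and identity threshold 0.8 are the standard
  mfDCA defaults; the published effective-sequence count is only
  reproducible if the deposited pipeline used matching values, so both are
  configuration, not constants.
* The mean-field inversion solves a dense $(L(q-1))^2$ system; a singular
  matrix (possible at $\lambda = 0$) raises an error advising a larger
  pseudocount rather than silently regularising.
* DI's iterative proportional fitting stops at $10^{-8}$ max-change or
  1000 iterations; with pseudocounted marginals the fixed point is unique
  and reached in tens of iterations.
* Contact distances use strict inequality at the cutoff; contact maps are
  stored with $i<j$ and are rotation/translation invariant by
  construction (property-tested under random rigid motions).
* Scores and deltas are plain coupling sums, so oracle equivalence is
  asserted to $10^{-9}$; gauge and enumeration identities to $10^{-8}$ or
  better.

## Validation surface

The acceptance script (`scripts/acceptance.R`) recomputes, against the
installed package: the score/oracle maximum error (200 random instances),
the $\Delta C$ additivity error (100 random multi-mutant sets) and a
constructed $\Delta SF$ non-additivity gap, the max deviation of the
Boltzmann distribution across the gauge change (27-sequence enumeration),
a chi-square p-value of Gibbs samples against enumerated probabilities
(n = 20,000), planted-pair precision@5 and coupling-sign agreement at the
default scenario scale, the rank of the best planted rescue in an
end-to-end scan of a mismatched hybrid (and whether it survives the SF
filter), and contact-map brute-force/rigid-motion checks. The test suite
asserts the same properties at the same tolerances, plus the per-module
unit behaviour.

## Known limitations

Mean-field inversion is the fastest but least accurate DCA flavour;
pseudolikelihood or Boltzmann-machine learning would give better couplings
at real-family scale but are out of scope, as are phylogenetic corrections
beyond reweighting, insertion/deletion design, multimeric-interface
contacts, and any prediction of experimental induction fold-changes —
scores order candidates, they do not forecast magnitudes. Absolute score
values depend on the gauge convention; published absolute numbers are only
comparable if computed in the same (zero-sum) gauge.
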