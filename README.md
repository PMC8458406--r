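# coevdesign

Rational design of hybrid (chimeric) transcription repressors from the
coevolutionary record of their protein family.

LacI-family repressors are built from two quasi-independent modules: a small
N-terminal DNA-binding module (DBM, ~47 residues) and a C-terminal
ligand-binding module (LBM) that senses the inducer and drives the allosteric
response. Swapping modules between family members ("hybrid repressors",
named DBM-LBM, e.g. a LacI DBM fused to an RbsR LBM) is a powerful way to
wire new chemical inputs to new promoters — but many hybrids are poorly
functional because residue pairs that coevolved across the module interface
are broken by the swap. `coevdesign` is for synthetic biologists and protein
engineers who want to *rescue* such hybrids by a handful of targeted LBM
mutations, predicted purely from sequence statistics of the family.

## The model

The family alignment is modelled as a Potts (maximum-entropy) distribution
over sequences S = (A_1, ..., A_L), q = 21 states (20 amino acids + gap):

    P(S) = (1/Z) exp{ Σ_{i<j} e_ij(A_i, A_j) + Σ_i h_i(A_i) }

Couplings e_ij and fields h_i are inferred by mean-field direct coupling
analysis (mfDCA): sequences are reweighted at 80% identity, single-site and
pair frequencies are regularised with a relative pseudocount λ = 0.5, and
the couplings are read off the inverse of the connected-correlation matrix.
All parameters are reported in the zero-sum gauge, which makes the two
design scores well-defined absolute numbers:

* **Compatibility score** — summed over the top-K (default 1500) coevolving
  inter-module pairs ranked by direct information:

      C(S) = − Σ_{i ∈ DBM, j ∈ LBM} e_ij(A_i, A_j)

  More negative than the original hybrid = a more compatible DBM/LBM pair.
  Because C(S) contains only DBM×LBM terms, the effect of LBM mutations on
  C(S) is exactly additive.

* **Structural fitness score** — summed over residue pairs in physical
  contact (< 10 Å) in a reference crystal structure:

      SF(S) = − Σ_{(i,j) ∈ contacts} e_ij(A_i, A_j)

  A candidate whose SF(S) is less favourable than the original hybrid's is
  likely to disrupt intra-module structure and is filtered out (the
  "gray-region" rule). ΔSF is *not* additive when mutated residues contact
  each other, so it is always recomputed exactly.

The design loop (`scan_single` / `scan_multi` → `select_candidates`)
enumerates all single LBM substitutions (never the DBM, never the gap state,
optionally excluding the ligand pocket), ranks them by ΔC, builds double and
triple candidates from the top singles, and keeps those passing the SF
filter.

Everything is testable offline: `make_planted_scenario()` builds a sparse
Potts model with two "subfamilies" coupled through planted inter-module
pairs, Gibbs-samples an alignment from it, and records which LBM states
rescue which DBM type — the computational analogue of the rescue experiment.

## Worked example

Fit a model to a synthetic family with 5 planted DBM×LBM couplings, build a
deliberately mismatched hybrid, and rescue it:

```r
library(coevdesign)

sc  <- make_planted_scenario(L = 60, q = 21, n_dbm_columns = 12,
                             planted_pair_count = 5, coupling_strength = 2,
                             n_sequences = 5000, seed = 11)
fit <- mfdca(sc$sampled_alignment)
fit
#> Mean-field DCA fit
#>   alignment: M = 5000 sequences, L = 60 columns, q = 21
#>   effective sequences Meff = 5000.0 (identity threshold 0.80)
#>   pseudocount = 0.50, gauge = zero_sum

top <- rank_pairs(fit, metric = "direct_information",
                  restrict_to = inter_module_pairs(sc$partition), top_k = 50)
head(as.data.frame(top), 5)
#>   i  j score
#> 1 4 16 0.573
#> 2 5 17 0.566
#> 3 2 14 0.556
#> 4 3 15 0.553
#> 5 1 13 0.519
```

The five strongest inter-module pairs are exactly the planted ones
((1,13) ... (5,17)). Now assemble the incompatible hybrid (subfamily-X DBM
with subfamily-Y LBM) and scan its LBM:

```r
lbm      <- sc$partition$lbm_columns
contacts <- contact_map(rbind(as.matrix(sc$planted_pairs),
                              cbind(lbm[-length(lbm)], lbm[-1])))
hyb  <- build_hybrid(sc$parent_x, sc$parent_y, sc$partition, "X", "Y")
scan <- scan_single(hyb, fit$model, top, contacts, sc$partition,
                    mask = exclusion_mask(sc$partition$dbm_columns, "dbm"))
scan
#> Mutational scan (1-mutation sets): 855 candidates, reference C = 3.4090, SF = 4.4974
#>  label columns delta_c delta_sf c_score sf_score rank
#>   C14A      14  -6.579   -6.025  -3.170   -1.527    1
#>   C16A      16  -6.050   -6.041  -2.641   -1.544    2
#>   C15A      15  -5.982   -5.810  -2.573   -1.312    3
#>   C17A      17  -5.886   -5.884  -2.477   -1.386    4
#>   C13A      13  -5.563   -5.641  -2.154   -1.143    5

select_candidates(scan, top_n = 3)
```

Every top candidate reverts a planted LBM column from the Y-compatible
state (C) to the X-compatible state (A): the scanner rediscovers the
planted rescues, and all of them also pass the SF filter
(`delta_sf < 0`), so `select_candidates` retains them.

On real data the same pipeline reads the family MSA with
`read_alignment()`, extracts contacts from a PDB structure with
`parse_structure()` + `map_structure_columns()` + `extract_contacts()`
(10 Å heavy-atom rule), and labels mutations in reference-protein numbering
via `numbering_map()` (e.g. K57A). A thin command-line wrapper with
`fit` / `pairs` / `contacts` / `scan` / `simulate` subcommands ships in
`inst/cli/coevdesign`.

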