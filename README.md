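# drugcipher

Genome-wide prioritization of candidate drug targets by relating a drug's
**pharmacological similarity** profile to its network-based closeness to
proteins in a protein–protein interaction (PPI) network.

## The problem

Identifying the protein targets of a small molecule is a central step in
pharmacology. Two classical indicators — a drug's therapeutic
classification (its phenotypic effect) and its chemical structure — each
predict targets only partially, and structure-based methods are usually
limited to proteins that already have known ligands. This package scores
*every* protein in a PPI network for its concordance with a query drug, by
exploiting two empirical regularities: therapeutically similar drugs tend
to act on functionally related proteins, and structurally similar drugs
tend to bind related proteins, where "related" is measured by network
proximity.

## The model

For a reference set of *n* drugs:

- **TS** (therapeutic similarity): for two drugs, the maximum over their
  ATC-code pairs of the information-content code similarity
  `sim(i, j) = 2 log p(prefix(i, j)) / (log p(i) + log p(j))`, where
  `prefix(i, j)` is the longest common ATC level prefix and `p(·)` is a
  prefix's frequency in the drug–ATC assignment corpus.
- **CS** (chemical similarity): the Tanimoto coefficient between binary
  structural fingerprints.
- **Closeness** `phi(p, d) = sum over targets t of d of exp(-L(p, t)^2)`,
  where `L` is the shortest-path distance in the PPI network
  (`exp(-Inf) = 0` for disconnected pairs).
- **Genomic relatedness (GR)**: the mean transfer value over all cross
  pairs of two drugs' target sets.

For a query drug *d* and a protein *p*, the scoring models relate the
drug's similarity vectors `TS_d`, `CS_d` (length *n*) to the protein's
closeness vector `Phi_p` (length *n*):

- **TS model**: concordance = Pearson correlation of `TS_d` and `Phi_p`;
- **CS model**: correlation of `CS_d` and `Phi_p`;
- **MS model**: `Phi_p` is regressed on both vectors (least squares with
  non-negative similarity coefficients and a free intercept) and the
  concordance is the correlation of `Phi_p` with the fitted combination.

Proteins are ranked by descending concordance; high-ranking proteins are
candidate targets. No binary target call is made.

The package also implements the surrounding machinery: leave-one-out
validation with 19 random negative controls per known interaction
(including the exact closeness adjustment for removed targets), pooled
rank-threshold ROC/AUC, fold enrichment of target ranks with a one-sided
exact test, drug "biological fingerprints" (genome-wide MS score vectors)
with unspecific-protein filtering, cosine activity resemblance with a
permutation/empirical significance threshold, extraction of unexpected
drug–drug relations across ATC classes, and a seeded synthetic-world
generator used throughout the test suite.

## Worked example

```r
library(drugcipher)

world <- generate_world(n_drugs = 20, n_proteins = 100, n_modules = 4, seed = 42)
ts  <- ts_matrix(world$drugs)
cs  <- cs_matrix(world$drugs)
phi <- closeness_matrix(world$graph, world$interactions,
                        drug_ids = names(world$drugs))
rank_proteins("D001", model = "MS", ts = ts, cs = cs, phi = phi)
#> <concordance_result> drug D001, model MS, 100 proteins; top 5:
#>   protein_id     score rank
#> 1      P0069 0.8323496    1
#> 2      P0077 0.8244631    2
#> 3      P0020 0.8053335    3
#> 4      P0095 0.7729956    4
#> 5      P0056 0.7341617    5
```

Two of drug `D001`'s four true targets (`P0069`, `P0077`) rank 1st and
2nd; all four rank within the top 12 of 100 proteins. The score is the
correlation between the protein's closeness profile over the 20 drugs and
its best non-negative reconstruction from the drug's TS and CS vectors, so
values near 1 mean the protein's network position mirrors the drug's
pharmacology.

Rank enrichment from a published-style worked example — five known targets
ranked 9, 12, 33, 267 and 305 among 9981 network proteins:

```r
rank_enrichment(c(9, 12, 33, 267, 305), 9981)
#> fold = 32.7, p = 2.58e-08
```

i.e. all five targets fall within the top 305 ranks, a ~33-fold enrichment
over chance.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/drugcipher.R simulate --drugs 60 --proteins 300 --seed 42 --out world/
Rscript inst/cli/drugcipher.R run-all --atc world/atc.tsv \
    --fingerprints world/fingerprints.tsv --targets world/targets.tsv \
    --ppi world/ppi.tsv --out results/
```

`run-all` writes `ts.tsv`, `cs.tsv`, `phi.tsv`, `ranks.tsv`,
`validation_report.tsv`, `fingerprint_map.tsv`, `resemblance_pairs.tsv`,
the resolved configuration and a log.

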