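# apisa

Affinity-propagation-guided iterative signature biclustering of gene
expression matrices, for cohorts whose latent sample groups have very
unequal prevalence — the motivating case being breast-cancer molecular
subtypes (Basal-like, HER2-enriched, LuminalA, LuminalB, Normal-like),
where roughly two thirds of tumors are Luminal and only a few percent
Normal-like. Global clustering recovers only the dominant structure;
`apisa` finds *biclusters* — sample subsets over-expressing gene subsets,
overlapping on both axes — whose sizes track the prevalence structure.

## The method

The iterative signature algorithm (ISA) finds biclusters as fixed points
of an alternating thresholding iteration on an `m x n` samples-by-genes
matrix `E`. With `E_C` the row-standardized and `E_G` the
column-standardized view, a binary sample vector `c` is updated by

```
g  =  z( t(E_C) c / |c| )  >  t_G        (gene selection)
c' =  z( E_G g / |g| )     >  t_C        (sample selection)
```

(`z(.)` standardizes the score vector; `t_G`, `t_C` are thresholds in
score-sd units) until the two support sets stabilize. Plain ISA seeds this
iteration with uniformly random sparse vectors and one global threshold
pair; the results are seed-sensitive and all biclusters come out about the
same size.

`apisa` instead runs affinity propagation (AP) over the samples first,
targeting `K` clusters by bisecting AP's preference parameter. Of 10,000
random 2-sparse seeds, only those falling entirely inside one AP cluster
are kept and grouped by it — with sparsity 2 the retained fraction tends
to the sum of squared cluster proportions, so prevalent groups dominate
the pool. 100 seeds are selected by largest-remainder apportionment of
group sizes, and each group receives its own gene threshold by a
rank-to-range map (largest group, lowest threshold), `t_G in [1, 2]` by
default with constant `t_C = 1`. Every selected seed is iterated to its
fixed point; identical fixed points are pooled with basin counts and
deduplicated by overlap (combined Jaccard > 0.8), keeping the
largest-basin record per overlap component.

Evaluation tools include the overlap-corrected **effective number of
biclusters**

```
F = sum_k (1/|U_k|) sum_{x in U_k} 1/N(x)
```

over the entry sets `U_k` (all (sample, gene) pairs of bicluster `k`,
`N(x)` = number of biclusters containing entry `x`; `F = K` iff the sets
are pairwise disjoint, and `F = r` for `r` groups of identical
biclusters), capture tables and majority-fraction subtype matching
against reference labels (e.g. PAM50 calls), and per-sample mean
methylation beta values in six genomic region categories (TSS200,
TSS1500, 5'UTR, 1st exon, gene body, 3'UTR) restricted to bicluster
sample sets. Seeded generators of planted-bicluster expression and
companion methylation data provide ground truth for benchmarking.

## Worked example

Five planted subtype modules at prevalences 0.30/0.15/0.35/0.15/0.05 in a
200 x 500 matrix (shift 3 noise-sd), recovered end to end:

```r
library(apisa)
inst <- planted_expression(plant_spec(), rng_seed = 1)
cfg  <- apisa_config(rng_seed = 2)
res  <- run_apisa(inst$expr, cfg)
print(res)
#> bicluster_set with 5 records
#> bicluster 'b5': 70 samples x 60 genes (seed group 5, t_G=1, t_C=1, converged)
#> bicluster 'b3': 60 samples x 60 genes (seed group 3, t_G=1.25, t_C=1, converged)
#> bicluster 'b2': 30 samples x 60 genes (seed group 2, t_G=1.625, t_C=1, converged)
#> bicluster 'b1': 30 samples x 60 genes (seed group 1, t_G=1.625, t_C=1, converged)
#> bicluster 'b4': 10 samples x 59 genes (seed group 4, t_G=2, t_C=1, converged)

effective_number(res)
#> [1] 5
```

The five biclusters have 70/60/30/30/10 samples — exactly the planted
prevalence structure, down to the 5% group — and are pairwise disjoint
here, so the effective number equals the raw count (ratio 1.0). Against
the generator's ground truth:

```r
match_modules(res, inst$truth)
#>         sample_jaccard gene_jaccard record
#> module1              1    1.0000000      2
#> module2              1    1.0000000      3
#> module3              1    1.0000000      1
#> module4              1    1.0000000      4
#> module5              1    0.9833333      5
```

Every planted module is recovered perfectly on the sample axis; the
rarest module drops one of its 60 genes at its tight threshold
(`t_G = 2`). A capture table against the latent labels
(`capture_table(res, labels)`) shows each bicluster drawing from exactly
one group.

The same flow is scriptable from a shell via the thin wrapper in
`inst/cli/apisa.R` (subcommands `simulate`, `cluster`, `run`, `metrics`,
`methyl`), e.g.

```sh
Rscript inst/cli/apisa.R run --expr expr.tsv --config cfg.yaml --seed 2 --out biclusters.json
```

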