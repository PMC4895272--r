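# mircore

Discovery of miRNA-mRNA regulatory modules from matched expression
profiles, modelled as *collective group relationships* (COREs).

## What it does and for whom

microRNAs repress their target mRNAs, and they do so in packs: a cohesive
group of miRNAs jointly regulating a cohesive group of mRNAs is usually a
more interpretable and more reproducible unit than any single miRNA-target
edge. Given two matched expression matrices — miRNA features × samples and
mRNA features × samples over the same samples, e.g. tumor panels profiled
on both platforms — `mircore` finds such module candidates and attaches a
quantitative strength to each. It is aimed at computational biologists who
have paired (typically differentially-expressed, log-scale) expression
matrices and want ranked miRNA-group/mRNA-group modules without supplying
prior target predictions, gene-gene interactions, or a module count.

The method is deterministic end to end and needs expression only. A
reference list of experimentally confirmed miRNA-mRNA interactions can be
supplied afterwards to count validated pairs inside each module.

## The method

1. **Interaction weights.** For every miRNA *i* and mRNA *j*, the Pearson
   correlation across samples gives a weight `w_ij = |PCC|` (or `|PCC|` of
   only negative correlations in repression-only mode). A cutoff `η` zeroes
   weights below it while keeping survivors *at their value*, interpolating
   between fully weighted and unweighted bipartite graph mining.
2. **Collaboration scores.** Two miRNAs collaborate when they share
   weighted targets:

   v_ij = (Σ_k w_ik·w_jk)² / (Σ_k w_ik · Σ_k w_jk)

   (for binary weights this is |N(i)∩N(j)|²/(|N(i)||N(j)|)); mRNA-mRNA
   scores use the transposed weight matrix.
3. **Greedy grouping.** Each side is clustered separately by overlapping
   greedy neighbourhood expansion maximizing the cohesiveness

   cs(C) = w_int(C) / (w_int(C) + w_ext(C) + α·|C|),

   seeded in descending total-collaboration order; groups outside the size
   window are dropped (defaults: ≥ 3 miRNAs; 5–500 mRNAs) and near-duplicate
   groups (overlap score ≥ 0.8) are merged.
4. **CORE scoring.** Every (miRNA group, mRNA group) pair is scored by its
   first canonical correlation r = max Corr(aᵀX, bᵀY); pairs with r ≥ ρ
   (default 0.50) are ranked as COREs. Solvers: sparse diagonal-penalized
   CCA (default; suited to groups larger than the sample count), ridge,
   and exact classical CCA for small groups.

See the methods vignette (`vignettes/module-discovery.Rmd`) for the
assumptions, parameter meanings, and numerical conventions.

## Worked example

The built-in generator plants two known modules — (4 miRNAs, 20 mRNAs) and
(5 miRNAs, 30 mRNAs) — in 30 × 60 and 200 × 60 matched noise matrices:

```r
library(mircore)

gen <- generate_planted(planted_scenario(seed = 1))
res <- run_core_discovery(gen$pair, eta = c(0.3, 0.4, 0.5))
res$summary
#>   eta n_cores mean_mrnas mean_mirnas mean_strength
#> 1 0.3       6   23.33333    5.166667     0.8762601
#> 2 0.4       2   25.50000    4.500000     0.8851685
#> 3 0.5       2   25.00000    4.500000     0.8844362
```

Each summary row gives, for one cutoff `η`, the number of COREs and the
mean mRNA count, miRNA count and canonical correlation over them. At
`η = 0.4` the two COREs are exactly the planted modules:

```r
cores <- res$per_eta[["eta_0.40"]]$cores
cores[, c("rank", "strength", "n_mirnas", "n_mrnas")]
#>   rank  strength n_mirnas n_mrnas
#> 1    1 0.9003708        5      30
#> 2    2 0.8699662        4      21
```

(the rank-2 CORE carries one extra background mRNA, membership Jaccard
0.96). Validating the top CORE against the truth-derived reference finds
all of its 5 × 30 = 150 cross pairs confirmed:

```r
ref <- reference_from_truth(gen$truth)
count_confirmed(cores[1, ], ref)$n_confirmed
#> [1] 150
```

Real data enter the same way via `read_expression()` (TSV/CSV, feature
rows × sample columns) and `align_samples()`; `read_reference()` loads a
two-column confirmed-interaction table. `run_core_discovery(...,
out_dir = "...")` writes `summary.tsv` plus per-η `groups.json`,
`cores.json`, `cores.tsv` and `confirmed.tsv`.

## Command line

A thin Rscript front end wraps the exported functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/mircore.R", package = "mircore"))')
Rscript $CLI synth --seed 7 --out data/
Rscript $CLI run --mirna data/mirna.tsv --mrna data/mrna.tsv \
    --reference data/reference.tsv --eta 0.4 --out results/
Rscript $CLI validate --cores results/eta_0.40/cores.json \
    --reference data/reference.tsv
```

`run` accepts `--eta-grid 0:1:0.05` for the standard sweep, a YAML
`--config`, and flags mirroring every pipeline parameter.

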