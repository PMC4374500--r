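# modisa

Network module biomarkers by the discriminative area of functional activity.

## The problem

Single differentially expressed genes make fragile disease biomarkers: they
vary across cohorts, tissues and platforms. `modisa` instead searches a
protein–protein interaction (PPI) network for *modules* — connected sets of
genes whose **joint activity** separates control from case samples — and then
asks which of those modules is functionally coherent with what is already
known about the disease. The package is aimed at anyone with a two-group
expression matrix, an interaction network, and pathway annotations: it takes
plain TSV/GMT inputs, returns tibbles, and chains with the pipe.

## The method

For a module *M* of *k* genes, its activity in each sample is

> a(M) = Σ<sub>g ∈ M</sub> a(g) / √k

where a(g) is the (row z-scored) expression of gene g. Assuming the activity
is normally distributed within each phenotype group, fit N(μ<sub>N</sub>,
σ<sub>N</sub>) to the control samples and N(μ<sub>C</sub>, σ<sub>C</sub>) to
the case samples. The **discriminative area** is the common area under the
two densities,

> disa(M) = ∫ min( φ(x; μ<sub>N</sub>, σ<sub>N</sub>), φ(x; μ<sub>C</sub>, σ<sub>C</sub>) ) dx ∈ [0, 1],

computed in closed form (1 means indistinguishable groups, values near 0
mean clean separation). The pipeline is:

1. **Seeds** — per-gene Welch t-tests, Benjamini–Hochberg adjustment; genes
   with adjusted p < 0.01 seed the search.
2. **Greedy growth** — starting from each seed, repeatedly add the network
   neighbour g<sub>c</sub> ∈ N(M) minimizing disa(M ∪ {g<sub>c</sub>}),
   stopping at disa < δ (= 0.001), when no neighbour improves, or at a size
   cap. Modules with disa > 0.2 are discarded.
3. **Selection** — each surviving module's enriched pathways MF
   (hypergeometric upper-tail test against a catalogue, BH-adjusted) are
   compared with a disease-background pathway set DMF by bidirectional
   best-match Jaccard similarity; the top-scoring module is the candidate
   biomarker.
4. **Validation** — stratified 10-fold cross-validation of a linear-kernel
   SVM on the module's genes, ROC/AUC from pooled held-out decision scores,
   and robustness to artificial label noise in the training folds.

A synthetic-data generator (`generate_instance()`) plants a connected,
group-shifted module in a random network so the whole pipeline can be
exercised — and its recovery quantified — without any external data.

## Worked example

```r
library(modisa)

inst <- generate_instance(synthetic_spec(rng_seed = 42))
inst
#> Synthetic instance: 300 genes x 120 samples, 10-gene planted module (effect 1.5), 872 edges

res <- run_pipeline(inst$expr, inst$labels, inst$net,
                    inst$catalogue, inst$background,
                    config = run_config(rng_seed = 42))
res
#> Module biomarker pipeline run
#>   genes analyzed: 300; seeds: 10; modules surviving: 10
#>   biomarker: M_g0122 (9 genes), disa = 0.01519, score = 0.679
#>   10-fold CV: mean accuracy 0.9833, AUC 0.9978

head(tidy(res), 3)
#> # A tibble: 3 × 5
#>   module_id seed   size   disa score
#> 1 M_g0122   g0122     9 0.0152 0.679
#> 2 M_g0049   g0049     9 0.0181 0.679
#> 3 M_g0024   g0024     8 0.0145 0.599
```

Ten genes reached the seed threshold; each grew into a module and all ten
survived the disa ≤ 0.2 filter. The winning module `M_g0122` overlaps the
planted 10-gene truth with Jaccard 0.9, its group distributions overlap by
only 1.5% of their area (disa = 0.0152), its enriched pathways match the
disease background with similarity 0.679, and its genes classify held-out
samples with 98.3% mean accuracy (AUC 0.998). `autoplot(res$cv)` draws the
ROC curve; `noise_robustness()` and `compare_biomarkers()` reproduce the
robustness and baseline-comparison analyses.

File-based workflows use `read_expression()`, `read_phenotypes()`,
`read_network()` and `read_gene_sets()` (GMT); a thin command-line wrapper
with `simulate | preprocess | seeds | discover | score | evaluate | run`
subcommands lives in `inst/scripts/modisa-cli.R`.

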