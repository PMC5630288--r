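# netora

Network-based interpretation of differential-expression results against a
consolidated protein/gene interactome, with gene-set over-representation
analysis. The package was built around a recurring analysis in miRNA biology:
after inhibiting an oncomiR (here miR-21 in Tsc2-deficient cells under
rapamycin), which functional programs do the responding genes form, and are
those programs enriched for particular pathways and for predicted targets of
the miRNA?

The pipeline has five stages, each exposed as plain functions:

1. **Consolidated interactome (CI).** Interaction exports from several source
   databases (edge-list TSV or a simplified PSI-MITAB dialect) are merged into
   one undirected, deduplicated gene-symbol graph; each surviving edge keeps
   the set of sources that reported it. Self-loops are removed and symbols are
   upper-cased into a common namespace.
2. **DEG selection.** A DESeq2-style results table is thresholded with strict
   symmetric cuts: a gene is differentially expressed when
   `|log2FC| > log2(fc_threshold)` and `p < p_threshold` (defaults FC > 1.5,
   p < 0.05).
3. **Subnetwork and LCC.** The DEG-induced subnetwork keeps CI edges whose
   both endpoints are DEGs; its largest connected component (LCC) is the
   object that gets partitioned.
4. **Spectral modules.** Recursive two-way spectral bisection of the LCC: the
   Fiedler vector of the symmetric normalized Laplacian
   `L = I − D^{−1/2} A D^{−1/2}` proposes each split, a deterministic
   Kernighan–Lin sweep refines it, and the split is kept only if it raises
   Newman modularity
   `Q = Σ_c [ e_c/m − (d_c/2m)² ]` and both sides have at least
   `min_module_size` nodes. Predicted miRNA targets (union of per-algorithm
   prediction lists) are overlaid as node attributes.
5. **Over-representation analysis.** For a foreground of `n` genes in a
   universe of `N`, a term with `K` annotated genes and `k` foreground hits is
   scored with the upper-tail hypergeometric probability `P(X ≥ k)`,
   BH-adjusted across terms, with Storey q-values
   (`q = π̂₀ · BH`, `π̂₀ = min(1, mean(p > 0.5)/0.5)`). Output tables use the
   conventional `Description / GeneRatio / BgRatio / pvalue / p.adjust /
   qvalue` layout.

A synthetic-data module generates every input with known ground truth —
a stochastic-block-model interactome, a DE table with planted signal, gene
sets with planted enrichment folds, and target lists — so the whole pipeline
is testable without any download.

## Worked example

The numbered scripts under `analysis/` run the default synthetic study:

```sh
Rscript analysis/01_simulate.R      # inputs under results/sim/
Rscript analysis/02_network.R       # pipeline artifacts under results/run/
Rscript analysis/03_enrichment.R
Rscript analysis/04_reported_pvalues.R
```

`02_network.R` prints, for seed 1:

```
Pipeline run: CI 200 genes / 1614 edges; 3954 DEGs (1936 up, 2018 down);
  subnetwork 94 genes / 676 edges (1 components, 3860 isolated DEGs);
  LCC 94 genes / 676 edges; 2 modules (Q = 0.473); 44 predicted targets;
  203 terms tested, 3 at adjusted p < 0.05
Planted-block recovery on the LCC: ARI = 1.000 over 94 genes
```

Reading: of 3,954 selected DEGs only the 94 genes with interactome support
form the subnetwork (the rest are isolated); its LCC splits into the two
planted dense modules (modularity 0.473, adjusted Rand index 1.0 against the
planted blocks), and exactly the three planted terms reach adjusted p < 0.05
— `03_enrichment.R` shows them at `p.adjust` between 3.6e-60 and 4.4e-11.

`04_reported_pvalues.R` re-derives a published miR-21 enrichment table from
its printed counts: all 40 reported p-values reproduce to the 3 significant
figures printed (max relative deviation 3.8e-3), e.g.

```r
library(netora)
hypergeometric_pvalue(k = 138, n = 4009, K = 342, N = 20949)
#> [1] 5.20717e-20   # reported: 5.21E-20
```

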