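# atacdeconv

Cell-type deconvolution of bulk chromatin accessibility (ATAC-seq) profiles
with a patch-based transformer, using a labeled single-cell ATAC reference.

## The problem

Bulk ATAC-seq measures chromatin accessibility averaged over every cell in a
sample, hiding cellular composition; single-cell ATAC resolves it but is
sparse and expensive. Given a reference of labeled single cells,
`atacdeconv` treats each bulk profile $x$ over $n$ shared peaks as a mixture

$$x \approx p^\top M, \qquad p \in \Delta^{k-1},\; M \in \mathbb{R}_{\ge 0}^{k \times n},$$

and estimates both the cell-type proportions $p$ and the cell-type-by-peak
signature matrix $M$. It is aimed at epigenomics groups who have bulk ATAC
cohorts and a compatible single-cell (or FACS-sorted) reference.

## The method

* **Patches as tokens.** Shared peaks are ordered genomically and cut per
  chromosome into patches of 50 consecutive peaks. Each patch has its own
  LayerNorm + MLP projection into $\mathbb{R}^d$; a learnable class token is
  prepended.
* **Transformer encoder.** $L = 2$ pre-LayerNorm blocks of multi-head
  self-attention ($h = 4$ heads, $\mathrm{softmax}(qk^\top/\sqrt{d/h})\,v$)
  and MLP, with residual connections. Attention never crosses chromosome
  boundaries at the patch level, so patch–patch attention is interpretable
  as intra-chromosomal co-accessibility.
* **Heads.** Proportions come from a sigmoid MLP head on the class token,
  renormalized to the simplex. Signatures come from a factorized decoder
  $M = \mathrm{ReLU}(W_1 W_2 W_3 W_4 W_5)$ with no biases or intermediate
  activations.
* **Training.** Ground truth is simulated: Dirichlet proportion vectors
  under four regimes (random, rare < 5%, dominant > 50%, near-average),
  realized as pseudo-bulks by aggregating sampled reference cells. The loss
  is $\mathrm{MSE}(P,\hat P) + w_M\,\mathrm{MSE}(M,\hat M) +
  \mathrm{MSE}(x, \hat P \hat M)$. At prediction time an optional adaptive
  phase greedily alternates decoder-only and encoder-only refinement per
  bulk sample, anchored to the post-training solution.
* **Interpretability.** Per-chromosome patch-attention maps are extracted,
  categorized High/Median/Low, and compared with chromatin-interaction
  (Hi-C-like) contact maps by a top-pair overlap statistic with a
  circular-shift permutation test.

Everything — forward pass, backpropagation, Adam — is implemented in
vectorized base R; gradient correctness is enforced by a finite-difference
oracle in the test suite. See the methods vignette
(`vignettes/deconvolution-methods.Rmd`) for model details, defaults and
design rationale.

## Worked example

A desk-scale end-to-end run (3 cell types, 120 peaks, a few seconds):

```r
library(atacdeconv)

cfg <- run_config(n_celltypes = 3, n_peaks = 120, cells_per_type = 30,
                  n_chroms = 2, n_samples_per_regime = 50, n_heldout = 5,
                  n_cells_per_sample = 100, patch_size = 20, d = 16, L = 1,
                  h = 2, decoder_dims = c(8, 12, 16, 24), epochs = 15,
                  adaptive = FALSE, seed = 3)
res <- run_end_to_end(cfg, out_dir = "demo_run", verbose = FALSE)
res$report
#> <metric_report> overall: CCC 0.849, MAE 0.0852, Spearman 0.881 (5 samples, 3 cell types)
glance(res$report)
#> # A tibble: 1 x 4
#>     ccc    mae spearman spearman_per_sample
#>   <dbl>  <dbl>    <dbl>               <dbl>
#> 1 0.849 0.0852    0.881                   1
```

The report says: across the 5 held-out pseudo-bulk samples, predicted and
true proportions agree with concordance (CCC) 0.849 and rank correlation
0.881, with a mean absolute error of 0.085 per proportion entry — and even
this toy run orders the cell types correctly within every sample
(per-sample Spearman 1). `demo_run/` contains the proportions, signatures,
attention table, loss history and a checksum manifest.

At the package's standard study scale (5 cell types, 600 peaks, 4,000
training pseudo-bulks, 22 epochs, ~7 min on one core) held-out proportion
recovery reaches Spearman 0.99 and MAE 0.015, and every decoded signature
row rank-correlates with its true cell-type profile at ρ between 0.91 and
0.95 (see below for how to reproduce these numbers yourself).

A command-line front end with the same stages is in `exec/atacdeconv`
(subcommands `simulate-ref`, `pseudobulk`, `train`, `predict`, `eval`,
`attention`, `overlap-test`, `run-all`).

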