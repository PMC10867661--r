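# dbaae — denoising scRNA-seq counts with a dynamic-batching adversarial autoencoder

Single-cell RNA-seq count matrices contain many technical zeros
("dropout"): transcripts present in a cell but missed by capture or
sequencing. `dbaae` is an R package for researchers who want to recover
cell-type structure from such data. It implements a **dynamic-batching
adversarial autoencoder (DB-AAE)**: a fully connected autoencoder
(encoder input–1024–512–512, mirrored decoder) whose latent space is
shaped by a discriminator (512–256–1) that contrasts the latent code of
the current mini-batch, `z_b = l_e(x_b)`, with the code of the *previous
batch's reconstruction*, `n_r = l_e(x'_prev)`. Training minimises

* reconstruction: `L_rec = -(1/N) Σ [x log x' + (1-x) log(1-x')]`,
* discriminator: `L_disc = -(1/N) Σ [log D(l_e(x)) + log(1 - D(l_e(x')))]`,
* generator: `L_gen = -(1/N) Σ log(1 - D(l_e(x')))` (literal form;
  a conventional non-saturating form is selectable and recommended —
  see the vignette),

each with its own RMSprop optimizer at learning rate 2e-5. The training
batch size is not fixed: a search sweeps a candidate grid, records each
candidate's minimum reconstruction loss and held-out reconstruction
accuracy, selects the best (lowest loss, ties to higher accuracy, then
smaller batch), and retrains at that size.

The package also provides:

* a gamma-Poisson count **simulator** with logistic dropout and known
  group labels (`simulateCounts()`, `applyDropout()`, `fig2Preset()`),
  so everything is testable with no downloads;
* **preprocessing** with dispersion-ranked highly-variable-gene
  selection, per-gene z-scores and unit rescaling, all exactly
  invertible (`preprocessCounts()`, `inverseTransform()`);
* **evaluation** statistics: silhouette over known labels
  (`silhouetteScore()`) and squared Pearson correlation of a supplied
  pseudo-time ordering against annotated stages (`pseudotimeR2()`);
* **I/O**: AnnData h5ad (bridged through the Python `anndata` library),
  MatrixMarket and CSV;
* a command-line front end (`inst/scripts/dbaae`) with
  `simulate | denoise | evaluate` subcommands.

## Worked example

Simulate the six-group dropout benchmark (scaled to 500 cells), denoise
it, and compare the silhouette over the true labels before and after:

```r
library(dbaae)
library(SummarizedExperiment)

cfg <- fig2Preset(nGroups = 6, dropout = TRUE, nCells = 500, seed = 1)
sce <- simulateDataset(cfg)         # genes x cells, labels in colData

den <- denoiseCounts(sce, nTop = 200,
    searchConfig = batchSearchConfig(batchStart = 32, batchEnd = 64,
        batchStep = 32, epochsPerCycle = 5, finalEpochs = 100),
    template = aaeTemplate(genMode = "nonsaturating"), seed = 1)

labels <- colData(sce)$cell_type
ne  <- S4Vectors::metadata(den)$normalized
raw <- meanSilhouette(silhouetteScore(zScores(ne), labels))
fix <- meanSilhouette(silhouetteScore(t(assay(den, "dbaae_denoised")), labels))
c(raw = raw, denoised = fix,
  batch = S4Vectors::metadata(den)$selectedBatchSize)
#>         raw    denoised       batch
#>  0.01567665  0.06698026 32.00000000
```

The raw dropout matrix barely separates the six groups (mean silhouette
0.016); after denoising the same cells score 0.067 — the groups have
become markedly more compact relative to their neighbours. The search
selected batch size 32 (its recorded minimum loss beat batch 64). On
data with no dropout the denoiser leaves clean structure intact, which
is the second property the test suite asserts.

The same run from the shell:

```sh
Rscript inst/scripts/dbaae simulate --genes 200 --cells 500 --groups 6 \
    --dropout --seed 1 --out sim.h5ad
Rscript inst/scripts/dbaae denoise --input sim.h5ad --out den.h5ad \
    --batch-start 32 --batch-end 64 --cycle-epochs 5 --final-epochs 100 \
    --gen-mode nonsaturating --seed 1
Rscript inst/scripts/dbaae evaluate --input den.h5ad --labels cell_type
```

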