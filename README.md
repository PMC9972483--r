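# multiplexTME

Weakly supervised discovery of tumor microenvironment elements (TMEs)
from multi-channel multiplex tissue images.

## What this package does, and for whom

Multiplex immunofluorescence and imaging mass cytometry produce one
intensity channel per antibody marker. Computational pathologists want
to know which *elements of the tissue microenvironment* — local cell
phenotypes, multicellular neighborhoods, and areas where neighborhoods
interact — distinguish patient groups (a subtype, a mutation, a risk
class), using only image-level patient labels, with no cell-level
annotation.

`multiplexTME` implements an end-to-end, interpretable pipeline:

1. **Patch contrastive learning** (`trainPCL()`, `embedImage()`): a
   self-supervised encoder pulls together two augmented views of the
   same image crop and pushes apart views of different crops (NT-Xent
   loss over cosine similarities, temperature τ = 0.5), then converts
   each image into an `L x g` grid of patch embeddings.
2. **Patch graphs** (`buildPatchGraph()`, `mergePatientGraphs()`):
   patches become nodes, 4-adjacent patches are connected, and all
   images of a patient merge into one disjoint graph `G = (Z, A')` with
   a sparse edge list.
3. **The TME model** (`trainTMEModel()`): three parallel assignment
   networks produce row-stochastic matrices — `S_P = softmax(f1P(Z))`
   (phenotypes; deep MLP with skips), `S_N = softmax(f1N(Z, A'))`
   (neighborhoods; a K-hop GNN), and `S_A = f1A(S_N' Z_K, S_N' A S_N)`
   (areas; a GNN on the neighborhood-coarsened graph). **Max-sum
   pooling** keeps each row's maximum and sums columns, giving the
   patient's TME abundance vector `(P, N, A)`; a 1-layer classifier
   `f2` maps abundances to class probabilities. Training minimizes
   cross-entropy plus patch-entropy (sharpen assignments, range [0,1])
   and patient-entropy (prevent pooling collapse, range [-1,0])
   regularizers, end to end from patient labels only.
4. **Interpretability** (`differentialTMEAnalysis()`,
   `predictiveInfluenceRatio()`, `mapTMEToImage()`): leave-one-TME-out
   re-evaluation of the trained classifier flags cohort-level
   predictive TMEs; the per-patient predictive influence ratio
   `PIR = p_full / p_leave-one-out` quantifies how much one TME
   supported one prediction; masks map learned TMEs back onto pixels.

A bundled synthetic-cohort simulator (`simulateCohort()`) generates
multiplex tissues with ground-truth phenotype/neighborhood masks: 8 cell
phenotypes defined by probabilistic expression of 6 markers, 4 cellular
neighborhoods with configurable abundances, prevalences and
attraction/repulsion rules, and seven disease paradigms (PMI1/2, PF1/2,
CCI1/2, NNI1) in which patient types I/II/III differ by marker
intensity, phenotype frequency, cell-cell interaction, or
neighborhood-neighborhood interaction.

## A worked example

A desk-scale phenotype-frequency experiment (patient types differ in the
abundance of phenotype Ph6, at 0/30/60% in neighborhood Nb3):

```r
library(multiplexTME)

cfg <- experimentConfig(
  paradigm   = "PF1",
  n_per_type = 20L,
  image_size = c(200L, 200L),
  n_runs     = 1L,
  pcl   = pclConfig(patch_size = 10L, batch_crops = 48L,
                    embedding_dim = 16L, projection_dim = 16L,
                    max_iters = 300L, learning_rate = 2e-3),
  model = modelConfig(P = 8L, N = 8L, A = 4L, K = 2L, hidden = 32L,
                      epochs = 250L, patience = 250L),
  seed = 33L)
rep <- runSyntheticExperiment(cfg)
cat(sprintf("accuracy %.2f, contrast accuracy %.2f\n",
            rep$accuracy, rep$contrast_accuracy))
#> accuracy 1.00, contrast accuracy 0.84
```

The run simulates 60 patients (types I/II/III differ only in Ph6
abundance), trains the contrastive encoder on the 30 training images,
and classifies the 30 held-out patients perfectly; the contrastive
encoder retrieves the positive view for 84% of anchors on held-out
batches.

The report also carries, per run, the differential-TME table (one row
per learned TME with its abundance-vs-class p-value, Bonferroni
adjusted, a `flagged` column, and per-class mean abundances) and the
interpretability overlap between flagged neighborhoods and the
ground-truth region. `renderReports()` writes the TME-by-marker heatmap,
per-class abundance plots and CSV tables for any completed analysis.

A single simulated tissue with its ground truth:

```r
cfg <- applyParadigm(defaultCohortConfig(c(300L, 300L)), "CCI1", "III")
tt  <- simulateTissue(cfg)
tt$image
#> MultiplexImage: 300 x 300 px, 6 markers (Mk1, Mk2, Mk3, Mk4, Mk5, Mk6)
phenotypeNNDistance(tt$truth, 4, 5)   # attraction -> contact distances
```

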