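# gcanddi

Typed drug–drug interaction (DDI) prediction from drug-induced
transcriptome signatures, for computational pharmacologists and
cheminformaticians working with LINCS-L1000-style data.

Drug-induced expression signatures (977 landmark genes per drug) are a
rich drug representation, but they are noisy: the drug–drug similarity
structure they induce barely correlates with chemical-structure
similarity, undermining the similar-drugs-similar-effects assumption
that interaction models rely on. `gcanddi` addresses this with a
**graph convolutional autoencoder (GCAN)** followed by an **LSTM pair
classifier**:

1. Build the chemical-similarity graph: Morgan fingerprints (radius 2,
   1024 bits), Tanimoto similarity `T(a, b) = |a ∩ b| / |a ∪ b|`, keep
   the top 40 neighbours per row, add a unit self-weight, normalize each
   row to sum to 1 (row-stochastic weights `A`).
2. Embed signatures with a graph convolutional autoencoder. Each layer
   computes `H' = σ(A H W + b)` (tanh on hidden layers); the encoder is
   977 → 640 → 512 and the decoder 512 → 640 → 1024 with a sigmoid
   output. Training minimizes the mean per-bit binary cross-entropy
   between the decoded bits and the drug's Morgan fingerprint, plus an
   L2 penalty (Adam, lr 1e-4, L2 1e-5, dropout 0.3).
3. Classify ordered pairs: the sequence `(f(a), f(b))` of embedded
   drugs feeds a 2-layer, 400-unit LSTM (forget-gate bias 0.7, dropout
   0.5, batch 256, lr 1e-4, L2 1e-5) with a sigmoid multi-label head
   over the DDI-type vocabulary; a concatenation DNN is the baseline.
4. Evaluate with macro-averaged metrics under fivefold cross-validation
   (macro-recall = mean over types of TP/(TP+FN); macro-precision =
   mean of TP/(TP+FP); macro-F1 = their harmonic mean), with paired
   fold-level t-tests between methods, plus similarity-profile
   correlation diagnostics (`1/(d² + 1)` similarity, per-drug Pearson r
   against structure similarity) and a nearest-training-neighbour
   consistency analysis.

A seeded synthetic-data generator (`simulation_config()`,
`simulate_drugs()`, `simulate_ddis()`) plants latent structural classes
so the entire pipeline — graph, embedding, classification, evaluation —
is exercised and tested without any external download. The documented
tab-separated text formats (`read_drug_table()`, `read_ddi_list()`,
`import_l1000_signatures()`, `prepare_ddi_dataset()`) are the interface
for real data.

## A worked example

```r
library(gcanddi)

cfg <- simulation_config(n_drugs = 60, n_classes = 3, fp_bits = 64,
                         sig_dim = 50, expr_noise_sd = 2, n_types = 4,
                         n_pairs = 400, seed = 7)
drugs <- simulate_drugs(cfg)
pairs <- simulate_ddis(drugs, cfg)
graph <- build_similarity_graph(drugs, k = 10)
graph
#> <similarity_graph> 60 drugs, 600 directed edges (row-stochastic)

model <- train_gcan(drugs, graph,
                    gcan_config(encoder_dims = c(50, 32, 16),
                                decoder_dims = c(16, 32, 64),
                                learning_rate = 1e-2, epochs = 150))
model
#> <gcan_model> kind=gcan, 60 drugs, embedding dim 16, 123 epochs, final loss 0.3041
emb <- embed_drugs(model, drugs)

# does embedding restore the structure correlation the noise destroyed?
corr <- structure_correlation_table(
  drugs, list(original = drugs[c("drug_id", paste0("g", 1:50))], gcan = emb)
)
dplyr::summarise(dplyr::group_by(corr, feature_kind),
                 median_r = median(r, na.rm = TRUE))
#>   feature_kind median_r
#> 1 gcan           0.964
#> 2 original       0.0862

cv <- fivefold_cv(pairs, emb, method = "lstm",
                  config = lstm_config(units_per_layer = 32,
                                       learning_rate = 3e-3, epochs = 120,
                                       batch_size = 64, dropout = 0.2),
                  feature_kind = "gcan")
cv
#> <ddi_cv> LSTM on gcan features (5 folds): F1 100.0% ± 0.0%, recall 100.0% ± 0.0%, precision 100.0% ± 0.0%
```

The raw signatures' similarity profiles barely correlate with chemical
structure (median r ≈ 0.09) while the GCAN embedding restores the
correlation (median r ≈ 0.96), and the embedded features let the LSTM
recover the planted interaction types perfectly under cross-validation.
`run_feature_model_grid()` reproduces the full feature-by-method
comparison table (original / autoencoder / GCAN × DNN / LSTM) with
paired p-values in one call, and `autoplot()` / `plot_grid_results()` /
`plot_correlation_distribution()` draw the standard figures.

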