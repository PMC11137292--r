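# gcfe — Gershgorin Circle Feature Extraction for biomedical time series

Spectral features of a signal's visibility graph — the eigenvalues of its
Laplacian — are informative for classifying neural spikes and EEG states,
but a full eigendecomposition costs O(N³) per epoch and dominates the
runtime of any real-time pipeline. `gcfe` implements a cheaper summary:
instead of computing eigenvalues, it records where the Gershgorin circle
theorem *confines* them.

For each fixed-length epoch the pipeline is:

1. **Normalize** the recording to [0, 1] against its full-recording
   extrema and segment it into non-overlapping epochs of N samples.
2. **Visibility graph.** Samples become nodes; nodes *i* and *j* are
   joined when the straight line between (i, qᵢ) and (j, qⱼ) passes
   strictly above every intermediate sample. Each edge carries the weight

   ```
   w_ij = | q_i − q_j | / | i − j |  +  1e-8
   ```

   (absolute slope in sample-index units, floored away from zero). The
   dual-perspective variant (WDPVG) unions this graph with the visibility
   graph of the reflected signal.
3. **Modified weighted Laplacian.** `L = D − A`, where `A` is the
   *weighted* adjacency and `D` the diagonal of *unweighted* degrees.
   Because normalized epochs keep every weight ≤ 1 + 1e-8, each integer
   diagonal entry dominates its absolute off-diagonal row sum, so `L` is
   (near-)strictly diagonally dominant and positive semi-definite.
4. **Gershgorin features.** Disk radii `r_i = Σ_{j≠i} |L_ij|` and centers
   `c_i = L_ii`. Every eigenvalue of `L` lies in the union of disks
   (c_i, r_i); the 2N-vector `[r; c]` is the epoch's feature
   representation, at O(N²) total cost and with no eigensolver.

The package also ships a seeded simulator for synthetic extracellular
action potentials (damped-cosine templates under a Gaussian envelope,
Poisson firing at 3.3 Hz, 20 kHz sampling, Gaussian noise at configurable
levels) plus a five-class surrogate EEG generator, and a classifier
harness: the reference 1-D CNN (conv[32 filters, kernel 3] → max-pool
blocks → dense(100) → dropout(0.1) → dense(100) → softmax, Adam,
cross-entropy) implemented in base R, with an SVM alternative.

## Worked example

The five-sample epoch `Q = [0.6, 0.4, 0.1, 0.5, 0.7]`:

```r
library(gcfe)
f <- extract_features(c(0.6, 0.4, 0.1, 0.5, 0.7), graph = "wvg")
print(f)
#> <gcfe_features> wvg, N = 5 (10 features)
#>   radii:   0.258 0.65 0.7 0.683 0.325
#>   centers: 3 4 2 4 3
```

Node 3 (the valley) sees only its two neighbours, so its center — its
degree — is 2, while its radius 0.700 = 0.3 + 0.4 sums the two steep
slopes flanking it. All five eigenvalues of `L` lie inside the union of
the disks (3, 0.258), (4, 0.650), (2, 0.700), (4, 0.683), (3, 0.325).

A small end-to-end run on simulated spikes (four classes: three spike
templates plus noise, noise level 2.0):

```r
es    <- simulate_dataset1(n_per_class = 100, snr = 2.0, duration = 60, seed = 7)
feats <- extract_features_batch(es, graph = "wvg")   # 400 x 112 (+ label)
train_eval(feats, arch = "cnn", seed = 7)
#> <eval_report> cnn | test n = 60
#>   accuracy     96.67 %
#>   sensitivity  96.67 % (macro)
#>   specificity  98.89 % (macro)
```

Accuracy is the test-split fraction correct; sensitivity and specificity
are macro-averaged one-vs-rest. The `snr` argument is a noise *level*
(noise sd = level × RMS of the clean recording): the conventional series
0.5 / 1.25 / 2.0 is monotonically harder.

From a shell, the same pipeline is available as subcommands:

```sh
Rscript inst/scripts/gcfe-cli.R simulate --out_dir out --n_per_class 100 --snr 2 --seed 7
Rscript inst/scripts/gcfe-cli.R extract  --input rec.txt --epoch_len 56 --out features.csv
Rscript inst/scripts/gcfe-cli.R classify --features features.csv --out_dir out --seed 7
```

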