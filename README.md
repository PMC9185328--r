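# gtotune

Hyperparameter optimization for transfer-learning image classifiers with
the Artificial Gorilla Troops Optimizer (GTO), built for brain-MRI-style
classification pipelines (e.g. staging Alzheimer's disease from axial MRI
slices).

Choosing the loss function, batch size, dropout, how much of a pretrained
backbone to unfreeze, the weight optimizer, the pixel-scaling convention
and the data-augmentation settings is a discrete-continuous search problem
that dominates classifier quality in this domain. `gtotune` encodes one
full training configuration as a vector $x \in [0,1]^{16}$ and minimizes a
black-box fitness over that hypercube with GTO — a swarm metaheuristic in
which candidate solutions are "gorillas", the incumbent best is the
"silverback", and each iteration alternates exploration moves (migration,
approaching other gorillas, moving to a known place) with exploitation
moves (following the silverback while the decay coefficient
$C = (\cos 2r + 1)(1 - t/T)$ is large, competition-for-adult-females
moves once it is small), under strict greedy acceptance.

A solution element $v$ decodes over an ordered domain of $L$ values via

    idx = clamp(ceil(v * L), 1, L)

so 0.75 over the batch-size grid 4,8,...,48 (12 values) gives index 9 —
batch size 36 — and continuous domains interpolate linearly. The package
also ships everything around the optimizer: SNR-based image cleaning
(threshold 1.15), bicubic resizing to 128×128×3, four scaling techniques,
stratified 85/15 splitting, augmentation-based class balancing, a
micro-averaged multi-class confusion-metrics suite, a CPU-trainable
classifier harness implementing all 6 searched losses and 11 searched
optimizer update rules, and a seeded synthetic brain-image generator with
ground-truth noisy images, so the entire loop runs and is tested at desk
scale with no external data.

## Worked example

```r
library(gtotune)

# the 16-dimensional search space and the index-mapping rule
sp <- build_default_space()
sp$D                                     # 16
map_element(0.75, sp$specs$batch_size)   # 36

# rate metrics from published benchmark confusion counts
cc <- confusion_counts(TP = 12360, TN = 37953, FP = 423, FN = 432, K = 4)
m <- derive_rate_metrics(cc)

# a scaled-down end-to-end run on synthetic 3-class data
res <- run_pipeline(run_config(
  synthetic = synthetic_spec(K = 3, n_per_class = 15,
                             image_size = c(32, 32),
                             noisy_fraction = 0.1, seed = 7),
  population = 4, iterations = 2, epochs = 1, seed = 7))
```

Output:

```
D = 16
batch size for element 0.75: 36

precision 96.69% | recall 96.62% | specificity 98.90% | MCC 95.54%

[..] generating synthetic dataset (K=3, n=15/class)
[..] SNR cleaning at 1.15 removed 4 images
[..] starting GTO: N=4, Tmax=2, D=16
[..] finished: best fitness 0.3171

  iteration best_fitness
1         1    0.3170732
2         2    0.3170732

<hp_config>
  loss: hinge | batch: 12 | dropout: 0.434 | learn ratio: 58%
  optimizer: rmsprop | scaling: standardize
  augmentation: off (sub-parameters inactive)
best fitness 0.3171 (accuracy 0.6829)
```

Reading the output: the pipeline generated 45 images (4 of them injected
pure-noise images that the SNR filter removed, exactly matching the
generator's ground truth), ran a population of 4 gorillas for 2 iterations
(each fitness evaluation trains the toy classifier for 1 epoch), and
reports the best decoded configuration with its fitness `1 - accuracy` on
the evaluation set. The per-iteration best-fitness trace is non-increasing
by construction. At study-scale settings (`run_config()` defaults:
population 10, 10 iterations, 5 epochs) the same call performs the full
search; `reference_metric_report()` recomputes the shipped benchmark metric
tables from their confusion counts and flags the cells that are not
arithmetically consistent with them.

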