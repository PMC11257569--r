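# spikeTempo

Feedforward neural pathways repeatedly converge (many neurons onto few) and
diverge (few onto many). A population sitting downstream of a convergence —
a structural bottleneck — has few neurons available to represent its input
and can compensate by coding with precisely timed spikes instead of spike
counts. spikeTempo is an R package for studying this relationship
end-to-end: it simulates and trains feedforward spiking neural networks
with controllable convergence/divergence, and quantifies each layer's
coding strategy by decoding and information-theoretic analysis of its spike
trains at multiple temporal resolutions.

The package is aimed at computational neuroscientists who want a
self-contained, reproducible pipeline for structure-versus-coding
questions: every stimulus is generated in-package, every random draw is
seeded, and every result table is reproducible from a config and a seed.

## What it computes

* **Maximum-entropy bounds.** With window `T` and refractory period
  `tau_ref`, `nbins = T/tau_ref` spike slots give a count-code bound
  `Hc = log2(nbins + 1)` and a timing-code bound `Ht = nbins` bits per
  window (times `N` for a population). Timing always dominates:
  a small population can match a larger one's capacity only by refining
  its temporal code.
* **Spiking networks.** Alpha (spike-response) and leaky
  integrate-and-fire neurons; quadrant- or direction-tuned input encoding;
  sparse signed weights (`p = 0.7`, N(0, 1/(p Npre))); training by
  backpropagation through time with a fast-sigmoid surrogate gradient
  against a dual readout `z = γ z_time + (1 − γ) z_count` (γ = 0.5) that
  does not bias the network toward either coding strategy.
* **Binned decoding analysis.** Sliding 50 ms windows binned at
  `Δt ∈ {1, 2, 5, 10, 25, 50}` ms; LSTM/GRU sequence decoders (bin axis =
  sequence axis) or a ridge baseline, chronological train/val/test splits,
  Gaussian-process hyperparameter search. Information curves (R² or KSG
  mutual-information rate vs Δt), their least-squares slopes, accuracy
  gains ΔR² = R²(5 ms) − R²(50 ms), and one-sided rank-sum comparisons
  across network seeds.
* **Single-neuron decomposition.** Im(s, R) = Im(s, Rc) + Σᵢ p(Rc = i)
  Im(Rt, s | Rc = i): a spike-count term plus a conservative spike-timing
  term, estimated with a hand-rolled Kraskov–Stögbauer–Grassberger
  estimator (tie-broken, chunked, bits).

## Worked example

Train a bottleneck autoencoder on a 4 + 20 Hz stimulus and ask whether its
hidden layer needs fine temporal resolution:

```r
library(spikeTempo)

s   <- sumOfSines(4, 20, duration = 2000, seed = 1)   # 2 s, 2 channels
net <- spikeNetwork(c(100, 10, 100), seed = 2)         # convergent hidden layer
tr  <- trainNetwork(net, s, epochs = 30, lr = 2e-3)
round(range(tr$lossTrace), 3)
#> [1] 0.280 5.754

rasters <- simulateNetwork(tr$net, s)
r2 <- sapply(c(5, 50), function(dt) {
  br  <- binSpikes(rasters$hidden, s, T = 50, deltaT = dt, stride = 4L)
  dec <- fitDecoder(br, architecture = "gru", hidden = 16, lrGrid = 3e-3,
                    epochs = 80, searchBudget = 1, minSamples = 100, seed = 1)
  decoderTestScore(dec, br)$r2
})
round(r2, 3)
#> [1] 0.946 0.715
```

Reading the output: the 10-neuron hidden layer reconstructs the stimulus
almost perfectly from 5 ms bins (R² = 0.95) but loses the 20 Hz component
from 50 ms counts (R² = 0.72) — an accuracy gain ΔR² ≈ 0.23 for the
temporal code. Rerunning with a divergent hidden layer
(`c(100, 1000, 100)`) gives ΔR² ≈ 0.01: expansion layers decode equally
well at either resolution, bottlenecks need spike timing.

The entropy-bound view of the same asymmetry:

```r
entropyBoundTable(15, 5, nNeuronsGrid = c(1, 10))
#>   nNeurons countBits timingBits countRate timingRate
#> 1        1         2          3 0.1333333        0.2
#> 2       10        20         30 1.3333333        2.0
```

Full experiments (hidden-size sweeps, frequency sweeps, the five-layer
visuomotor pathway model) run from `runThreeLayerSweep()`,
`runFrequencySweep()` and `runFiveLayer()`, or from a YAML config via
`runExperiment()` / `inst/scripts/run_experiment.R`. See the vignette
(`vignettes/spike-timing-vs-count.Rmd`) for the model, estimators and
design choices.

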