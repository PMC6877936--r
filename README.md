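# dgsnn — pattern separation and integration in a spiking dentate gyrus with adult neurogenesis

`dgsnn` is a computational-neuroscience simulator for researchers studying
how the dentate gyrus (DG) regulates the coding distance between memories.
It implements a spiking network of the DG driven by lateral entorhinal
cortex (LEC) input, with:

* adaptive exponential integrate-and-fire (AdEx) neurons for the four DG
  cell types — granule (GC), mossy (MC), basket (BC) and HIPP (HC) cells;
* conductance-based AMPA/GABA synapses with delay and exponential decay;
* spike-timing-dependent plasticity (STDP) on the perforant path (LEC→GC);
* adult neurogenesis: newborn granule cells born during stimuli that mature
  through five stages, each with its own excitability, inhibition
  attenuation and input-wiring propensity.

The scientific quantities at its core are the cosine similarity between
population rate vectors, `Sim(A, B) = A·B / (|A||B|)`, and the pattern
separation index comparing input (EC) and output (GC) coding similarity:

    PSI = (Sim_EC − Sim_GC) / Sim_EC        if Sim_EC > Sim_GC  (separation)
    PSI = (Sim_EC − Sim_GC) / (1 − Sim_EC)  if Sim_EC < Sim_GC  (integration)

`PSI > 0` means the DG pushed the two input patterns apart; `PSI < 0` means
it pulled them together. The package drives two experiment types: a
factorial sweep of PSI over neurogenesis rate × stimulus time interval ×
input similarity, and a multi-context concept-coding experiment in which 14
contexts of 4 concepts each reorganise the granule-cell code across repeated
presentations.

## A worked example

Train a 200-GC network (neurogenesis at 3 neurons/s) on a pair of concepts
with 30% input similarity, presented back-to-back, then test each concept
with plasticity and neurogenesis frozen:

```r
library(dgsnn)

cfg <- network_config("200gc", neurogenesis_rate = 3)
cfg
#> <dg_config preset=200gc LEC=100 GC=200 MC=50 BC=25 HC=50 ng=3/s maturation=5s dt=0.1ms>

rec <- run_pair_trial(cfg, time_interval = 1, input_similarity = 0.3, seed = 42)
as.data.frame(rec)
#>   neurogenesis_rate time_interval input_similarity seed sim_ec sim_gc    psi n_gc
#> 1                 3             1              0.3   42  0.278  0.652 -0.518  206
```

The test-phase EC similarity (0.278) recovers the constructed 30% input
overlap up to Poisson noise. The granule-cell similarity is far higher
(0.652): the two concepts arrived one second apart, so they share newborn
cells and potentiated synapses, and the network *integrates* them
(PSI = −0.52). The granule layer grew from 200 to 206 cells — three births
during each 1 s stimulus. Lower-level building blocks (`build_network()`,
`simulate_network()`, `make_pattern_pair()`, `rate_vector()`,
`cosine_similarity()`, `psi()`) are exported and documented, and experiment
results come back as tibbles with `tidy()` / `glance()` / `autoplot()`
methods:

```r
sweep <- run_psi_sweep(rates = c(0, 3), intervals = c(1, 5),
                       similarities = c(0.1, 0.3, 0.7), n_runs = 5)
glance(sweep)    # per-cell mean ± sd of PSI
autoplot(sweep)  # PSI against input similarity, one panel per rate
```

For the multi-context experiment and the synthetic reference matrix that
stands in for a human concept-norm similarity matrix, see
`run_context_experiment()` and `synth_reference_matrix()`; the methods
vignette (`vignettes/dentate-gyrus-model.Rmd`) explains the model, its
numerical choices, the calibration of the projection ratios, and the
regimes the implementation does and does not reproduce.

A thin command-line front end is included at `inst/cli/dgsim.R`:

```sh
Rscript inst/cli/dgsim.R sweep --rates 0,3 --intervals 1,5 --runs 3 --out out/
Rscript inst/cli/dgsim.R psi --sim-ec 0.8 --sim-gc 0.4
```

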