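---
title: "A spiking dentate gyrus model with adult neurogenesis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking dentate gyrus model with adult neurogenesis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgsnn)
```

## The scientific question

The dentate gyrus (DG) sits at the entrance of the hippocampus and regulates
the *coding distance* between memories: similar inputs can be pushed apart
(pattern separation) or pulled together (pattern integration). It is also one
of the two brain regions with substantial adult neurogenesis, and newborn
granule cells have repeatedly been implicated in both phenomena. `dgsnn`
implements a spiking-network model of this circuit and asks how three factors
shape the input-to-output similarity mapping: the neurogenesis rate, the
temporal distance between two stimuli, and the similarity of their input
codes. A second experiment presents many concepts organised into contexts and
tracks how the population code reorganises with repeated exposure.

## Circuit and neuron model

The network has an input layer of lateral-entorhinal-cortex (LEC) neurons,
modelled as independent Poisson sources, and four DG cell types modelled as
adaptive exponential integrate-and-fire (AdEx) neurons: granule cells (GC,
excitatory, the output layer and the only type with neurogenesis), mossy
cells (MC, excitatory feedback), and two GABAergic interneuron types — basket
cells (BC, feedforward perisomatic inhibition) and HIPP cells (HC, feedback
inhibition). The membrane equation is

$$C_m \dot V = g_l (E_l - V) + g_l \Delta_T e^{(V - V_T)/\Delta_T}
  + I_{syn} + I_{inj} - w, \qquad
  \tau_w \dot w = \alpha (V - E_l) - w,$$

with a reset $V \leftarrow V_{reset}$, $w \leftarrow w + b$ whenever $V \ge
V_{thr}$ ($V_{thr} = V_T$; no refractory period). Granule cells use
$\Delta_T = 0$, the hard-threshold limit in which the exponential term is
dropped. Per-type constants are in `neuron_param_table()`. Capacitances are
stated in nF and conductances in nS; with currents in pA and time in ms the
integration uses the capacitance in pF (1 nF = 1000 pF).

Synapses are conductance-based with a delayed instantaneous rise and a
single-exponential decay: a presynaptic spike at $t_s$ contributes
$g(t) = g_{max} \, e^{-(t - t_s - t_{delay})/\tau_{decay}}$ for
$t \ge t_s + t_{delay}$ ($t_{delay} = 2$ ms, $\tau_{decay} = 6$ ms), and the
current is $I = g \,(E_{syn} - V)$ with $E_{AMPA} = 0$ mV and $E_{GABA} =
-80$ mV, so AMPA input depolarises and GABA input hyperpolarises. The eight
pathways are LEC→GC (plastic), LEC→BC, GC→MC, GC→HC, MC→GC, MC→HC, BC→GC and
HC→GC, with maximum conductances per network-size preset in `gmax_table()`.

## Plasticity

The perforant path (LEC→GC) is plastic under pair-based STDP with soft
bounds: a causal pairing (pre before post, lag $\Delta t$) potentiates by
$(w_{max} - w)\,\eta_+ e^{-\Delta t/\tau_+}$ and an acausal pairing depresses
by $w\,\eta_- e^{-|\Delta t|/\tau_-}$, with $w_{max} = 2$, $\tau_+ = 20$ ms,
$\tau_- = 12$ ms and $\eta_\pm = 0.1$. Weights multiply the pathway's
$g_{max}$ and start at 1 (mid-range, leaving headroom in both directions).

Pairing uses the *reduced nearest-neighbour* scheme: each postsynaptic spike
pairs with the most recent strictly-earlier presynaptic spike and vice versa,
and every spike contributes at most one pairing per synapse in each
direction. The reduction matters here: with the published parameter scales a
granule cell can emit a short burst for a single presynaptic event, and an
unreduced nearest-neighbour rule would let one presynaptic spike potentiate
once per burst spike, saturating the weight in a single event and locking
unselective "hub" cells into every representation. The reduced scheme is a
standard variant in the STDP literature and keeps single-event updates
bounded by $\eta$.

## Adult neurogenesis

During training, new granule cells are born at the configured rate while a
stimulus is present: `round(rate × duration)` births per stimulus, evenly
spaced within its window. Maturation spans five equal stages over the
maturation period (default 5 s, scaled variants 10/20 s):

* extra injected current of 100, 50, 20, 0, 0 pA per stage (heightened
  intrinsic excitability of immature cells);
* GABA conductance onto the cell multiplied by 0.2, 0.6, 0.8, 1.0, 1.0
  (immature cells receive weaker inhibition);
* at birth and at each stage entry during a stimulus, the cell gains
  perforant-path synapses from a fraction 0.4, 0.3, 0.2, 0.1, 0.1 of the
  *currently active* LEC neurons (rounded up, duplicates skipped) — newborn
  cells preferentially wire to whatever is driving the network when they
  grow.

Stages 4 and 5 are identical (sustained mature state); stages never regress,
and there is no cell death. Newborn efferents (GC→MC, GC→HC) and inhibitory
afferents (BC→GC, HC→GC) are wired at the standard pathway probabilities at
birth. Births only occur inside stimulus windows; stage transitions that
happen between stimuli add no wiring (there is no active set to wire to).

## Stimuli and measures

A concept is a binary LEC code: 10% of LEC neurons fire at 40 Hz, the rest at
0.1 Hz background. `make_pattern_pair()` constructs pairs whose active sets
overlap by exactly the requested fraction, so the binary-code cosine equals
the target similarity by construction. `make_context_set()` draws 14 contexts
× 4 concepts by rejection sampling with all pairwise similarities below 0.5.

Population codes are compared with the normalised dot product (cosine) of
per-neuron firing-rate vectors, and the pattern separation index combines
input (EC) and output (GC) similarities:

$$PSI = \frac{Sim_{EC} - Sim_{GC}}{Sim_{EC}} \;\text{(separation, > 0)},
\qquad
PSI = \frac{Sim_{EC} - Sim_{GC}}{1 - Sim_{EC}} \;\text{(integration, < 0)},$$

with $PSI = 0$ when the two are equal (both branch limits agree, so the index
is continuous). A zero rate vector is defined to have similarity 0 to
anything, with a diagnostic. Matrix-level comparison (context experiment)
applies the same cosine to the flattened strict upper triangles — the unit
diagonal is excluded so it cannot inflate agreement.

## Experiment protocols

A pairwise trial has a training phase — stimulus A at $t = 0$, stimulus B at
the onset-to-onset interval (1 s means immediate succession), plasticity and
neurogenesis on — and a test phase in which each concept is presented for 1 s
with plasticity, births and maturation frozen. Each test presentation starts
from a reset dynamic state (resting potentials, zero conductances); stage
phenotypes (injected current, attenuated inhibition) persist because the
cells are still immature, merely not advancing. Rates are computed over the
full presentation. We also evaluated a continuous test protocol in which
concepts follow each other without reset; it left inhibitory tone from one
concept leaking into the next and matched the published regime structure
less well, so the per-concept reset is the default.

The context experiment trains on all contexts sequentially (concepts within a
context in fresh random order per pass, back-to-back 1 s stimuli), repeats
the full pass 1–5 times, then tests all 56 concepts and compares the GC
similarity matrix against a reference. Because the human property-norm
database used for evaluation is external, the package ships
`synth_reference_matrix()`, a synthetic block-structured stand-in (within
context 0.6, across 0.1, optional truncated noise); a loader for a real
concept-by-feature CSV is provided (`feature_matrix_similarity()`).

## Numerical scheme

The network integrates at $dt = 0.1$ ms with an exponential-Euler update:
exact for the linear conductance part, explicit for the AdEx exponential and
the adaptation current. This choice is forced by the parameter scales: the
granule cell has $C_m = 6.7$ pF and $g_l = 0.03$ nS while single inhibitory
synapses reach 120 nS, so the voltage equation is stiff and plain forward
Euler diverges at this step. Inside the spike-initiation zone
($V > V_T - 5\Delta_T$) the step is refined fivefold (deterministically), so
that the explicitly-treated exponential does not bias spike times; the
production integrator agrees with a 1 µs forward-Euler reference to ~0.2 ms
on the first-spike benchmark. The exponent argument is capped at +10 before
exponentiation; spike detection is a threshold test after the update with no
interpolation. A single-neuron forward-Euler surface (`adex_step()`,
`adex_spike_times()`) is kept for validation.

LEC Poisson spikes are drawn per step as Bernoulli events with
$p = r\,dt$; all randomness flows through R's RNG, so a single `set.seed()`
makes whole experiments bit-reproducible. Sweep cells derive their seeds
deterministically from a base seed (`cell_seed()`).

## Calibration of the projection ratios

The membrane and conductance tables fix everything except the pathway
connection probabilities, which are exposed as configuration
(`default_conn_prob()`). The defaults were calibrated once against four
internal coding invariants measured on untrained networks — fewer than 20% of
mature granule cells recruited by a 1 s stimulus (sparse coding); high
test–retest similarity for the same concept; a low similarity floor between
unrelated concepts; and graded tracking of intermediate input overlap — and
frozen: LEC→GC 0.03, LEC→BC 0.3, GC→MC 0.05, GC→HC 0.2, MC→GC 0.01, MC→HC
0.2, BC→GC 0.4, HC→GC 0.4. Two features are worth explaining. First, the
perforant receptive fields are small (≈3 LEC afferents per GC) because single
EPSPs at the published conductance scale are suprathreshold for the tiny
granule-cell membrane; selectivity must therefore come from *which* afferents
a cell has, gated by the inhibitory veto, rather than from subthreshold
summation of many weak inputs. Second, the recurrent excitatory ratios
(GC→MC, MC→GC) are small because any mossy EPSP fires an uninhibited granule
cell; larger values flood the code with pattern-unspecific activity.

## What the synthetic data do and do not emulate

The generators reproduce the statistical structure the experiments need —
binary codes with exact pairwise overlap, Poisson spiking at the nominal
rates, block-structured reference similarity — but not the content of real
concept norms: feature vectors, their skewed frequency distributions, or
semantic relations between contexts. Passing the context-experiment checks
therefore shows that the network reorganises codes toward *a* block
structure under repetition, not that it reproduces human similarity
judgements for particular words.

## Replication scope and known limitations

The default test and acceptance runs use the 200-GC preset with a 5 s
maturation period and reduced replication (5–10 seeded runs per design cell,
two seeds for the context experiment); the 400/1000-GC presets and the
10/20 s maturation variants are supported through configuration but not
exercised by default. Within those conditions the package reproduces: the
irrelevance of the stimulus interval without neurogenesis; weak integration
at low input similarity and weak separation above 20% similarity without
neurogenesis; integration of temporally close stimuli with neurogenesis; and
the growth-then-plateau of the context-code match with repetition.

Two published regimes do **not** emerge from this implementation and are
reported as genuine mismatches rather than worked around. With neurogenesis
at 3 neurons/s the model integrates at *every* stimulus interval: the
developing cells' pattern-independent firing (they respond at ~20–30 Hz even
to unrelated concepts — about 17% of their preferred-concept rate — by firing
through transient lulls in inhibition) dominates the sparse mature code, so
far-apart stimuli never tip into net separation, and the input–output
similarity curve stays above the diagonal below 50% input similarity. Both
behaviours trace to the same mechanism, which also keeps the across-context
granule similarity in the context experiment above its input-code
counterpart (within-context integration and the within > across ordering do
reproduce). A model variant in which inhibitory tone never lapses (dense
MC→HC feedback) was evaluated and did not improve the developing cells'
selectivity. Other limitations follow the modelled
system: no CA3, no activity-dependent neurogenesis rate, no cell death, and
an accelerated maturation clock in which seconds stand in for weeks.
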