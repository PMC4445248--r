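---
title: "A Bayesian context-fear automaton: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian context-fear automaton: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ctxfear` simulates contextual fear learning as a discrete-event
process: a context is a set of attributes, attributes are observed one
per cycle in random order without replacement, and on every cycle a
hippocampal circuit and a Bayesian evidence computation jointly decide
what to store, what to recall, and how much fear to express. This
vignette records the model, its assumptions, and every numerical and
design choice a maintainer might want to interrogate.

## The synthetic world

The generator (`build_ensemble()`, `add_context()`, `sample_stream()`)
emulates only the combinatorial skeleton of a context: `N_ctx` possible
attributes, of which each context expresses exactly `N_A`, with `N_gen`
general attributes common to every context. Unconstrained contexts draw
their `N_A - N_gen` unique attributes uniformly and independently from
the non-general pool, so two of them share the general core plus a
chance number of uniques. Contexts at a stated similarity `s` share
exactly `s * N_A` attributes with their reference — all the generals
plus a uniform choice of the reference's uniques — with the remainder
drawn outside the reference's uniques so that realized similarity is
exact, not merely expected. Sampling within a visit is a uniform random
permutation: one attribute per cycle, none repeated.

What the generator does **not** emulate: attribute salience (all
attributes are equally likely to be sampled), any notion of wall-clock
time (the independent variable is sample number), time-varying sampling
rates, or suppression of sampling while the animal freezes. Passing
tests therefore speak to the combinatorial and circuit-level logic of
context recognition, not to the temporal microstructure of real
exploration.

## Circuit model

Neurons are instantaneous rate or binary units. Three primitives
(`membrane_potential()`, `linsig()`, `kwta()`) cover all of them:

* depolarization `V = Ge * E / (1 + Ge + Gi)` with conductances
  relative to leak and the excitatory reversal potential fixed at
  `E = 1` (dimensionless; forced by consistency with the fear-output
  transfer function `Ge/(1+Ge)`);
* the linear sigmoid `linsig(v | thrsh, mxat)`, 0 below threshold, 1 at
  saturation, linear between;
* K-winners-take-all selection in two flavors (below).

The network (`build_net()`) has `N_hipp` dentate cells and `N_hipp` CA3
cells joined one-to-one into dyads. Each cell receives `F` entorhinal
afferents, drawn uniformly and independently for the two layers. All
Hebbian synapses are silent until potentiated. The CA3 recurrent
collaterals and the CA3-to-entorhinal-output projection are anatomically
complete.

Three operating modes:

* **Creation** (`create_representation()`): all anatomical synapses
  transmit regardless of potentiation; the `K` dentate cells most
  densely innervated by the active attributes win a strict KWTA
  competition and their CA3 partners fire. Entorhinal synapses from the
  active attributes onto each winner potentiate with equal weights
  renormalized to sum 1 per cell; all recurrent pairs among winners and
  all winner-to-output synapses for active attributes potentiate in one
  step to weight 1. The winner set is registered permanently.
* **Recall** (`recall_cycle()`): no plasticity. Dentate is rate-coded
  (its KWTA disabled), CA3 excitation is the dyad rate plus `dpf` times
  the direct potentiated input, strict KWTA gives the pre-recurrent
  pattern, and if at least `K0` cells are active the recurrents iterate
  `n_recurrent_iters = 2` times with ties kept. A final pattern of more
  than `K` cells (an exact evidence tie) suppresses all downstream
  output. Otherwise an output cell fires when at least `thrsh_ctx` of
  the active CA3 cells drive it.
* **Update** (`update_representation()`): the representation's cells
  re-potentiate from every currently sampled or recalled attribute
  (dentate reached through the backward CA3-to-dentate path), weights
  renormalized as at creation; membership never changes.

### KWTA tie semantics

The two flavors are deliberately different. During pattern *selection*
(creation winners, the pre-recurrent pattern) ties are broken: each
nonzero excitation receives independent uniform noise on
`(0, noise_eps)` with `noise_eps = 1e-6`, far below the smallest
meaningful excitation difference (one synaptic weight quantum), so
noise can reorder only exact ties and silent cells can never win; the
result is "at most, exactly K" cells. During the recurrent iterations
ties are *kept*: the K-th highest excitation defines a cutoff and every
cell at or above it fires, so an exact tie between two stored patterns
propagates to a `> K`-cell final pattern whose downstream consequences
are suppressed, rather than being resolved arbitrarily. Convergence to
the correct representation depends on this.

## The evidence model

With `Z_cur` sampled, `Z_rec` recalled and `Z_com` common attributes,
the weight of evidence is
`B_Rep = log10(P[Z_com | Same] / P[Z_com | Diff])`, zero by definition
when the output layer is silent. The `Same` term is the hypergeometric
overlap of a uniform `Z_cur`-sample with a fixed `Z_rec`-subset of the
context's `N_A` attributes. The `Diff` term integrates the same
hypergeometric over the number `m` of recalled attributes that lie in
the current context when the recalled set belongs to a *different*
context; `ctxfear` ships two observation models for `m`:

* `diff_model = "chance"` (default) — exactly the generator's law:
  different contexts share the general core plus
  `u ~ Hyp(N_A - N_gen, N_ctx - N_A, N_A - N_gen)` chance uniques, and
  `m ~ Hyp(N_gen + u, N_A - N_gen - u, Z_rec)` given `u`. The tests
  verify this model against a brute-force Monte Carlo of the generator
  on a reduced world.
* `diff_model = "general"` — different contexts share exactly the
  general core (`u = 0`).

The chance model is the default because the general model makes any
overlap beyond `N_gen` literally impossible under `Diff`, which pins
`B_Rep` at the positive clamp in highly similar novel contexts; the
evidence then exceeds `B_add` and the automaton improperly updates the
familiar context's representation with the novel context's attributes —
precisely the corruption the high `B_add` threshold exists to prevent,
and enough to abolish the early-shock fear-misattribution effect the
acceptance suite checks. Under the chance model the evidence stays
finite and the misidentification of a 95%-similar novel context is
eventually broken by the impossibility bound (below), as intended.

The model choice moves the two deterministic calibration constants the
acceptance suite computes: under the shipped chance model the smallest
full-sampling recall reaching `B_old` is 11 and the `B_add` crossing of
the `Z_cur = Z_rec` diagonal is 71 (under the general variant, 10 and
67). Notably, the chance model's `B_old` crossing of that diagonal
falls exactly at `Z_0 = 45`, the default creation threshold: a
representation created at `Z_0` and revisited supports conditioning
from the same sample count onward, which is the self-consistency
argument behind the default `Z_0`.

Numerical choices: probabilities come from `stats::dhyper` (log-space
gamma internals); the `Diff` mixing distribution is memoized on the
full parameter tuple; `P[Same] = 0` (in particular whenever
`Z_cur - Z_com + Z_rec > N_A`, which no single context can produce)
returns the finite floor `b_floor = -50`, `P[Diff] = 0` with positive
`P[Same]` clamps at `+50` — both far beyond every decision threshold,
so control behavior never depends on the clamp values; a recalled count
exceeding `N_A` (possible only after representation corruption) is
likewise floored. `expected_b_rep()` evaluates the real-valued expected
overlap `Z_cur * Z_rec / N_A` by linear interpolation between the two
adjacent integer overlaps — interpolation rather than rounding avoids
threshold-crossing artifacts in calibration scans.

A calibrated functional stand-in for the evidence computation
(`calibrate_approx_circuit()`, `b_rep_approx()`) shows the quantity is
computable by a handful of rate-coded neurons: a power-function
excitation in `Z_com` tuned to the envelope of the exact curves,
divisive inhibition in a power of `Z_hi * (Z_lo - Z_com)`, a tonic bias
so the output can signal invalidity below baseline, and an
impossibility gate. It is calibrated by least squares against the exact
evidence on a `Z_lo, Z_hi in {30, ..., 100}` grid and records its own
reference RMSE; it is an illustration, not part of the control path.

## Session control

`step_sample()` runs the cycle order: sample, recall, evidence,
bookkeeping, mode decision, learning-rule evaluation, optional shock.
The mode logic (`decide_mode()`):

* once a representation has been created this session it is valid by
  construction, so every later sample updates it (one creation per
  session; a session is one uninterrupted visit to one context);
* `B_Rep >= B_add` (virtual certainty) also updates;
* creation requires `Z_cur >= Z_0`, no standing suppression, and either
  `B_Rep < B_new` or a pre-recurrent pattern still below `K0`; the
  silent-hippocampus trigger is evaluated at every sample from `Z_0`
  onward, since persistence costs nothing;
* otherwise the cycle is plain recall.

Suppression bookkeeping: a representation whose evidence ever reaches
`B_pv` this session marks creation suppressed; the mark is released
only when that same representation, while active, later falls below
`B_new`. A representation that merely stops being active keeps
suppressing — the conservative reading, which prevents a transiently
active competitor from licensing a duplicate representation.

Conditionability is `Cnd = linsig(B | B_old, B_add)` and a shock adds
`alpha * Cnd` to each active CA3-to-amygdala weight; expressed fear is
`membrane_potential(linsig(B | 0, B_add) * Ge)` — the expression gate
starts at zero evidence (better to err on the side of fear) while the
conditioning gate starts at `B_old`. On a session in which a
representation was created, the governing evidence for both is the
*expected* evidence at `Z_rec = Z_cur` (the representation tracks the
sample set exactly, so the snapshot `B_Rep` would overstate what a
later visit could reproduce). Fear is computed *after* the mode
decision, so a representation created on this very cycle expresses
through its expected evidence immediately; the alternative ordering
(before the switch) would only delay the identical values by one
sample. Amygdala weights never decrease: extinction is deliberately out
of scope.

Why misidentification self-corrects: in a novel context 95% similar to
a familiar one, the familiar representation's evidence grows for tens
of samples, but `Z_cur - Z_com + Z_rec` grows too, and once it exceeds
`N_A` the observation is impossible under `Same`, the evidence floors,
suppression releases, and a fresh representation is created. The
default protocol lengths place an "early" shock before this bound is
reached (conditioning the familiar context) and a "late" shock after it
(conditioning the actual context).

## Parameters

| name | default | meaning |
|---|---|---|
| `N_ctx` | 1000 | possible attributes (entorhinal cells per layer) |
| `N_hipp` | 10000 | dentate/CA3 dyads |
| `N_A` | 100 | attributes per context |
| `N_gen` | 50 | attributes common to all contexts |
| `F_aff` | 60 | entorhinal afferents per cell |
| `K` | 60 | KWTA winner count |
| `K0` | 15 | minimum pre-recurrent pattern size |
| `Z0` | 45 | samples required before creation |
| `thrsh_ctx` | 42 | active CA3 inputs to fire an output cell |
| `B_old`, `B_new`, `B_add`, `B_pv` | 3, -3, 15, 3 | evidence thresholds (log10 units) |
| `alpha` | 0.025 | amygdala learning rate (weight per shock at `Cnd = 1`) |
| `dpf` | 0 | direct-path strength in recall (0 = dentate route only) |
| `noise_eps` | 1e-6 | tie-breaking noise half-width (excitation units) |
| `n_recurrent_iters` | 2 | recurrent cycles to the final pattern |
| `b_floor` | -50 | finite stand-in for infinite evidence (log10) |

All are exposed through `fear_params()` and a flat YAML/JSON config
(`load_config()`); invariants are enforced by `validate_params()`.

## Experiment drivers and problem sizes

The `run_*` drivers script the reference protocols: pattern separation
over replicate worlds (`run_pattern_separation()`), the two calibration
scans (`run_z0_calibration()`), paired recall-pathway sweeps over full
100-sample probe sessions (`run_recall_dynamics()`; full sessions
because competitor discrimination keeps improving as sampling
approaches completeness, and the paired design shares connectivity,
familiarization draws and sampling orders across pathway conditions),
generalization and misattribution protocols with their phase lengths
(95/80/99 and 60 + 75/88/95 samples), and a factorial dentate lesion
suite. `familiarize()` compresses repeated visits into
create-then-update to an exact associated-attribute count, which is
equivalent under the model to any visit schedule reaching the same
count. The lesion suite first familiarizes two background contexts with
the dentate intact so that previously potentiated dentate synapses
exist to misdirect recall after encoding-stage silencing — without that
experience the direct path alone would trivially suffice — and runs
recall with a weak direct path (`dpf = 0.15`) so the lesioned routes
remain viable, as they are in the intact circuit.

Default replicate counts are 30 (protocol drivers) and 24 paired sets
(pathway sweep); the test suite runs the same drivers at 6–16
replicates and the full-scale network tests at `N_hipp = 10,000`, with
reduced 200-cell networks for the exhaustive completion checks — sizes
chosen so the whole suite completes in a few minutes while leaving the
stochastic contrasts comfortably clear of their decision boundaries.

## Known limitations

* No extinction, by design: fear weights are monotone, so repeated
  unreinforced testing does not reduce fear.
* Sample number stands in for time; no claims about seconds.
* Representations never decay and membership never changes; an
  improperly updated representation (possible if evidence saturates in
  a very similar novel context under the `"general"` evidence model)
  is permanent.
* The creation rule at full-attribute exposure separates 90%-similar
  contexts to roughly 43% representation overlap (the acceptance suite
  computes this figure); strong separation (~7–10%) requires the
  partial-sampling regime that normal operation actually produces,
  since creation fires at `Z_0`, not after exhaustive sampling.
* Exactly one representation's evidence is evaluated per cycle (the one
  controlling the output layer); parallel evaluation of several
  candidates is out of scope.
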