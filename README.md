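# contrastinfo

Information dynamics ask how much a *specific* observation, at a *specific*
moment, tells us about the rest of a sequence. The classical tools — per-event
information content `-log2 p(x)` and the entropy of the predictive
distribution — work well for discrete symbol streams (they underpin successful
models of melodic expectation), but both lose meaning on continuous state
spaces: their values change under a mere change of units, e.g. describing a
pitch in Hz versus log-Hz.

`contrastinfo` implements **contrast information**, a coordinate-invariant
dynamic information measure. For a target regime `A` of a stochastic process,
a specific source observation `b` and a specific context `c`, it is the
relative entropy from the conditional distribution of the target given both
observations to its distribution given the context alone:

    I(A; b | c) = D( p(A | b, c) : p(A | c) )
                = sum_a p(a | b, c) log2 [ p(a | b, c) / p(a | c) ]   (discrete)

measured in bits. Assigning the temporal regimes past `X`, present `Y` and
future `Z` to (target, source, context) yields six variants: **predictive**
`I(Z; y | x)`, **connective** `I(Z; x | y)`, **reflective** `I(Y; z | x)` and
their backward counterparts with past and future swapped. Connective contrast
is exactly zero for Markov processes, making it a per-moment measure of
non-Markovianity.

The package provides:

* the definitional brute-force evaluation over finite joints
  (`contrast_from_joint`, `expected_contrast`) plus `surprisal`/`entropy`,
  and a seeded Monte-Carlo estimator for continuous states
  (`mc_contrast_continuous`);
* exact closed forms for stationary discrete- and continuous-time Markov
  chains (`dtmc_contrast`, `ctmc_contrast`, via matrix powers of the
  transition matrix or matrix exponentials of the rate matrix, and the
  time-reversed matrices for backward variants) and for stationary Gaussian
  processes (`gaussian_contrast`, Gaussian conditioning + Gaussian KL);
* per-event / per-time-point information profiles along realised sequences
  (`markov_profile`, `gp_profile`);
* a variable-order PPM sequence model (escape method C, backoff smoothing,
  no update exclusion: `train_ppm`, `ppm_predict`, `ppm_profiles`) producing
  information content, entropy, forward predictive contrast and its expected
  form per event, with `correlate_profiles` for Pearson/Spearman comparison
  of profiles;
* maximum-likelihood estimation (`estimate_dtmc`, `estimate_ctmc`,
  `estimate_stationary_gp`, `fit_continuous_autocov`), seeded simulators
  (`simulate` methods), and plain-text IO (events CSV/JSON, monophonic MIDI,
  model JSON, profile TSV) plus a command-line front end in
  `inst/cli/contrastinfo.R`.

## Worked example

The two-state stop-light chain (stay with probability .95, switch with .05)
makes the semantics concrete: while the light stays red each moment is like
the last, but the switch to green sharply changes the expected future.

```r
library(contrastinfo)

light <- dtmc_model(matrix(c(.95, .05, .05, .95), 2), c("RED", "GREEN"))

# present GREEN observed after a RED past: the future distribution shifts hard
dtmc_contrast(light, "predictive", x = "RED", y = "GREEN")
#> [1] 2.946936

# present RED after RED: nothing has changed
dtmc_contrast(light, "predictive", x = "RED", y = "RED")
#> [1] 0.02020926

# connective contrast is identically zero for a Markov chain
dtmc_contrast(light, "connective", x = "RED", y = "GREEN", z = "RED")
#> [1] 0

# profile a realised path (one value per event with both neighbours)
path <- simulate(light, nsim = 8, seed = 1)
markov_profile(light, path, "predictive")
#> <info_profile: 6 rows, variant(s): predictive>
#>   event_index time    variant value_bits
#> 1           2   NA predictive 0.02020926
#> 2           3   NA predictive 0.02020926
#> ...
```

So observing GREEN in a RED context carries about 2.95 bits — nearly three
bits of change in what we expect next — while RED-in-RED carries 0.02 bits,
essentially the status quo. The same measure applies unchanged to
continuous-time chains (`ctmc_contrast`), Gaussian processes of pitch
frequency in Hz (`gp_profile`), and PPM models of symbol streams
(`ppm_profiles`).

## Note on corpus studies

The published correlation study between PPM information content/entropy and
(expected) forward predictive contrast information uses an external corpus of
Nova Scotia folk melodies that is not shipped here. The full workflow is
supported for users who obtain it: convert the melodies to monophonic MIDI or
CSV, `read_events` each one, `train_ppm` on the corpus (optionally
`link_viewpoints` for product features), `ppm_profiles` per melody, and
`correlate_profiles` on the pooled columns. See the vignette for details and
for why exact published values are not expected to reproduce bit-for-bit.
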