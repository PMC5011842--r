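# stagecast

Automated monitoring of *implementation stages* from the free-text
communication logs that implementation brokers keep while a multi-site
health program is rolled out.

When an evidence-based program is adopted across many sites (counties,
clinics, agencies), knowing which stage of the adoption process each site is
in — considering the program, preparing, recruiting, training, delivering —
normally requires expensive expert rating. The broker's dated log notes
("called county X about the referral plan", "training schedule drafted")
already carry much of that signal. `stagecast` turns those notes into:

- per-note **stage membership probabilities** (a note may straddle stages),
- per-site **stage start and end dates** detected from sustained changes in
  the probability trajectory,
- **stage-attainment flags** (which sites appear to have reached stage k),
- **Markov transition matrices** summarizing how sites move between stages.

## Method

Notes are deidentified (names by dictionary match with a capitalization
heuristic, phone numbers and email addresses by pattern), tokenized and
Porter-stemmed. For each stage *i* with description sentences *A<sub>i</sub>*,
discriminating keywords are selected greedily by a max-relevance /
min-redundancy rule: the *k*-th keyword maximizes

    sim(w; A_i) − (1/(k−1)) Σ_{p ∈ selected} sim(w; w_p)

where `sim` is the cosine between per-sentence count vectors. Keywords
selected by exactly one stage carry that stage as a label.

Counting the K selected keywords in each of the L notes and normalizing each
row to sum 1 gives a non-negative matrix **X** (L×K), which is factorized as

    min ‖X − F H Gᵀ‖² + α·tr((F−F₀)ᵀC₀(F−F₀)) + β·tr((G−G₀)ᵀC₁(G−G₀))

with F (L×S) the note→stage probabilities, G (K×S) the keyword→stage
probabilities, H (S×S) a stage-correlation core, and F₀/G₀ the one-hot
partial labels masked by the diagonal indicators C₀/C₁ (α = β = 1 by
default). The problem is solved by multiplicative updates whose denominators
are the positive part of the exact gradient, so the objective is
non-increasing at every sweep and the iteration's fixed points are KKT
points of the objective; convergence can additionally be certified by a KKT
complementarity residual. Rows of F and G are normalized to probability
vectors after convergence.

A synthetic-corpus generator with known ground truth (stage vocabularies
with controllable adjacent-stage overlap, per-site stage trajectories,
imbalanced note counts, partial labels) makes the whole pipeline testable
end to end.

## Worked example

```r
library(stagecast)

gen <- generate_corpus(synth_config(seed = 7))   # 4 stages, 40 sites, ~460 notes
res <- run_stage_pipeline(gen$corpus, gen$descriptions, seed = 7)
res$fit
#> Semi-supervised NMF fit: 542 notes x 20 keywords -> 4 stages
#>   53 iterations (converged), objective 127.397, scaled KKT residual 0.000492

evaluate_predictions(res$assignments$category, gen$truth$note_stage)
#> Accuracy: 99.6% on 466 notes
#> Confusion (rows = true, columns = predicted): ...

tr  <- site_trajectories(res$assignments)        # stage intervals per site
rec <- interval_recovery(tr, gen$truth$intervals)
rec$rate                                         # 0.977: boundaries within +/-1 note
estimate_transition_matrix(res$assignments)      # row-stochastic transition matrix
```

On this clean-vocabulary synthetic corpus the classifier recovers 99.6% of
note stages and 97.7% of true stage intervals to within one note on each
boundary; raising the adjacent-stage vocabulary overlap to 0.3 drops
accuracy to the high-80s-to-high-90s depending on seed — the expected
confusability effect.

A command-line wrapper is installed at `inst/scripts/stagecast`
(subcommands `scrub`, `select-keywords`, `fit`, `classify`, `intervals`,
`transitions`, `simulate`, `evaluate`), driven by a single YAML
configuration; see `?cli_main`.

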