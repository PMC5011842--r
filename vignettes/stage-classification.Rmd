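---
title: "Classifying implementation stages from communication logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying implementation stages from communication logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A large health system adopting an evidence-based program across dozens of
sites moves through discrete implementation stages — agreeing to consider
the program, pre-implementation planning, recruitment, training, delivery.
Expert stage rating is accurate but expensive. The dated free-text log
notes kept by implementation brokers are cheap and already exist, and their
vocabulary tracks the stage ("feasibility", "referral", "certification").
`stagecast` builds a semi-supervised classifier from three inputs:

1. per-stage **description sentences** (the published definition of what
   happens in each stage),
2. the **log-note corpus**, dated and site-keyed, with a small expert-labeled
   fraction,
3. optional deidentification dictionaries.

Two properties shape the model. A note may genuinely straddle stages, so the
output is a probability vector over stages rather than a hard call. And the
expert can only label a fraction of notes, so unlabeled notes must
contribute to the fit — the reason for a semi-supervised factorization
rather than a purely supervised classifier.

## Text preparation

**Scrubbing.** Listed person names are replaced by stable numbered
placeholders (`person001`), phones and emails by pattern (`phone001`,
`email001`). Capitalization resolves name/word homographs: lowercase "bill"
mid-sentence is an invoice and is kept; capitalized "Bill" is a person and
is replaced. We also replace capitalized occurrences at sentence starts:
for deidentification a false replacement is cheaper than a leaked name.
Scrubbing is idempotent, and the placeholder map is written separately so
outputs can be shared without it.

**Stemming.** Tokens are split on non-alphanumerics; tokens containing
digits (including placeholders) are dropped; the rest are lowercased and
reduced with the classical Porter suffix-stripping algorithm, implemented
in the package from the published algorithm definition and tested against
hand-traced outputs. Note that Porter is purely suffix-driven: it conflates
"connect/connected/connecting/connection" onto `connect`, but does not
produce truncation-style stems (the stem of "take" is `take`, not `tak-`),
and irregular forms like "took" stay distinct. No stopword removal is done
by default (the keyword selection step already ignores uninformative
words); a list can be supplied.

## Keyword selection

For stage $i$ with $m$ description sentences, let $P_i$ be the unique stems
of those sentences. The relevance of a candidate stem is the cosine between
its per-sentence occurrence-count vector and the per-sentence total
word-count vector (both $m$-dimensional); redundancy against an
already-selected stem is the cosine of their count vectors. Keywords are
picked greedily, the $k$-th maximizing

$$\mathrm{sim}(w;P_i) \;-\; \frac{1}{k-1}\sum_{p\in W_{k-1}}\mathrm{sim}(w;w_p),$$

with the redundancy term defined as $0$ at $k=1$ (the standard convention
for the first pick) and exact ties broken lexicographically. A stem absent
from every sentence has relevance 0 by convention. The default total budget
is $K=20$, split evenly across stages; a pooled per-stage budget is also
available because the best split is data-dependent — both are exposed in
`select_keywords()`.

Keywords selected by exactly one stage become **labeled keywords** with
that stage as their label; keywords selected by several stages stay
unlabeled, since description authors and note writers use vocabulary
differently and a shared word should earn its stage association from the
data.

## The factorization

Counting the $K$ keywords in each of $L$ documents and dividing each row by
its total keyword count yields the row-stochastic non-negative matrix $X$
($L\times K$; documents with no keyword become zero rows, which are
reported — by default they are kept and end up with uniform probabilities).
The model is

$$\min_{F,H,G\ \ge 0}\; \|X - FHG^\top\|^2
  + \alpha\,\mathrm{tr}\!\big((F-F_0)^\top C_0 (F-F_0)\big)
  + \beta\,\mathrm{tr}\!\big((G-G_0)^\top C_1 (G-G_0)\big),$$

with $F$ ($L\times S$) note→stage weights, $G$ ($K\times S$) keyword→stage
weights, $H$ ($S\times S$) a stage-correlation core, $F_0,G_0$ one-hot
partial labels and $C_0,C_1$ their diagonal indicator masks. The defaults
$\alpha=\beta=1$ suit trusted expert labels; lower either to soften noisy
labels. By default the stage description sentences themselves are appended
to the document set as fully labeled pseudo-notes
(`include_descriptions = TRUE`), which anchors the stage identities of the
factors even when very few notes are labeled.

### Update rules

Each sweep updates $F$, then $H$, then $G$ by elementwise multiplicative
ratios, e.g.

$$F \leftarrow F \circ
 \frac{XGH^\top + \alpha C_0F_0}{F\,HG^\top GH^\top + \alpha C_0F + \varepsilon}.$$

The denominators are the positive part of the objective's exact gradient,
which gives the two properties the tests certify:

* **monotonicity** — each update is a majorization-minimization step, so
  the objective never increases (verified to relative tolerance $10^{-8}$
  over 50 random problems);
* **correct fixed points** — the update is stationary exactly where the KKT
  complementarity condition $[\nabla_F]_{ik}F_{ik}=0$ holds, so converging
  means converging to a first-order point of *this* objective.

An alternative denominator family circulating for tri-factorizations,
$F F^\top X G H^\top$ (and $G G^\top X^\top F H$ for $G$), originates in
*orthogonal* tri-factorization, where it is the Lagrangian-stationary form
under $F^\top F=I$. Since we deliberately do not enforce orthogonality —
probability rows are the point of the model — that form is only stationary
where the factors happen to be column-orthonormal; empirically it
oscillates (relative objective increases up to $10^{-4}$) and its
plain-gradient KKT residual stalls at $O(1)$. It is retained as
`update_rule = "orthogonal"` for comparison, but the gradient form is the
default and the one the convergence guarantees refer to.

### Initialization, convergence, numerics

* Factors start strictly positive — uniform in $(0.1, 1.1)$, $H = I+0.1$,
  labeled rows of $F$ blended half-and-half with their one-hot target — so
  no entry is trapped at the absorbing zero state by accident.
* $\varepsilon = 10^{-12}$ stabilizes denominators.
* Convergence is declared when the relative objective change stays below
  `tol` (default $10^{-6}$) for 5 consecutive sweeps; the consecutive
  requirement guards against stopping inside a transient stall before a
  saddle escape. With `tol = 0` the loop always runs `max_iter` sweeps.
* Because an objective stall does not by itself certify stationarity (the
  complementarity residual at a stall scales like $\sqrt{\texttt{tol}}$),
  `kkt_tol` optionally extends the run until the scaled residual
  $\max_{ik}|[\nabla_F]_{ik}F_{ik}|/\max|X|$ falls below the given value,
  so `converged = TRUE` then certifies a first-order point. The
  stationarity-verified experiments in the test suite use
  `tol = 1e-10, kkt_tol = 1e-6`.
* Entries that decay into the denormal floating-point range are flushed to
  exact zero (zero is the absorbing state of a multiplicative update
  anyway); this avoids the large hardware penalty of denormal arithmetic
  in long runs.
* Rows of $F$ and $G$ are normalized to sum 1 **once after convergence**,
  not per sweep — per-sweep renormalization would break the monotonicity
  guarantee. The un-normalized factors are kept in the fit for
  diagnostics, and the KKT residual is evaluated on them.
* Argmax stage calls break ties toward the lowest stage index.

## Temporal summaries

Stage probabilities, optionally pooled into categories (stages
`collapse_at` and above summed; default pooling at 4 mirrors the
four-category scheme used when later stages are sparse), feed three
summaries:

* **Intervals**: a stage interval opens at the first of `min_run`
  (default 2) consecutive notes with stage probability at or above
  `threshold` (default 0.5) and closes when the run ends; disjoint runs
  give re-entries. This threshold-with-run rule was chosen over a formal
  change-point model because the probability trajectories are step-like
  and the rule is transparent; an optional centered moving average
  (`smooth_window`) bridges single-note dips. Interval dates are the dates
  of the first and last qualifying notes.
* **Attainment flags**: a site is flagged for stage $k$ if any of its
  notes is called at $\ge k$ — deliberately alarm-like and monotone in
  added notes.
* **Transitions**: maximum-likelihood Markov estimates over consecutive
  note pairs within a site (notes are the observed process; calendar
  spacing is ignored). Rows with no outgoing observation stay zero and are
  flagged; optional Laplace smoothing.

## The synthetic generator

Real multi-year implementation logs are rarely shareable, so the package
ships a generator whose defaults emulate a forty-site effort at desk
scale: 4 stage categories; 40 sites of which a fraction 31/40 never passes
stage 3; about 460 notes (2 + Poisson(1.6) notes per occupied site-stage);
stage durations gamma-distributed with mean 90 days; description sentence
counts 8/9/12/47 across the categories (76 in total); 10% of notes
labeled; per-stage vocabularies of 15 words with a configurable fraction
shared with adjacent stages; notes of 8 + Poisson(6) tokens with a 15%
stage-neutral background word rate. Words are pronounceable CVCV-strings
ending in a consonant and verified to be Porter fixed points, so the
generator exercises tokenization but isolates the pipeline from stemmer
behavior. Per-stage note totals can be pinned to an exact distribution
(e.g. 781/2937/183/688) for count-summary checks.

What passing on synthetic data does **not** show: robustness to natural
English (spelling, negation, multi-topic notes), to label noise (synthetic
labels are always correct), to systematic writing-style differences
between description authors and brokers, or to stages whose vocabularies
overlap non-adjacently. The overlap knob gives a one-dimensional
confusability axis — accuracy degrades monotonically in it — but real
confusability is richer.

## Problem sizes and expected numbers

The shipped experiments use: 50 random factorization problems of size
$60\times 25$ with $S=4$ and 10% labeled rows for the optimization
guarantees; the default ~460-note corpus for end-to-end recovery (note
accuracy $\ge$ 0.95 observed ~0.99; interval boundary recovery within one
note $\ge$ 0.90 observed ~0.97–0.99; overlap 0.3 accuracy observed
~0.88–0.98); and exhaustive checks of the interval scanner against all
4096 binary sequences of length 12. `scripts/acceptance.R` recomputes all
of these from scratch.

## Known limitations

* Porter stemming is English-only; no statistical named-entity recognition
  is attempted in scrubbing, so unlisted names survive.
* Bigram features are not used; the feature space is selected unigram
  stems only.
* Notes are classified independently; no temporal smoothing of the
  probabilities feeds back into classification (the interval detector
  smooths only for boundary detection).
* The multiplicative updates converge slowly near the optimum (typical of
  NMF); stationarity-verified runs can take $10^5$–$10^6$ sweeps on small
  problems, which the compiled loop makes affordable.
* The four-category confusion matrix and count distributions reproduced in
  `inst/extdata` are transcribed from typographically run-together
  published tables; the parse is the unique one consistent with the stated
  totals, but should be treated as a reading, not a canonical source.
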