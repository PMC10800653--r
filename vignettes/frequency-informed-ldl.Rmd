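---
title: "Frequency-informed linear discriminative learning: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-informed linear discriminative learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldlfreq)
```

## The model

Linear discriminative learning treats word comprehension as a linear map
from form to meaning. Each of the $m$ words in a lexicon contributes one
row to a binary cue matrix $C \in \{0,1\}^{m \times r}$, coding the
presence of overlapping n-grams in its (boundary-padded) form, and one row
to a semantic matrix $S \in \mathbb{R}^{m \times q}$ of distributional
embedding vectors. Comprehension is a matrix $F \in \mathbb{R}^{r \times
q}$ with $CF \approx S$; production reverses the roles ($SG \approx C$)
and is estimated by the same functions with the arguments swapped. The
model is deliberately shallow: its interest lies in what a single linear
mapping can and cannot learn about a lexicon, and in how *frequency of
experience* shapes that mapping.

A predicted vector $\hat{s}_i = c_i F$ is scored by its Pearson
correlation $r_i$ with the target row $s_i$ (`target_correlations()`). A
word is *correct at k* if $r_i$ is at least the $k$-th largest of its
correlations with all $m$ gold rows (`accuracy_at_k()`). Averaging
correctness over types gives the usual accuracy; weighting each word by
its token frequency gives token accuracy
(`frequency_weighted_accuracy()`), the measure appropriate to usage-based
questions. $1 - r_i$ serves as a proxy for lexical decision latency
(`one_minus_r()`): the better a form approximates its meaning, the faster
a word/nonword decision should be.

## Three estimators

**Endstate learning (EL).** `solve_linear_mapping()` minimises
$\lVert CF - S\rVert_F^2$ through the normal equations
$F = (C^\top C)^{-1} C^\top S$. It is the endstate of learning in the
sense that error-driven training with every word presented equally often,
forever, converges to it. Frequency plays no role.

**Widrow-Hoff learning (WHL).** `train_incremental()` applies the delta
rule once per learning event,
$F \leftarrow F + c_t^\top (s_t - c_t F)\,\eta$, starting from the zero
matrix. `frequencies_to_events()` expands a frequency vector into an event
sequence: `raw` presents a word of frequency 100 exactly 100 times;
`scaled` divides frequencies by a divisor and applies a ceiling (so
attested words keep one event); `log_backoff` uses
$\mathrm{round}(\ln(f+1))$, floored at one event for attested words. The
rounding convention is ours: a count of presentations must be an integer
and the log transform does not dictate one. Event order is shuffled under
a caller-supplied seed; training is deterministic given the sequence.

**Frequency-informed learning (FIL).** Conceptually, FIL is EL applied to
matrices $C_f, S_f$ in which word $i$'s rows appear $f_i$ times: the
entire learning history, order forgotten. Because
$C_f^\top C_f = \sum_i f_i\, c_i^\top c_i$ and
$C_f^\top S_f = \sum_i f_i\, c_i^\top s_i$, the same normal equations are
reached by scaling row $i$ of both $C$ and $S$ by a factor whose *square*
is proportional to $f_i$; `solve_frequency_informed()` uses
$\sqrt{f_i / \max_j f_j}$, the maximum-normalisation keeping the scaled
entries in $[0,1]$ for numerical stability. Row replication is the
normative definition: the test suite verifies, over hundreds of random
instances, that the scaled solution equals the brute-force replicated
solution to $10^{-8}$, that uniform weights collapse FIL to EL, and that
$FIL(\alpha f) = FIL(f)$ for any $\alpha > 0$. Words of frequency 0 are
legal: they get zero weight in the objective (and no learning events) but
remain rows of $C$ and $S$ and are still evaluated.

## Numerical choices

*Solving.* The Gram matrix is factorised by Cholesky decomposition. Cue
matrices are routinely rank-deficient — homophones contribute identical
rows, and inventories can exceed the word count — and a rank-deficient
Gram has no stable Cholesky solution, so the solver first estimates the
reciprocal condition number and falls back to the SVD minimum-norm
solution below $10^{-10}$ (or when the factorisation fails outright). The
minimum-norm solution is the right canonical choice for two reasons: it is
invariant under the frequency rescaling FIL applies, and Widrow-Hoff
training from the zero matrix stays inside the row space of $C$, so its
limit *is* the minimum-norm solution. `ridge` (default 0) adds an optional
L2 penalty for users who prefer explicit regularisation.

*Ties and degeneracy.* Correlations within $10^{-12}$ of the target's own
correlation count in the target's favour, so a homophone set whose members
share one predicted vector is not automatically scored wrong. A
zero-variance prediction (e.g. an untrained row of the zero matrix) has no
defined correlation; it receives the sentinel $r = 0$, is flagged, and is
ranked last — it cannot legitimately select a target.

*Trajectory moments.* `occurrence_moments()` treats a word's batch index
as a random variable weighted by its per-batch token counts and reports
mean, mode (smallest batch on ties, for determinism), skewness and excess
kurtosis; words confined to a single batch get sentinel 0 for the shape
moments. Raw kurtosis is outlier-dominated, so a damped version
$\mathrm{sign}(k)\,\log(1+|k|)$ is exported alongside; this transform is
this package's own choice of variance-stabiliser.

## The synthetic study conditions

Every empirical claim in the package is exercised on synthetic lexicons
from `generator_config()`; the defaults are the study conditions and are
used unchanged by the test suite and `scripts/acceptance.R`.

- **m = 500 words** over a 6-letter alphabet, form lengths 3–7: large
  enough for stable accuracy estimates, small enough that every estimator
  runs in seconds; the small alphabet makes cue sharing between words
  pervasive, as in real lexicons.
- **Zipfian frequencies**, exponent $a = 1$, top frequency
  $f_{\max} = 10{,}000$, deterministic ($f_i = \max(1,
  \mathrm{round}(f_{\max}\, i^{-a}))$) so oracle tests are exactly
  reproducible. The resulting ~68,000 tokens give roughly corpus-like
  per-word experience: the most frequent word accounts for several percent
  of all tokens while half the types sit in the sparsely-attested tail.
- **Planted linear semantics**: $S = C F^\ast + \varepsilon$ with
  $F^\ast$ i.i.d. standard normal and noise $\sigma = 4$ on $q = 50$
  dimensions. With mean cue support around 6 per word this leaves roughly
  a quarter of the semantic variance linearly predictable from form —
  deliberately weak form–meaning systematicity, as for real embeddings.
  (With small $\sigma$ every estimator sits at ceiling and frequency has
  nothing to explain; the noise level is what puts the model in the regime
  where usage matters.) A `gaussian` model with form-independent semantics
  is available as a null.
- **Homophones** are injected as distinct entries with identical forms, so
  tie handling is exercised rather than averaged away.
- **Token streams** draw identities from a multinomial over the lexicon
  frequencies. Burst schedules relocate all tokens of designated words
  into the first or last fraction of the stream's positions, emulating
  words whose frequency drifts across a learning history.

Under these conditions the package reproduces the qualitative signature of
frequency-informed learning: EL beats FIL on type accuracy while FIL beats
EL on token accuracy; FIL's correct@1 rises steeply with log frequency
(logistic slope positive, $p \ll 0.01$) while EL's does not differ from
flat; and per-word target correlations of single-pass raw-frequency WHL at
$\eta = 10^{-3}$ correlate above 0.9 with FIL's.

What the generator does *not* emulate: the covariance structure of real
embeddings (dimensions here are independent), morphological families,
realistic phonotactics or n-gram statistics, polysemy, and the gap between
community frequency counts and any individual's experience. Passing tests
therefore show that the estimators and measures behave as the theory
predicts on data satisfying the model's own assumptions — not that the
linear model is adequate for any particular natural language.

## The convergence fixture

One check deserves its own note. Widrow-Hoff training with uniform
frequencies should approach the endstate solution over repeated shuffled
epochs. Its convergence rate is governed by the spectrum of $C^\top C$:
after $E$ epochs at rate $\eta$, the residual along an eigenvector with
eigenvalue $\lambda$ scales as $\exp(-E\,\eta\,\lambda)$. Short forms over
a small alphabet give heavily overlapping cue rows whose Gram matrix has
near-zero small eigenvalues — such a system cannot reach the endstate in
any realistic budget, which is a fact about the geometry, not a bug. The
convergence check therefore uses 50 long, distinctive forms (26-letter
alphabet, lengths 16–24) with trigram cues and noise-free planted
semantics: cue rows are then nearly orthogonal with $\lambda_{\min}
\approx 15$, and 500 epochs at $\eta = 10^{-3}$ drive the relative
Frobenius distance to the endstate below $10^{-3}$. The fixture probes
estimator consistency, not lexical realism.

## Tonal cues and priming

For tone languages, `tonal_union_cues()` builds the union of three cue
sets from a transcription such as `wen4ti2`: segmental triphones over the
concatenated segments (`#we, wen, ent, nti, ti#`), tritones over the tone
digits (`#42, 42#`), and tone-segment triphones in which each vowel
carries its syllable's tone digit as a suffix and the compound
vowel-plus-digit occupies a single symbol position (`#we4, we4n, e4nt,
nti2, ti2#` — note `e4nt` spans the three positions `e4–n–t`). The vowel
set is a required argument, not hardcoded, since it is
transcription-scheme dependent.

`generate_priming_design()` emits prime–target pairs in four conditions:
identity (ST), segments shared / tone different (S), tone shared /
segments different (T), and unrelated (UR). The priming measure is
$1 - \mathrm{cor}(\hat{s}_{\mathrm{prime}}, s_{\mathrm{target}})$
(`priming_measures()`), a simulated reaction time. Because segment sharing
implies many shared cues and tone sharing only a few, a
frequency-informed mapping fitted on a synthetic tonal lexicon orders the
condition means ST < S < T ≈ UR — more priming from segmental than from
tonal overlap. Condition contrasts are summarised by a label-permutation
test rather than a parametric multiple-comparison procedure: on synthetic
data the permutation test makes no distributional commitments and is
exactly valid at any size.

## Ordered learning and what FIL loses

`run_trajectory()` trains WHL over a token stream in order, recording all
words' target correlations and within-batch counts after every batch
(default 5,000 events, following common practice for corpus-scale
streams; the package's own studies use batches of 1,000 on 20,000-event
streams), then fits FIL on the stream's aggregate counts.
`whl_fil_delta()` reports $\delta_i = r^{\mathrm{WHL}}_i -
r^{\mathrm{FIL}}_i$ joined with the occurrence-time moments. Two planted
regimes bracket the behaviour: words whose tokens arrive in the final 10%
of the stream show $\delta > 0$ (recency: WHL has just learned them,
while FIL dilutes them across the whole history), and early-burst words
sharing cues with later words show $\delta < 0$ (unlearning: subsequent
events on overlapping cues overwrite them). For stationary streams the
two solutions' per-word correlations agree closely, which is the
justification for using the order-free FIL whenever no principled event
order exists. Whether batch evaluation uses the mapping state at the
batch boundary (as here) or mid-batch snapshots is a free choice; batch
ends are assumed.

## Tunable parameters at a glance

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `n` | `build_cue_matrix()` | 2 | gram order; 2–3 typical for alphabetic scripts |
| `boundary` | cue functions | `#` | word-edge marker, one per side |
| `eta` | `train_incremental()` | — | delta-rule learning rate; must satisfy $\eta < 2/\lambda_{\max}(C^\top C)$ for stability; $10^{-3}$–$10^{-2}$ typical |
| `transform` | `frequencies_to_events()` | `raw` | raw / scaled(divisor) / log-backoff event counts |
| `ridge` | solvers | 0 | optional L2 penalty on the Gram diagonal |
| `batch` | `run_trajectory()` | 5000 | events between trajectory evaluations |
| `k` | `accuracy_at_k()` | 1 | leniency of the nearest-neighbour criterion |
| `noise_sd` | `generator_config()` | 4 | semantic noise; controls form-predictable variance share |
| `zipf_exponent`, `f_max` | `generator_config()` | 1, 10000 | frequency distribution shape and scale |

## Known limitations

The mappings are linear; systematic nonlinear form–meaning structure is
invisible to every estimator here. FIL inherits least-squares sensitivity
to extreme weights: a single word carrying most of the token mass
dominates the fit. The latency proxy $1 - r$ is one of several
learning-based predictors of reaction time and is exported for external
regression modelling rather than interpreted absolutely. Production is
supported as the reverse mapping $G$ only; decoding predicted cue vectors
into word forms is out of scope. And the permutation summary for priming
contrasts describes the synthetic items it is computed on — it is not an
inference about human listeners.
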