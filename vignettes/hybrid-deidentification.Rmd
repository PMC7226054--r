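---
title: "Hybrid de-identification of clinical notes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid de-identification of clinical notes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deidr)
```

## The task

Clinical notes cannot be shared for research until protected health
information (PHI) — names, dates, contact details, identifiers, locations,
ages, professions — has been found and removed. `deidr` treats this as
sequence labeling: a note is tokenized into a sequence
$S = (s_1, \dots, s_n)$, and a tagger produces $T = (t_1, \dots, t_n)$
where each $t_i$ is `O`, `B(CAT)` or `I(CAT)` under the IOB scheme over 23
fine-grained PHI categories (the i2b2 extension of the 18 HIPAA classes).
Runs of `B, I, \dots, I` decode back into character-offset entities, and
quality is measured by *strict* entity-level micro F1: a prediction counts
only when start offset, end offset and category all equal a gold entity's.

Three taggers with deliberately different inductive biases are combined by
stacked generalization:

1. a **rule-based tagger**: a small regex initial annotator whose output is
   repaired by an ordered list of automatically learned transformation
   rules (transformation-based error-driven learning, TBED);
2. a **linear-chain CRF** over a unified feature set with feature crosses;
3. an optional third tagger behind a plug-in contract (the package ships a
   memorizing gazetteer as a demonstration; any object with
   `fit(preps)`/`predict(fitted, prep)` can register).

A binary RBF-kernel SVM scores the pooled candidate entities and the
high-scoring non-overlapping subset is the final answer.

## Subword tokenization

Whitespace tokens misalign with PHI ("`Dr.Smith`" contains the PHI
"`Smith`"), so token boundaries are refined in three steps: (1) split
everything except runs of letters and runs of digits; (2) split letter runs
before internal uppercase characters (`HealthCare` → `Health`, `Care`);
(3) byte pair encoding re-merges frequent adjacent pieces within a
whitespace chunk to fight sparseness. Offsets are preserved exactly —
tokens plus whitespace gaps reconstruct the source string — and
`phi_alignment_error_rate()` measures the residual fraction of gold
entities whose boundaries still fall inside a token.

Decisions worth recording:

* **BPE ties and stopping.** Pair-frequency ties are broken
  lexicographically so the merge list is a pure function of the corpus and
  the merge budget (default 1,000). Learning stops when the best remaining
  pair occurs fewer than twice: a singleton merge memorizes one chunk and
  cannot reduce sparseness. Merges never cross whitespace, otherwise
  offset reconstruction would break.
* **Sentence boundaries** (needed by the sentence-length feature) are
  newlines and `.?!` followed by whitespace and an uppercase letter. This
  is deliberately simple and pluggable; clinical section headers are
  handled separately.
* **Unicode**: letters/digits/uppercase are Unicode character classes, not
  ASCII ranges.

## The rule-based submodel

The initial annotator applies prioritized regular expressions to the *raw
text* (one shipped pattern deliberately contains a space) and projects
matches onto tokens; tokens only partially covered by a match stay `O` so a
sloppy pattern can never corrupt a span boundary. This first pass is weak
on purpose — its job is to give the transformation learner something to
correct.

TBED then iterates greedily: at every mistagged position each template
(e.g. *current token*, *current token + previous tag*, *length of previous
token + current token*) binds its conditions to that position's feature
values, proposing a rule `from-tag -> gold-tag`. Every candidate is scored
by its net benefit

$$s(r) = \text{errors fixed} - \text{correct tags broken}$$

over the whole corpus, and the best rule is appended to the ordered list.
Rules are applied **simultaneously**: conditions are evaluated against the
pre-application tagging, then all firing positions rewrite at once.
Consequently the training error falls by exactly $s(r)$ each iteration and
the trace is strictly decreasing — both properties are asserted in the test
suite, and on small corpora the selected rule is checked against exhaustive
enumeration of every bindable candidate.

Further choices: ties among equal-benefit rules prefer fewer broken tags,
then smaller template arity, then the lexicographically smallest rule
string (determinism); the stopping threshold is a minimum benefit of 1 with
an iteration cap of 200 (the published system reported 43 iterations on its
corpus — a data-dependent outcome, not a setting); features other than the
explicit `tag@offset` slots are computed once from the text and never
depend on the evolving tags, which keeps scoring linear in corpus size.
Learned rules serialize to a human-readable text file
(`IF token@0='Hospital' THEN O->I(HOSPITAL) # score=17 ...`) that parses
back losslessly.

## The CRF submodel

The linear-chain CRF assigns

$$P(T \mid S) = \frac{1}{Z(S)} \exp \sum_i \Big( \lambda_{f} f(t_i, S, i) +
\mu_{t_i, t_{i+1}} \Big)$$

with one weight per (observation feature, tag) indicator and one per tag
bigram. Training maximizes the L2-penalized conditional log-likelihood
with exact forward–backward gradients; decoding is Viterbi with ties
broken toward the lowest tag index. The observation features are the
unified feature set: token identity in a ±1 window, shape flags
(all-digits, initial-uppercase, length), prefix/suffix, a Porter-style
stem, sentence length, a section label from header heuristics, POS/NER
labels from the pluggable external tagger (a coarse built-in heuristic by
default), and 49 declared feature crosses (the cross inventory is a config
file, not code — the published count is known but not the membership, so
the shipped file is an explicit approximation).

Numerical choices: the forward–backward recursions run in scaled linear
space (emissions shifted by their row maximum, transitions by their global
maximum) so nothing overflows; probabilities over all tag sequences sum to
1 to 1e-9 on enumerable instances and analytic gradients match central
finite differences to 1e-5 relative error. The optimizer is batch gradient
ascent seeded at the configured learning rate (default 0.0005,
regularization weight 0.0003) with bold-driver step control — a step that
lowers the objective is rolled back and retried at half the rate, accepted
steps grow the rate by 5% — so the recorded objective is non-decreasing
and training is deterministic (weights start at zero; no random
initialization). IOB transition constraints are left off: ill-formed
output is repaired at decode time (an `I` without a matching predecessor
becomes `B`), which is also how ensemble candidates from any tagger are
normalized.

Epoch count is not part of the published configuration; the default of 100
full-corpus steps sits well past the objective plateau on corpora of the
benchmark's size.

## The stacking ensemble

Submodel predictions are pooled into candidates: exact duplicates (same
start, end, category) merge with a union of sources; overlapping but
distinct spans all survive, because arbitrating between them is precisely
the meta-classifier's job. Each candidate is featurized by provenance
indicators (one per registered tagger), the count and maximum character
fraction of overlap with other candidates, a category one-hot and its
length in tokens. A binary SVM with RBF kernel (gamma 0.009) and
per-class costs (positive 5.2, negative 12.48) scores candidates; the
decision threshold is the classifier's native boundary (decision value 0).

Stacking labels are built **out-of-fold** (default 5 folds, submodels
retrained per fold; the fold assignment is drawn from the pipeline's root
seed): in-sample submodel output would look optimistically accurate and
teach the stacker to trust everything. A candidate is labeled positive iff
it strictly matches a gold entity — the same criterion as the task metric.
Remaining overlaps among accepted candidates are resolved greedily by
descending score, so the output is always a sorted, non-overlapping subset
of the candidate pool; the ensemble never invents spans. If stacking
training data is single-class (e.g. perfect submodels), the stacker
degenerates to a constant scorer rather than failing.

## The synthetic corpus

The real de-identification corpora are access-restricted, so the package
generates surrogate notes: every document starts with a `Record date:`
header (exercising section features), then an `HPI:` section interleaving
single-PHI carrier sentences, PHI-free filler, and — in *hard mode* —
confusion material mirroring the failure classes a hybrid system must
arbitrate: four-digit lab values that look like years ("a CK of 1028"),
and multi-token state names in ambiguous travel sentences. Category
frequencies follow the published training-split distribution (DATE 7502,
DOCTOR 2885, PATIENT 1316, ... down to BIOID/HEALTHPLAN at 1), so DATE is
the modal category and the rare identifier classes stay rare. Surrogate
surface forms are built to be matchable by the shipped regex patterns
(ISO and two-digit dates, 3-letter-TLD emails, spaced usernames), and all
lexicons are small and plainly fictional.

What the generator does *not* emulate: real clinical language (telegraphic
style, misspellings, templated EHR boilerplate), annotation noise,
document-length distributions, or PHI that crosses line breaks. Passing
tests on this corpus therefore demonstrates the machinery — encoding,
learning, scoring, stacking — not clinical-grade accuracy; absolute scores
on it are far above what restricted real corpora allow and are not
comparable to published figures.

`plant_rule_corpus()` builds a second kind of fixture: gold tags corrupted
by a small number of expressible, non-interacting transformations, so rule
recovery ("zero training error within r iterations for r planted
corruptions") is testable exactly.

## Problem sizes and benchmark construction

The package's own benchmark uses 100 training and 50 test hard-mode
documents (construction seed fixed), 5-fold stacking, 1,000-merge BPE, the
200-iteration rule cap and 100 CRF epochs; the determinism check re-runs a
reduced configuration (18 training documents, 2 folds, 40 epochs) twice
and compares artifacts byte for byte. These sizes were chosen as the
smallest corpora on which all three submodels have enough signal to
diverge and the stacker has enough out-of-fold candidates to learn from.

## Known limitations

* The gazetteer third tagger is a placeholder for a stronger neural
  submodel; the plug-in contract is the supported path to add one.
* The official challenge evaluation script is not redistributable; this
  package's evaluator deduplicates identical predictions before one-to-one
  matching, which is the defensible convention but may differ from the
  official script in corner cases.
* Gold entities misaligned with token boundaries (possible after
  aggressive BPE) are skipped at training time with a warning; the
  alignment error rate function exists to keep that quantity visible.
* The category inventory is closed; the IOB codec itself is
  category-agnostic, but document validation enforces the 23-name set.
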