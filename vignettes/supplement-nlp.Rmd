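---
title: "Detecting supplement use in clinical notes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting supplement use in clinical notes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(suppuse)
```

## The problem and the pipeline

Structured medication tables under-record dietary supplements: patients
buy them over the counter, clinicians mention them in prose or in
semi-structured med lists, and nothing forces them into the pharmacy
record. The recoverable signal lives in note text, and it is noisy in a
characteristic way — the same token can be a supplement (`calcium 600mg
daily`), a lab value (`Calcium is 8.1`), a drug salt (`ATORVASTATIN
CALCIUM`), an allergy (`ALLERGIES: NIACIN`), or food (`ginger ale`).

The pipeline therefore separates *finding* mentions from *interpreting*
them:

1. a lexicon matcher finds every keyword occurrence (high recall, no
   disambiguation);
2. a linear SVM over snippet bigrams classifies each occurrence as
   active use or not (all disambiguation lives here, learned from
   annotated examples rather than hand-coded rules);
3. an any-positive roll-up lifts occurrence decisions to patient-level
   calls within a survey-anchored date window;
4. agreement with survey self-report is summarised per category and as
   micro/macro averages.

The key modelling assumptions: a ±20-token window carries enough context
to interpret a mention; binary bigram presence (not counts) is an
adequate snippet representation at this window size; one positive
occurrence suffices to call a patient a user; and the survey is usable as
a reference standard even though self-report is itself imperfect (see
*Limitations*).

## Tokenization

`tokenize()` splits on whitespace and then isolates punctuation into
standalone tokens, with deliberate exceptions: intra-word slashes,
hyphens and apostrophes (`CAP/TAB`, `QID-INSULIN`, `hasn't`), periods
between digits (`0.97`), and trailing colons (`Give:`, `ALLERGIES:`).
Punctuation is isolated, never deleted — in semi-structured notes it *is*
signal, and bigrams such as `("*", "folic")` or `("ACTIVE", "Give:")` are
among the most discriminative features. Asterisks are split into their
own tokens because med-list items frequently run together
(`qday*Glargine`); a dialect option (`tokenizer_dialect()`) turns this
off, and another isolates colons, because what the original annotation
tooling did at markup boundaries is not knowable — the dialect makes the
choice explicit and testable.

The tokenizer is idempotent under space-joining: `tokenize(paste(tokens,
collapse = " "))` returns the same tokens. This makes token indices a
stable coordinate system (annotation joins, CSV round trips) and is
enforced by a property test.

A "word" in the ±20-word window means one token from this tokenizer. No
sentence splitting is attempted: clinical notes are too non-grammatical
for it to be reliable, which is precisely why a fixed token window is
used instead.

## The lexicon

The packaged lexicon (`inst/extdata/supplement_lexicon.tsv`, 83 keywords
→ 44 categories) is a two-column TSV and can be replaced by the user.
The keyword and category inventories are fixed; the mapping between them
is curated here, because several keywords are genuinely ambiguous. The
decisions, recorded in the file itself:

* misspelling clusters map to their target category (`crea`, `creat`,
  `creatinin`, `creatinine`, ... → *creatine*; `ginko` → *ginkgo
  biloba*; `tumeric` → *curcumin*; `potasium` etc. → *potassium*);
* abbreviation clusters likewise (`fe`, `ferr`, `irn` → *iron*; `zn` →
  *zinc*; `flex`, `flexion`, `flx` → *glucosamine*, as joint-supplement
  shorthand);
* `acidophilus` → *probiotic*, `palmetto` → *palmetto*, `vera` and
  `aloe` → *aloe vera*, `krill` → *fish oil*;
* generic vitamin stems (`vit`, `vita`, `vitamin`, `vitamine`, `vits`,
  and misspellings) map to *multivitamin*, refined by one-token
  lookahead: a following `a`, `b2`, `b3`, `b6`, `b12`, `c`, `d`, `d2` or
  `d3` selects the specific vitamin category (`d` resolves to *vitamin
  d3*, the common over-the-counter form). A following token outside this
  set — including `e`, which has no category of its own here — falls back
  to *multivitamin*. This is conservative: it never invents a category
  the lexicon does not carry.

Matching is case-insensitive whole-token equality, never substring, and
deliberately over-matches (drug salts, labs, allergies): the
keyword-then-classify architecture puts disambiguation downstream. There
is no stemming and no fuzzy matching; the misspelling variants are
enumerated, not computed.

## Features and classifier

`build_feature_space()` collects the unique ordered case-folded adjacent
token pairs from the training snippets (lexicographic column order, so
the design matrix is reproducible) plus one one-hot block indicating the
observation's keyword, with a reserved `(unknown)` level for keywords
never seen in training. Features are binary presence indicators — at
≤41 tokens per snippet, counts add little beyond presence. Bigrams
unseen at training are ignored at prediction time.

The classifier is a soft-margin linear SVM (hinge loss + L2 penalty).
Tunables:

* `C` (cost, default 1): the standard default; no tuning is performed,
  by design — the pipeline deliberately avoids feature selection and
  hyperparameter optimisation, so reported numbers reflect the plain
  method.
* kernel: linear, fixed. High-dimensional sparse binary text features
  are near-linearly separable, and a linear decision function can be
  stored explicitly.

The fit goes through `e1071::svm` (libsvm), but the fitted object keeps
only the explicit weight vector and bias, with positive decision values
meaning "yes". Consequences: prediction is independent of the solver, a
test cross-checks the stored `(w, b)` against the solver's own decision
values, and serialization is a versioned JSON file in which weights are
written as 17-significant-digit strings (the smallest decimal length
that round-trips IEEE doubles exactly, making serialization bit-exact).

`cross_validate()` uses stratified folds (each class dealt round-robin
after a seeded shuffle) so fold class balances differ by at most one
observation. The feature space is rebuilt inside every training fold;
per-fold weight vectors are retained, and a test verifies that
scrambling a held-out fold's labels cannot change them (no leakage).
Reported metrics: per-class precision/recall/F1 and their
support-weighted averages. libsvm's optimiser is deterministic for fixed
data, so the whole report is reproducible bit for bit under one seed.
Degenerate inputs fail loudly: single-class training data and `k`
larger than the observation count are errors.

## Roll-up and agreement

Date window: "one year prior to one month after" the survey is
implemented as 365 and 30 days, both bounds inclusive, both
configurable. Calendar-month arithmetic was rejected as
under-determined (which month?); fixed day counts are unambiguous and
symmetric across patients, at the cost of being off by one day across
leap years.

Roll-up is the any-positive rule per (patient, category); with a
supplied category universe, unobserved categories are reported as
explicit negatives. The rule is monotone (extra positives can only turn
calls on) and order-invariant, both property-tested.

Agreement treats the survey as the reference standard — this orientation
is what makes "precision" and "recall" meaningful — and reports, per
category: tp/fp/fn/tn, precision, recall, F1 and prevalence. Zero
denominators yield `NA`, never silent zeros, and `NA` rows are excluded
from macro means with a warning. The micro average pools counts over the
included categories; the macro average is the unweighted mean of each
metric column, so macro F1 is the mean of per-category F1 values — *not*
the harmonic mean of macro precision and recall (the two disagree
whenever per-category metrics vary, and the mean-of-F1 convention is the
one consistent with summary rows computed from a per-category table).
Categories reported by a fraction of participants at or below the
prevalence threshold (default 0.10, strict inequality to include) are
excluded from the headline summary; the unfiltered summary is always
reported alongside. Chance-corrected agreement (kappa) is deliberately
not computed.

## The synthetic generator

Real clinical notes cannot be shipped, so the generator produces corpora
whose difficulty comes from the same sources: the same token meaning
different things in different structural contexts. Positive template
families: numbered active-medication lists (`(16) MELATONIN 5MG CAP/TAB
ACTIVE Give: ...`), asterisk-run med lists, and narrative current use.
Negative families: all-caps allergy lines, chemistry panels with
homonyms (`creatinine`, `calcium`, `potassium`, `magnesium`), food/diet
mentions (`ginger ale`, baked fish, iced tea) and compound drug names
(`ATORVASTATIN CALCIUM`, `LOSARTAN POTASSIUM`, `ZINC OXIDE`). Every
keyword occurrence is labeled at generation; the generator re-matches
the assembled document and refuses to emit a note whose document-level
matches differ from the planned per-segment matches, so templates cannot
create unlabeled accidental keywords.

Defaults encode the emulated study conditions: 377 patients, a common
survey date with note dates uniform in the [−365, +30] day window, and a
0.58 positive share of keyword occurrences (chosen so that the two class
supports sit in the proportion implied by support-weighted averages
falling where they do between per-class values in this kind of
annotation set). Where the emulated setting is silent, values were fixed
once at what a realistic chart would show: 5 notes per patient, 3–6
keyword segments plus 1–3 keyword-free filler sentences per note, each
patient using 2–8 of the 44 categories, template families uniformly
weighted. Survey discordance defaults to zero — the truth-faithful
baseline — with two dials: `underreport_prescribed` flips true use of
prescribed-style categories (default folic acid, melatonin,
multivitamin) to "no", modelling patients not regarding prescribed items
as supplements; `overreport` flips non-use to "yes".

With an oracle classifier (labels read from ground truth) and zero
discordance, the full pipeline returns precision = recall = F1 = 1
for every represented category — an identity check that the plumbing
adds no distortion. Injecting only under-reporting leaves corpus-truth
agreement perfect while survey-referenced *precision* degrades
(documented use the patient no longer reports becomes a false
positive); survey-referenced recall is essentially unaffected, because
with no over-reporting the remaining survey positives are a random
subset of true positives. The under-reporting dial therefore reproduces
the direction of the prescribed-supplement discordance mechanism, not
any particular published number.

What the generator does **not** emulate: real note length and template
frequency distributions, demographics, per-supplement base rates
(uniform by default), OCR/typo noise outside the fixed misspelling list,
and topic drift within notes. Passing tests on synthetic corpora
therefore demonstrate correctness of the machinery and achievable
separability under clean conditions — not expected performance on real
clinical text.

## Problem sizes

The test suite and the acceptance script size their simulations to keep
a full run fast on one core while leaving no code path untested: unit
corpora of 5–25 patients, a 1000-observation single-segment fixture for
the cross-validation competence check (one keyword segment per note, so
windows do not straddle segments of opposite sign and the corpus is
cleanly separable; 10-fold CV reaches weighted F1 = 1 there), a
600-row truth table for the exact-binomial check of the under-reporting
rate, and the full default configuration (377 patients, ~8500 evaluation
observations) for the end-to-end pipeline run in the acceptance script.

## Limitations

* The survey-as-reference orientation means every reported
  precision/recall conflates NLP error with self-report error; the
  synthetic discordance dials exist precisely to study that confound.
* Mixed-template corpora are *not* fully separable by bigrams — windows
  straddle neighboring segments — so cross-validated F1 on the default
  generator sits well below 1; this is intended realism, not a defect.
* No dosage, duration or start-date extraction is attempted; a mention
  classified positive says "active use near this note's date", nothing
  more.
* The category of an occurrence comes from the lexicon (with vitamin
  lookahead), so a misspelled designator (`vitamin d 3`) degrades to
  *multivitamin* rather than the specific vitamin.
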