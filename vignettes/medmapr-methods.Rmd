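---
title: "medmapr: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{medmapr: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medmapr)
```

## The problem

Observational studies collect medication use as free text. A single drug
appears under misspellings, brand names, and dose/form decorations, and the
accompanying "reason for use" text is equally unnormalized. Analysis needs
each entry reduced to a drug class and each reason to a disease category.
`medmapr` automates that reduction, leaving only genuinely unresolvable
entries for manual review.

## String metric

The package's only similarity primitive is the Levenshtein edit distance,
computed by a two-row dynamic programme in C++ over Unicode code points:

$$
\mathrm{lev}(i,j)=
\begin{cases}
\max(i,j) & \min(i,j)=0\\
\min\bigl(\mathrm{lev}(i{-}1,j)+1,\ \mathrm{lev}(i,j{-}1)+1,\
\mathrm{lev}(i{-}1,j{-}1)+[a_i\neq b_j]\bigr) & \text{otherwise}
\end{cases}
$$

with unit substitution cost. The similarity ratio is
$\mathrm{ratio}(a,b)=\dfrac{|a|+|b|-\mathrm{lev}(a,b)}{|a|+|b|}$,
algebraically $1-\mathrm{lev}/(|a|+|b|)$. Note this is **not** the
substitution-cost-2 ratio returned by some string libraries; the package
deliberately implements the displayed formula. When both strings are empty
the ratio is defined as 1.0 (identical strings), a convention the tests pin
down explicitly.

Distances satisfy the metric axioms (symmetry, identity of indiscernibles,
triangle inequality) and the bounds
$\bigl||a|-|b|\bigr|\le \mathrm{lev}(a,b)\le\max(|a|,|b|)$; the test suite
verifies all of these on random pairs and checks the dynamic programme
exhaustively against a direct memoized recursion of the definition for all
pairs of strings of length ≤ 5 over a three-letter alphabet.

## Match policies

A `match_policy(ratio_threshold, distance_threshold, combinator)` decides
acceptance. All comparisons are strict (`>` and `<`):

* **supplement screening** — ratio clause only, `ratio > 0.85`. Distance
  alone must not qualify, otherwise every 4-letter supplement would absorb
  arbitrary short tokens.
* **drug matching** — `ratio > 0.85` **or** `lev < 2` (combinator `"any"`),
  generous because the drug lexicon names are long and mutually distant.
* **reason mapping** — `ratio > 0.85` **and** `lev < 2` (combinator
  `"all"`), conservative because stem strings are short and disease
  categories are easily confused.

`best_match()` is deterministic: candidates are ranked by higher ratio,
then lower distance, then byte order (`order(..., method = "radix")`), so
results do not depend on locale or candidate order.

## Medication branch

1. Case-fold, collapse whitespace, strip punctuation.
2. Drop dose numbers (`200`, `200mg`), bare units (`mg`, `mcg`, `ml`, `g`)
   and dosage-form tokens from a configurable stoplist (`er`, `succ`,
   `tab`, `inhaler`, …). Alphanumeric tokens such as `b12` are *not*
   dropped. If everything would drop, the folded original is kept.
3. Screen against the supplement lexicon. Both the preprocessed form and
   the folded raw entry are screened, because token dropping cannot tell a
   dose digit from a digit that is part of a supplement's name
   (e.g. "omega 3"). A hit excludes the record from drug mapping.
4. Fuzzy-match against canonical names and synonyms; synonyms resolve to
   their owning canonical entry ("advil" → "ibuprofen").
5. Expand the matched concept to ATC codes through an adapter and truncate
   to the requested level. ATC levels here are 1 (`C`), 2 (`C07`) and 3
   (`C07A`); truncation discards labels, which belong to the full code.

The ontology adapter is a deliberate seam: `offline_adapter(bundle)` serves
concept resolution and ATC expansion from packaged files, and any service
with the same two-function contract could replace it. The package never
performs network access.

## Reason branch

1. Case-fold, strip punctuation, tokenize.
2. Spell-correct each word against a general word list using the
   ratio-only rule; unknown words pass through unchanged.
3. Stem each word with a Lancaster (Paice/Husk) stemmer and rejoin.
4. Fuzzy-match the stem string against a stem → category map under the
   AND rule; exact key hits short-circuit with distance 0.
5. Apply manual overrides (folded raw reason → category), which always win
   and are idempotent.

### Stemmer pinning

The Lancaster stemmer is implemented in R from a 115-rule table frozen in
the package source, with the standard acceptability condition
(vowel-initial stems need ≥ 2 characters; consonant-initial stems need ≥ 3
and a vowel or `y` in the second or third position). The implementation was
cross-validated word-for-word against an independent implementation of the
same table, and ~30 reference stems are frozen in the tests, so the rule
table cannot drift silently. Two behaviours worth knowing:

* Stemming is **not** idempotent under this table ("ulc" → "ul",
  "diarrhe" → "diarrh"); the pipeline applies it exactly once, to corrected
  words only. The tests assert the properties that actually hold: stems are
  never longer than their input and never empty.
* The standard table stems "arthritis" to "arthrit", not the shorter
  "arthr" some presentations use; the packaged stem map therefore carries
  both keys so either convention resolves.

Custom rule tables can be loaded with `read_stem_rules()`; rules use the
compact Paice encoding (reversed ending, intact flag `*`, remove count,
append string, continue `>` / stop `.`).

## Synthetic data and evaluation

Real study data cannot ship with a package, so `medmapr` generates its own
ground truth:

* `generate_lexicon()` draws pronounceable consonant–vowel names of 6–12
  characters and keeps a sample only if every pairwise distance meets
  `min_separation` (rejection sampling with a bounded retry budget that
  errors loudly when the request is infeasible). Drugs get synthetic
  concept ids and syntactically valid ATC level-3 codes.
* `generate_corpus()` allocates record kinds *exactly* (a 60/30/10 split of
  200 records is exactly 120/60/20), corrupts drug and supplement names
  with a seeded number of random character edits, and fills the garbage
  share with strings rejection-sampled to be unmappable by construction
  (distance > 3 **and** ratio ≤ 0.85 against every lexicon name).
* `evaluate_pipeline()` scores precision, recall, auto-mapped fraction,
  supplement confusions and reason accuracy against the emitted truth
  table.

With `min_separation = 5`, single-edit corruption and default thresholds,
recovery is exact and supplement confusions are zero — not by tuning but by
arithmetic: one edit leaves the true name within distance 1 (always
accepted), while a wrong candidate is at distance ≥ 4, and with names
capped at 12 characters its ratio is at most $(24-4)/24 < 0.85$. The test
suite verifies this across seeds, and the name-length cap is part of the
generator's documented contract for exactly this reason.

All generators use an internal seed guard that saves and restores
`.Random.seed`, so library calls never perturb the caller's random stream,
and identical seeds give byte-identical corpora.

### Why degradation is measured with `garbage_frac = 0`

The auto-mapped fraction is computed over *distinct* non-supplement terms.
With garbage present, an uncorrupted corpus collapses its many drug records
onto few distinct canonical names while every garbage string stays
distinct, so the denominator — and hence the fraction — is not comparable
across corruption levels, and the raw curve can be non-monotone for
reasons unrelated to matching quality. Degradation (the auto-mapped
fraction is non-increasing as edits go 0 → 3) is therefore asserted on
drug/supplement-only corpora, averaged over seeds.

## Scale and limitations

Problem sizes in the tests and acceptance script (10–20 lexicon entries,
60–200 records, 5 seeds, 132k exhaustive oracle pairs) are the package's
own choices, set to finish comfortably within a desktop minute while still
exercising every code path; the algorithms themselves are linear in the
number of records and quadratic in string length per comparison.

Out of scope by design: live terminology services (the adapter seam is the
extension point), alternative category hierarchies, clinical conclusions
of any kind, and multi-process orchestration. Fuzzy matching is also
inherently blind to semantics — a misspelling equidistant from two drug
names is resolved by the deterministic tie-break, not by pharmacology —
which is why the manual queue and the override mechanism are first-class
outputs rather than afterthoughts.
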