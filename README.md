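# medmapr

Free-text medication lists collected in observational studies are noisy:
entries arrive misspelled ("Quinipril"), decorated with dose and form tokens
("Metoprolol Succ ER"), under brand names ("Advil"), or describing dietary
supplements that are not drugs at all ("Vit B12"). The stated reasons for
use are just as messy ("hygh blood presure"). Before such data can be
analysed, every entry has to be resolved to a standard drug class and every
reason to a disease category — a job traditionally done by hand, one row at
a time.

`medmapr` automates this curation step. It normalizes raw medication text to
canonical drug names and Anatomical Therapeutic Chemical (ATC) level-3
classes, screens out supplements, and maps free-text reasons for use to
organ-system disease categories, queueing only the genuinely unresolvable
entries for manual review.

## Method

**Fuzzy matching.** Two strings are compared with the Levenshtein edit
distance `lev(a, b)`, defined by the recursion

```
lev(i, j) = max(i, j)                                   if min(i, j) = 0
            min( lev(i-1, j) + 1,
                 lev(i, j-1) + 1,
                 lev(i-1, j-1) + [a_i != b_j] )         otherwise
```

computed by dynamic programming in C++ (an exhaustive test verifies the DP
against direct memoized recursion). The similarity ratio is

```
ratio(a, b) = (|a| + |b| - lev(a, b)) / (|a| + |b|)  =  1 - lev / (|a| + |b|)
```

A *match policy* bundles a ratio threshold, a distance threshold and a
combinator. The defaults are:

| stage                | rule                                |
|----------------------|-------------------------------------|
| supplement screening | `ratio > 0.85` (ratio clause only)  |
| drug matching        | `ratio > 0.85` **OR** `lev < 2`     |
| reason mapping       | `ratio > 0.85` **AND** `lev < 2`    |

**Medication branch.** Each entry is case-folded; dose, unit and dosage-form
tokens (`200 mg`, `ER`, `Succ`, …) are stripped; the entry is screened
against a supplement lexicon (matches are excluded from drug mapping); the
remainder is fuzzy-matched against canonical drug names and their synonyms;
matched concepts are expanded to ATC codes and truncated to the requested
level (level 3 by default, e.g. `C07A` "beta-adrenergic blocking agents").

**Reason branch.** Each reason is case-folded, tokenized and
spell-corrected word-by-word against a general word list, stemmed with a
Lancaster (Paice/Husk) stemmer pinned to a 115-rule table frozen inside the
package, and the stem string is fuzzy-matched against a stem → category map
(`"high blood press" → hypertension`). Manual overrides, applied last,
always win.

Everything that cannot be resolved lands in a manual queue, and a summary
report counts records, distinct terms, categories and manual percentages.
All matching is deterministic: ties break by higher ratio, then lower
distance, then byte order.

## Worked example

Five study records ship with the package:

```r
library(medmapr)
lex <- system.file("extdata", "lexicon", package = "medmapr")
bundle <- load_bundle(lex)
records <- read_records(file.path(lex, "records.tsv"))

meds <- process_medications(records, bundle)
meds[, c("medication_raw", "status", "canonical_name", "match_distance",
         "match_ratio", "atc_codes")]
#> # A tibble: 5 × 6
#>   medication_raw     status  canonical_name match_distance match_ratio atc_codes
#>   <chr>              <chr>   <chr>                   <int>       <dbl> <chr>
#> 1 Fexafenedine       mapped  fexofenadine                2       0.917 R06A:ant…
#> 2 Hydrochlorothazide mapped  hydrochloroth…              1       0.973 C03A:diu…
#> 3 Metoprolol Succ ER mapped  metoprolol                  0       1     C07A:bet…
#> 4 Quinipril          mapped  quinapril                   1       0.944 C09A:ang…
#> 5 Vit B12            supple… <NA>                       NA      NA     <NA>

reasons <- process_reasons(records, bundle)
reasons[, c("reason_raw", "corrected", "stem_string", "category", "status")]
#> # A tibble: 5 × 5
#>   reason_raw          corrected           stem_string      category     status
#>   <chr>               <chr>               <chr>            <chr>        <chr>
#> 1 allergies           allergies           allergy          allergies    auto
#> 2 high blood pressure high blood pressure high blood press hypertension auto
#> 3 HTN                 htn                 htn              hypertension auto
#> 4 high blood pressure high blood pressure high blood press hypertension auto
#> 5 fatigue             fatigue             fatigu           fatigue      auto

summarize_run(meds, reasons)
#> <summary_report>
#>   records: 5 (4 after supplement removal)
#>   medications: 5 distinct raw -> 4 categories (0.0% manual)
#>   reasons: 4 distinct raw -> 3 categories (0.0% manual)
```

The same pipeline is available from the shell, along with a synthetic-data
generator and an evaluator:

```sh
inst/cli/medmapr run --records records.tsv --lexicon-dir lexicon/ --out-dir out/
inst/cli/medmapr gen-corpus --seed 5 --n-records 200 --out-dir synth/
inst/cli/medmapr evaluate --records synth/records.tsv \
    --lexicon-dir synth/lexicon --truth synth/truth.tsv --out-dir eval/
```

## Synthetic benchmarking

`generate_lexicon()` builds artificial drug/supplement lexicons whose names
keep a minimum pairwise edit distance; `generate_corpus()` corrupts them
with a seeded number of character edits and mixes in rejection-sampled
garbage entries that provably match nothing; `evaluate_pipeline()` scores a
run against the known truth (precision, recall, auto-mapped fraction,
supplement confusions, reason accuracy). With separation ≥ 5 and single-edit
corruption the pipeline recovers 100% of canonical names with zero
supplement confusions — a property the test suite checks across seeds.

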