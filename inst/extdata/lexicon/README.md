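# Demonstration lexicon

A small, self-contained lexicon bundle used by the examples and tests. It is
*not* a redistributable terminology: it exists to make the worked examples of
the workflow reproducible offline.

- `drugs.tsv` — ten real drug names with common brand-name synonyms and their
  WHO ATC level-3 therapeutic classes. The `concept_id` column is **synthetic**
  (`RX000xx` placeholders shaped like RxCUI identifiers, not real RxCUIs).
- `supplements.tsv` — common supplement names, one per line. Abbreviations
  such as `vit b12` are stored as explicit entries because they are too far
  from the full name for fuzzy matching (ratio 14/18 ≈ 0.78 < 0.85).
- `stem_map.tsv` — Lancaster stem strings mapped to organ-system reason
  categories. Both `arthr` and `arthrit` map to the arthritis category: the
  pinned rule table stems "arthritis" to `arthrit`, while older rule-table
  variants produce `arthr`; carrying both keys keeps the mapping stable.
  Entries beyond the worked examples (e.g. `htn`, `fatigu`, `seiz`) are
  synthetic additions for the demo records.
- `wordlist.txt` — a small general-language dictionary for reason spell
  correction. Caller-supplied in real use; this one only covers the demo
  vocabulary.
- `records.tsv` — five demo records (misspelled or brand-form medications
  paired with free-text reasons), `overrides.tsv` — an example manual
  override (`b/p` → hypertension).
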