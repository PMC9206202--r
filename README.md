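# phenossu

Deep phenotyping of clinical free text by linguistic-pattern discovery.

Phenotype descriptions in clinical narratives — especially Chinese EHR
text — follow a small number of highly conventionalized arrangements:
attribute words stacked before a phenotype ("右下腹部突发剧烈疼痛", *a
sudden severe pain in the right-lower abdomen*), a negation distributed
over an enumerated list ("没有出现发热, 乏力", *no fever or fatigue*),
or a lab analyte followed by a number and unit ("WBC 12.5 × 10⁹/L").
`phenossu` structures such text into **PhenoSSU instances** — one
phenotype concept plus ten standardized attribute slots (assertion,
severity, temporal pattern, laterality, spatial pattern, quadrant
pattern, body location; specimen, analyte, abnormality) — and, rather
than hand-writing the extraction rules, **learns them from an annotated
corpus with a sequence-motif discovery algorithm**:

1. **Encode** text as a single-letter sequence over
   {P, A, C, O, S, L, N, U, R} (phenotype, attribute, punctuation,
   other, specimen, analyte, number, unit, result word) by
   leftmost-longest keyword matching, with a per-letter map back to
   character spans.
2. **Mine motifs** in the encoded sequences with a two-component-mixture
   EM (any-number-of-repetitions site model, widths 2–30, pseudocounted
   PWMs), scored by a Monte-Carlo E-value: the site log-likelihood ratio
   is ranked against refits on composition-preserving letter
   permutations of the corpus.
3. **Reduce** motif segments to regular-expression pattern classes by
   run-length abstraction (`AP, AAP, AAAP → A+P`; `SLNU, LNU → S*LNU`;
   `APCP, APCPCP → A+P(CP)+`) and **enrich** the library against gold
   annotations until a fixed point.
4. **Recognize** instances by scanning encoded text with the library and
   assembling phenotype–attribute structures; quantitative lab matches
   are normalized against a knowledge base of reference ranges and
   mapped to SNOMED CT concepts (e.g. an elevated white-cell count →
   *increased blood leukocyte number*, 414478003).

A synthetic annotated-corpus generator, exact-span and attribute-level
evaluation metrics (entity F1, per-value and weighted attribute
accuracy, instance accuracy, Cohen's κ), brat standoff I/O, and a
minimum-corpus-size experiment harness make the whole pipeline testable
without access to any private EHR collection.

## A worked example

```r
library(phenossu)

lex <- load_lexicon(phenossu_file("lexicon_zh.tsv"))
kb  <- load_lab_kb(phenossu_file("lab_kb.tsv"))
sch <- load_schema(phenossu_file("phenossu_schema.tsv"))

encode("右下腹部突发剧烈疼痛", lex)$letters
#> [1] "AAAAP"

recognize_document("右下腹部突发剧烈疼痛", lex, builtin_library(),
                   lab_kb = kb, schema = sch)
#> [[1]]
#> [phrase-based] pain {quadrant pattern=right-lower; body location=abdomen;
#>   temporal pattern=acute; severity=severe; assertion=present(default)}

recognize_document("WBC 12.5 × 10^9/L", lex, builtin_library(),
                   lab_kb = kb, schema = sch)
#> [[1]]
#> [logic-based] leukocyte {specimen=blood(default); analyte=leukocyte;
#>   abnormality=higher} SNOMED:414478003
```

The five-letter sequence `AAAAP` matches the pattern class `A+P`, so the
four attribute triggers all bind to the phenotype *pain*; the assertion
slot defaults to *present* because no negation trigger occurred. The lab
value 12.5 × 10⁹/L exceeds the knowledge-base reference range
(4–10 × 10⁹/L for blood leukocytes), so the abnormality is *higher* and
the instance is normalized to SNOMED CT 414478003.

Learning the pattern library from a corpus:

```r
corp <- generate_corpus(generator_config())   # 500 synthetic documents
res  <- learn_patterns(corp, seed = 1)
res$library$pattern
#> [1] "S*LNU"    "A+P(CP)+" "A*PC*A+"  "S*LR"     "A+P"      "AP+"
```

On the default synthetic corpus the discovery pipeline (EM motif mining
→ O-splitting → reduction → enrichment) recovers exactly the six
built-in pattern classes.

A thin command-line wrapper is installed at `inst/cli/phenossu`
(subcommands `encode`, `discover`, `reduce`, `enrich`, `recognize`,
`simulate`, `evaluate`, `compare`); see `phenossu_cli()`.

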