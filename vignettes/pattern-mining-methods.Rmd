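---
title: "Mining linguistic patterns of phenotype descriptions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining linguistic patterns of phenotype descriptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenossu)
```

## The problem

Clinical narratives describe phenotypes as short, highly conventionalized
phrases: a phenotype concept surrounded by attribute words ("sudden severe
pain in the right-lower abdomen"), an enumeration of negated findings
("no fever or fatigue"), or a laboratory result whose clinical meaning only
emerges when the number is compared with a reference interval
("WBC 12.5 × 10⁹/L"). `phenossu` structures such text into
entity–attribute–value instances (one phenotype concept plus ten
standardized attribute slots, seven phrase-based and three logic-based)
by *recognizing linguistic patterns*, and — the methodological core —
*learns* those patterns from an annotated corpus with a biological
sequence-motif discovery algorithm rather than by manual rule writing.

The pipeline has four layers:

1. **Encoding.** Text becomes a single-letter sequence over
   {P, A, C, O, S, L, N, U, R} by keyword replacement against a lexicon,
   with a per-letter map back to character spans.
2. **Motif discovery.** Recurring letter arrangements are found by an
   expectation–maximization (EM) motif finder with an
   any-number-of-repetitions site model and a Monte-Carlo significance
   test.
3. **Reduction and enrichment.** Motif-derived segments are abstracted
   into a small library of regular-expression pattern classes; a
   gap-driven loop against the gold annotations fills classes the miner
   missed.
4. **Recognition.** New text is encoded, scanned with the library, and
   matches are assembled into instances; quantitative lab matches are
   normalized against a knowledge base of reference ranges.

## Encoding model

Keyword matching is leftmost-longest over the lexicon's surface forms:
at every position the longest surface starting there wins, numbers are
consumed by a dedicated grammar (optional sign, decimals, `×10^k` or
e-notation exponents, full-width digits), and every maximal unmatched run
collapses to a single `O`. Which characters count as pattern punctuation
(`C`) is lexicon-controlled; in the shipped Chinese lexicon the
enumeration comma maps to `C` while sentence stops fall into `O`, so
patterns never bridge sentence boundaries.

Letter spans are 0-based half-open offsets in code points
(brat-compatible). The spans tile the source text exactly — unmatched
whitespace is absorbed into the nearest letter's span — so concatenating
`decode_span()` over consecutive letters reproduces the document
byte-for-byte. A consequence worth knowing: when users put spaces between
keywords, a keyword's span includes the adjacent whitespace; annotation
spans are exact whenever content tokens are contiguous, which is the
norm in Chinese clinical text.

## The motif model

Given encoded sequences, every length-`w` window is modelled as
independently *motif* (probability `lambda`, letters drawn from a
position weight matrix) or *background* (order-0 letter frequencies with
pseudocount 0.1) — the two-component-mixture form of the
any-number-of-repetitions site distribution. The E-step computes
per-window site posteriors; the M-step re-estimates the pseudocounted
PWM (0.1 per cell) and `lambda`. `lambda` is initialized at
`min(0.1, sqrt(n)/n)` for `n` windows; iteration stops when the
log-likelihood improves by less than a relative `1e-6`, or after 200
iterations. The observed-data log-likelihood is non-decreasing across
iterations, which the test suite asserts on random instances. Final
sites are chosen greedily by descending posterior, non-overlapping
within a sequence, keeping posteriors above 0.5.

**Warm starts.** Every distinct w-mer in the data seeds a one-iteration
EM run (on large corpora, the 100 most frequent w-mers; a deterministic
frequency-then-key ordering makes this independent of sequence order).
The top five warm starts are run to convergence and the fit with the
largest site log-likelihood ratio is kept. Refining a handful of starts
rather than one matters in practice: a single maximum-likelihood basin
can absorb a weak genuine motif into a diffuse fit that models corpus
composition rather than order.

**Significance.** The motif's statistic is the summed log-likelihood
ratio of its selected sites against the background model. The null is
composition-preserving: all unmasked letters of the corpus are permuted
(sequence lengths and masked positions fixed), the same per-width search
is rerun, and `p = (1 + #{null LLR ≥ observed}) / (n_shuffles + 1)`.
The E-value multiplies `p` by the number of widths scanned. Because the
smallest attainable E-value is `n_widths / (n_shuffles + 1)`, the null
must be large enough for the significance threshold (default
`E < 0.05`) to be reachable — with widths 2–8 that means at least 140
shuffles.

**Width selection.** For strongly supported motifs the rank-based
p-values saturate at their minimum for every width, so E-values tie.
Ties are broken by penalized likelihood, `llr − c·w·(A−1)` with `c = 1`
(AIC-style; `A = 9` is the alphabet size), then by the narrower width.
Two alternatives were evaluated and rejected on planted-word instances:
a null z-score tie-break systematically favours degenerate width-2
motifs (their null spread is tiny), and a BIC penalty truncates noisy
planted words because site loss grows with width.

**Sequential discovery.** The best motif per round is reported, its site
letters are masked with a reserved symbol the encoder never emits, and
the search repeats until no motif passes the threshold or `n_motifs` is
reached.

## From motifs to pattern classes

Segments for reduction are the O-free fragments of each motif's
consensus *and of its site words* (the actual letter words at the
selected sites). Site words matter: the argmax consensus of a family
that mixes widths (AP, AAP, AAAP) is a single word, while the site words
retain exactly the within-class variation that reduction abstracts over.

`reduce_segments()` works on letter runs:

* repetitions of `CP` pairs after a phenotype fold into an enumeration
  group `(CP)+`; in such conjunction families the pre-phenotype
  attribute run is treated as open-ended (`A+`), since the attribute
  block distributes over an unbounded list of phenotypes;
* within a skeleton family, a run whose length varies across members
  becomes `X+`, a constant run stays literal; when two run positions
  vary in one family, the family is split so each part varies in one
  position only — this is precisely what keeps `A+P` (stacked
  attributes) distinct from `AP+` (one attribute, several phenotypes);
* families whose skeletons differ only by absent specimen or
  punctuation runs, or absent pre-phenotype attribute runs, merge with
  the absent run marked `X*` (so {SLNU, LNU} → `S*LNU`);
* segments are trimmed of edge punctuation, and fragments that bind no
  attribute-bearing letter (no A/S/L/R) or carry a number with no
  following unit are dropped — a pattern that cannot bind an attribute
  cannot drive attribute prediction.

Enrichment then recognizes the gold documents with the current library;
every gold instance not recovered exactly contributes the letter word of
its minimal covering span, the words are abstracted by the same
reduction, and new patterns enter the library flagged for review. The
loop reaches a fixed point on fixed documents. The final library is
rebuilt by one reduction over the union of discovery segments and
enrichment words — variants of one class discovered through different
routes must abstract together — and consolidated by dropping patterns
whose language another pattern contains (a literal `AAP` next to `A+P`
adds nothing).

## Recognition and lab normalization

Scanning is left-to-right with priority = longest literal skeleton
first, then insertion order; at each position the highest-priority
matching pattern wins with its greedy match length, and matches never
overlap. Assembly emits one instance per `P`: attribute letters before
the first phenotype apply to every phenotype in the match, attribute
letters after a phenotype attach to the nearest preceding one, and
same-category conflicts resolve to the trigger nearest the phenotype
(with a warning). An instance with no assertion trigger takes the schema
default `assertion = present`; other phrase-based slots appear only when
evidenced. Whether one attribute should distribute over all phenotypes
of an `AP+` match is linguistically ambiguous; this implementation
propagates to all, which users should keep in mind for enumerations
with heterogeneous attributes.

Quantitative matches (`S*LNU`) are normalized by resolving the analyte
(specimen-disambiguated when given), converting the value to the
entry's canonical unit by a multiplicative factor, and comparing with
the reference interval, which is treated as *closed*: a value exactly on
a bound is `normal`. Unresolved analytes and unconvertible units yield
error records carrying a diagnostic note, not exceptions. Qualitative
matches (`S*LR`) take the direction word's normalization directly.

## The synthetic corpus generator

The study corpus this method was developed for is not distributable, so
the package ships a generator that emulates its structure: every
sentence instantiates one of the six pattern classes with tokens drawn
from a generator lexicon, interleaved with sentence stops and filler
phrases that encode as `O`. Defaults: 500 documents, 2–4 sentences per
document, class weights (0.20, 0.15, 0.25, 0.15, 0.15, 0.10) for
A+P(CP)+, AP+, A+P, A\*PC\*A+, S\*LNU, S\*LR, filler probability 0.5,
seed 42 — chosen once as a plausible desk-scale stand-in for a
respiratory-disease EHR collection in which stacked-attribute and
negated-enumeration sentences dominate. Content tokens are concatenated
without internal separators (as in Chinese text), which keeps gold
annotation spans exact. Lab values are drawn away from the reference
bounds (10% of the interval width) so that rounding cannot flip the
intended abnormality. The generator emits gold brat standoff and
instance files; on noise-free output the recognizer reproduces the gold
instances exactly, and the test suite asserts this end to end.

What the generator does *not* emulate: real lexical ambiguity,
segmentation errors, misspellings, cross-sentence discourse, section
structure, or the empirical frequency profile of pattern classes in any
real EHR collection. Passing tests on synthetic corpora therefore
demonstrate the correctness of the machinery, not field performance.

## Problem sizes and numerical choices

The end-to-end pattern-recovery check runs on the default 500-document
corpus with widths 2–8, up to 25 motifs, 149 null shuffles per round and
threshold `E < 0.05` (the smallest attainable E-value is then
7/150 ≈ 0.047); this takes a few minutes on one core, with the EM core
in C++. Planted-word checks use 20 copies of the logic-class word
`SLNU` in ten 50-letter uniform-background sequences at 0% and 10%
letter noise; null calibration uses twenty replicates of uniform random
corpora. Ties everywhere break deterministically (frequency then key for
seeds; E then penalized LLR then width for motifs; skeleton length then
insertion order for patterns). All randomness flows from explicit seed
arguments through a private RNG stream, so no function disturbs the
caller's `.Random.seed`.

## Known limitations

* The encoder is a dictionary matcher: it does not segment, stem, or
  correct spelling, and recognition quality is bounded by lexicon
  coverage. An external NER's spans could replace the dictionary by
  supplying an equivalent lexicon of matched surfaces.
* Patterns are category-blind (letters, not attribute categories), as
  in the underlying method; two same-category attributes in one match
  cannot both be kept.
* The Monte-Carlo E-value is rank-based: its resolution is limited by
  the number of shuffles, and discovery cost scales linearly with it.
* Reference intervals are single-valued; age- and sex-specific ranges
  are out of scope.

## A worked call

```{r example, eval = FALSE}
lex <- load_lexicon(phenossu_file("lexicon_zh.tsv"))
kb <- load_lab_kb(phenossu_file("lab_kb.tsv"))
sch <- load_schema(phenossu_file("phenossu_schema.tsv"))
recognize_document("WBC 12.5 × 10^9/L", lex, builtin_library(),
                   lab_kb = kb, schema = sch)

corp <- generate_corpus(generator_config(n_docs = 200))
res <- learn_patterns(corp, seed = 1)
res$library
```
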