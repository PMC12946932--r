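---
title: "From free text to a PHQ-9 severity band and a SNOMED CT concept: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From free text to a PHQ-9 severity band and a SNOMED CT concept: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phqscreen turns a free-text account of someone's mental state into four
linked artifacts: a yes/no checklist over the nine PHQ-9 depression items, a
0-27 severity score with its standard band, the closest SNOMED CT concept
for the resulting diagnosis label, and a deterministic explanation that ties
each of those back to the evidence in the text. This vignette describes the
models and procedures behind each stage, the parameters that matter, and the
limits of what the packaged synthetic evaluation can show.

```{r setup}
library(phqscreen)
```

## The screening instrument

The PHQ-9 asks how often, over the last two weeks, the respondent has been
bothered by each of nine depressive symptoms, on a 0 ("not at all") to 3
("nearly every day") frequency scale. The total score ranges 0-27 and maps
onto five severity bands at fixed cut points: 0-4 minimal, 5-9 mild, 10-14
moderate, 15-19 moderately severe, 20-27 severe. `severity_band()`
implements that lookup on closed integer intervals, exactly as printed;
`total_and_band()` additionally builds the diagnosis label `"<band>
depression"` that downstream attribution consumes.

## Evidence channel 1: the symptom ontology

A symptom ontology is a lexicon mapping surface phrases ("loss of
interest", "cannot sleep", "feeling like a failure") to items S1-S9,
optionally with a frequency weight on the same 0-3 scale. `match_cues()`
performs exact phrase matching on normalized text (lowercased,
punctuation-stripped, whitespace-collapsed), with these deliberate choices:

* **No stemming or fuzzy matching.** Semantic expansion is treated as the
  ontology author's job; keeping the matcher exact makes it fully auditable
  and testable against a brute-force oracle.
* **Longest match wins, left to right, non-overlapping.** Ties at the same
  position cannot involve distinct phrases (equal spans imply equal
  strings), but one phrase listed under two items yields one match per item.
* **Temporal modifiers scope to the sentence.** "nearly every day" upgrades
  a cue's frequency to 3, "more than half the days" to 2, "several days" to
  1; sentences are delimited by `.`, `!`, `?`. Offsets are 0-based,
  half-open, into the normalized text.

The packaged ontology (`default_ontology_path()`) carries six curated
phrases per item. It is a working fixture, not a clinically validated
lexicon; real deployments would substitute a clinician-reviewed file in the
same CSV format.

## Evidence channel 2: embeddings and the item classifier

Text is preprocessed (lowercase, punctuation stripped, ~150 packaged stop
words removed, truncated at 128 tokens) and embedded by mean pooling of
per-token vectors followed by L2 normalization. Because mean pooling makes
pad tokens a no-op, the 128-token budget is realized as truncation only.

The built-in **reference embedder** encodes each token as a feature-hashed
character-3-gram count vector (token wrapped as `^token$`; each 3-gram
hashed to one of `dim` buckets, sign from a second hash, L2-normalized; 128
dimensions by default). It is deterministic across platforms, needs no model
download, and places morphologically similar tokens near each other — which
is what the attribution reranker needs. It is *not* a semantic model:
synonyms with different surfaces ("insomnia" vs "cannot sleep") are
near-orthogonal. An external sentence-transformer can be plugged in through
`make_embedder(token_fun = ...)` under the same contract (fixed dimension,
finite values); all packaged tests use the reference embedder only.

The classifier is a feedforward network: the embedding feeds a fully
connected 128-unit hidden layer with ReLU, then a softmax output over the
nine items. It is trained with mini-batch Adam (learning rate 0.001),
cross-entropy loss, 32 epochs; batch size 16, He initialization and seeded
shuffling are package choices the cited recipe left open. Each training post
contributes one (embedding, item) pair per positively annotated item.
At inference the text is split into sentences, and each sentence's argmax
item is **emitted only if its softmax probability reaches the confidence
threshold 0.55**; strictly lower probabilities are suppressed. That
suppression rule, not a tenth "background" class, is what keeps neutral
sentences out of the checklist: an off-topic sentence tends toward a flat
distribution (max well under 0.55).

The checklist combines both channels by an auditable OR: an item is "yes"
iff the classifier emitted it in at least one sentence or the ontology
matched at least one cue for it. Each "yes" therefore carries its
provenance (a confidence at or above 0.55, supporting cue spans, or both).

## From binary checklist to 0-3 item scores

Corpus annotations are binary, but PHQ-9 items are ordinal. The only
frequency signal available in text is linguistic, so item scores come from
the matched cues: a "no" scores 0; a "yes" scores the maximum cue frequency,
floored at 1. Presence without any temporal evidence thus scores the most
conservative positive value, 1 ("several days"). No DSM-style diagnostic
algorithm is applied; the diagnosis label is purely the severity band.

## SNOMED CT attribution

The diagnosis label is normalized to a concept in an RF2-style description
table by candidate generation and reranking:

1. **Keyword filter**: the label is normalized, stop words are removed, and
   a case-insensitive word-boundary alternation over the keywords selects
   candidate rows ("press" cannot hit "depression").
2. **Cosine rerank**: the label and each candidate term are embedded
   (preprocess, mean pool) and candidates are sorted by cosine similarity,
   ties broken by shorter term then lexicographically smaller conceptId so
   results are platform-independent.

An exact-term candidate always wins with similarity 1. A table row matching
no keyword can never influence the result. When no row matches any keyword
the stage returns a distinct no-match value rather than an error, and the
explanation says so. A clinician override map (label to conceptId) is
consulted before matching, and override decisions can be appended to a
JSONL feedback log; learning from that log is out of scope.

The packaged description table (`snomed_fixture_table()`) is **synthetic**:
real SNOMED CT releases are licensed and cannot ship. It reproduces two
published concept rows used in the documentation — "Depressed mood
(finding)", conceptId 366979004, and "Moderate major depression", conceptId
370143000 — and fills the rest with severity-band phrasings, psychiatric
neighbours and non-psychiatric distractors under clearly fake 9xxxxxx
identifiers.

## Explanations and their quality measures

`explain()` is a pure template engine: per-item rationales cite the detected
cue phrases and the frequency wording implied by the item score, and the
narrative states the total, band, elevated items (score of at least 2) and the
attributed concept with its identifier. Identical inputs give byte-identical
output; there is no sampling and no external model in the default path (a
`postprocess` hook exists for one). Three similarity measures accompany it:
plain `cosine_similarity()`; `semantic_similarity()` between two texts via
their embeddings; and `context_relevance()`, defined here as the share of
the input's distinct content tokens that the explanation reuses — the
numerator and denominator of that ratio were genuinely open, and this
set-overlap reading was chosen because it is the simplest one guaranteed to
land in [0, 1].

## The synthetic corpus generator

`generate_posts()` emulates a social-media-style annotated corpus: each post
draws 0-3 positive items uniformly; each positive item yields one symptom
sentence, which with probability 0.9 (`cue_rate`) plants an exact ontology
phrase (with probability 0.5 of carrying a temporal modifier) and otherwise
uses a paraphrase worded without any ontology term; one to three neutral
filler sentences are mixed in, and sentence order is shuffled. Annotations
mark exactly the planted items. The paraphrase share is the package's
resolution of an under-specified point: it models posts whose annotation has
no lexicon-visible trigger, and it is the only reason the trained classifier
can beat the lexicon alone. Filler and paraphrase banks are checked by the
test suite to be free of ontology phrases, so gold labels are exact.

What the generator does *not* emulate: real discourse style, negation
("I never feel down"), sarcasm, co-morbid topics, or annotator disagreement.
A green synthetic evaluation therefore demonstrates that the machinery
recovers planted signal under the stated noise model — it says nothing
about performance on real clinical or social-media text.

## Numerical and design notes

* Emission boundary: a probability exactly at 0.55 is emitted; suppression
  is strictly below, per the stated rule.
* Zero vectors: an empty token sequence embeds to the zero vector, and any
  similarity against it is defined as 0.
* Metric conventions: precision and recall are 0 (not NaN) when their
  denominators vanish, as is F1 when both are 0. The evaluation report
  offers micro (pooled over all post-item decisions, the default), macro and
  per-item views, since single-number reports for a multi-item task are
  ambiguous about pooling.
* Determinism: all randomness flows through explicit seeds
  (`generator_config()`, `classifier_hyperparams()`); no function touches
  the global RNG state without restoring it.
* Problem sizes: the packaged evaluation trains on 500 generated posts and
  scores 100 fresh ones, averaged over 5 seeds, which is ample to estimate
  recovery of the planted signal; the classifier unit example uses a
  balanced single-cue-per-item corpus (504/99), the regime in which a
  nearest-centroid baseline is a meaningful oracle for a surface-form
  embedder.

## A worked run

```{r}
embedder <- make_embedder()
ontology <- load_ontology(default_ontology_path())
snomed <- snomed_fixture_table()

train <- generate_posts(generator_config(500, seed = 1), ontology)
model <- train_classifier(train, embedder, classifier_hyperparams(seed = 1))

text <- paste(
  "I have been feeling down nearly every day.",
  "I cannot sleep.",
  "I have no energy nearly every day.",
  "I feel worthless nearly every day.")
result <- assess(text, model, ontology, snomed, embedder)
result$assessment$total_score
result$assessment$band
result$snomed_match$conceptId
print(result$explanation)
```

## Known limitations

The ontology matcher cannot see negation or hypotheticals; a post saying "I
do not feel hopeless" matches the S2 cue. The reference embedder is
surface-based, so the classifier generalizes across paraphrases only insofar
as they share character 3-grams with training text. Severity rests entirely
on detected frequency phrases, which underestimates respondents who do not
use PHQ-9-style temporal language. None of the outputs are a clinical
diagnosis; the intended consumer is a clinician reviewing the evidence trail.
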