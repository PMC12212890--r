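---
title: "Quantifying mortality misrepresentation in film: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mortality misrepresentation in film}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinemort)
```

## The problem

Crowd-sourced movie wikis catalogue tens of thousands of on-screen character
deaths, each as a one-to-two-sentence free-text description attached to an
actor's page. Set against a national vital-statistics reference — the 2021
NVSS leading causes of death by gender for the United States — such a corpus
lets us ask two questions: which causes of death does cinema over- or
under-represent, and within each cause, how does the on-screen gender split
compare with the real one?

`cinemort` implements that comparison as a pipeline of five testable stages:
ingestion of a MediaWiki-style XML dump (or CSV), rule-based cause-of-death
classification on word stems, name-dictionary gender classification with a
consolidation rule, a packaged and validated NVSS reference table, and a
per-cause chi-square battery with representation-ratio summaries. A
synthetic-corpus generator with planted structure makes every stage testable
without the (unarchived) real dump.

## Statistical model

### Representation ratios

For cause $c$, let $s^{\mathrm{film}}_c$ and $s^{\mathrm{ref}}_c$ be the
cause's share of all deaths *within* each dataset. The representation ratio
is

$$R_c = \frac{s^{\mathrm{film}}_c}{s^{\mathrm{ref}}_c},$$

with $R_c > 1$ meaning the cause is overrepresented in film. Only
within-dataset shares make the identity line of the share-vs-share scatter
mean "equal representation"; a raw-counts mode is provided for completeness
but the default plot uses shares on log-log axes.

### The gender goodness-of-fit test

For each cause, the observed film gender counts $(O_m, O_w)$,
$n = O_m + O_w$, are tested against the fixed real-life male proportion
$p_c = \mathrm{men}_c / (\mathrm{men}_c + \mathrm{women}_c)$ from the
reference table:

$$X^2 = \frac{(O_m - n p_c)^2}{n p_c} + \frac{(O_w - n(1-p_c))^2}{n(1-p_c)},
\qquad X^2 \sim \chi^2_1 \text{ under } H_0,$$

with no continuity correction. Two readings of "Pearson chi-square" exist
here — this one-sample goodness-of-fit, and a 2×2 independence test of
source × gender. They diverge whenever the film sample is not negligible
relative to the reference counts (for suicide the independence statistic is
503.4 against the goodness-of-fit 545.5), and only the goodness-of-fit
reading reproduces the published battery from the published counts, so it is
the default; `run_battery(..., mode = "independence")` gives the other.

```{r}
ref <- load_reference()
p_men <- gender_proportion(ref, "heart")["p_men"]
gender_gof_chisq(477, 171, p_men)$chi2
```

### Applicability rule

The test is only reported for causes with at least 5 *observed* film deaths
(the threshold applies to observed counts, not expected cell counts, because
the rule is stated in terms of observations in films). Causes below the
threshold appear in the battery with a dash and no statistic.

## Rule-based cause classification

Descriptions are lowercased, punctuation-stripped, tokenized, and passed
through a light suffix stemmer (plural / `-ed` / `-ing` stripping in the
style of the first Porter step). The packaged stemmer exists because no
Snowball binding is assumed at runtime; since the lexicon, the synthetic
templates, and the corpus text all pass through the *same* stemmer, matching
is self-consistent and no external stemmer agreement is required.

The lexicon (`inst/extdata/cause_lexicon.json`, version
`cinemort-lexicon-1.0.0`) maps each of the 12 named causes to colloquial
phrases ("heart attack", "stroke", "kills himself", ...), compiled at load
into single stems and stem bigrams; bigrams match on adjacent stems *after*
stopword removal, so "dies of a heart attack" matches "heart attack". Load
validation enforces that no pattern belongs to two causes, every named cause
has a pattern, and `other` — the fallback — has none. Ties between matching
causes break by the NVSS table order (heart first) and are logged; homicide
and most violent deaths deliberately fall into `other`, which is not a
top-10 category. Negation is not modelled: every database entry is a death
by construction. Exact replication of any particular research group's stem
list is impossible from published examples alone, so reproducibility is
achieved by versioning the shipped lexicon and embedding its version in
every report manifest.

## Gender classification

The actor's first name (page titles are per-actor) is looked up in a name
dictionary with the six-label vocabulary `male`, `female`, `mostly_male`,
`mostly_female`, `androgynous`, `unknown`, then consolidated:
mostly-male joins male ("man"), mostly-female joins female ("woman"), and
androgynous/unknown entries are excluded from gender-stratified statistics
while remaining in overall cause counts. Hyphenated names are looked up in
full first, then by first component. The packaged dictionary is a small
**synthetic** list (~160 names) in the same two-column format as exports of
the large open name-gender databases; substitute any such file via
`load_name_dictionary(path)`. Consequences: corpus-level gender coverage
numbers obtained with the packaged dictionary characterize the synthetic
world, not any real corpus. Nonbinary identities are not modelled — a stated
limitation of the binary reference data this package compares against.

## The synthetic world

`generate_corpus()` plants known structure: each entry samples a cause from
a mixture, a gender from a per-cause $P(\text{man})$, a name from the pool
matching the planted gender (or, with probability
`ambiguous_name_fraction`, from an androgynous/unknown pool), a year uniform
on the year range, and a description template embedding exactly one lexicon
phrase for the planted cause. Template filler avoids every lexicon stem, so
cause recall is 1 by construction and the truth table is exact.

Defaults state the published film-side world: per-cause masses 648 (heart),
72 (cerebrovascular), 2,382 (suicide), 1,250 (accidents) per 68,535 deaths
with the remainder mostly `other`; per-cause male proportions 0.736, 0.694,
0.603, 0.612 with 0.709 (the corpus-wide male share) elsewhere; 13%
ambiguous names (the published excluded fraction); years uniform on
1895–2023; film-only media. These were fixed once, before any test was run.

What a green synthetic test does and does not establish: it proves the
pipeline's plumbing — conservation of counts, exact recall on template
text, binomial-accurate recovery of planted mixtures, round-tripping of the
XML and CSV formats. It does not establish classifier accuracy on real
free-text prose (vocabulary outside the lexicon, sarcasm, multi-death
sentences), name-dictionary coverage of real actor names, or the published
full-corpus statistics, all of which need the real dump.

## Numerical and design choices

* **Percentiles** use the nearest-rank convention (`quantile type = 1`), so
  reported years are always observed years.
* **Reference proportions** are recomputed from counts, never taken from
  printed percentages; the NVSS diabetes row, whose printed gender counts do
  not sum to its printed total, is stored as printed and *flagged*, with
  proportions computed over `men + women`.
* **Entry grammar**: one wiki list item is one entry; the film title is the
  italic/link span (else the capitalized word run) before the first
  parenthesized 4-digit year. Entries describing several deaths in one
  sentence count once — the database is organized per actor.
* **Medium**: category tags when present, else keyword evidence
  ("episode"/"season" → television, "video game" → video game); entries with
  no evidence count as film. Duplicate entries are kept and reported, not
  deduplicated.
* **P-value display**: three decimals, `<.001` below 0.001.
* **Uniformity property**: the two-cell test's p-values are *discrete* under
  a binomial null, so a plain KS test against a continuous uniform
  over-rejects at n = 500 regardless of implementation correctness. The
  property suite therefore applies the standard randomized-p transform
  $P(X > x) + U\,P(X = x)$ — exactly uniform under the null for any discrete
  test — and separately checks the plain p-values' rejection rate at
  $\alpha = 0.05$ against a 3σ binomial band.
* **Tie-break, threshold, and mixture defaults** are frozen in code and were
  not adjusted after observing test outcomes.

## Known limitations

The lexicon is intentionally broad and shallow — no negation handling, no
multi-cause attribution (single assignment with logged multi-match
frequency), no machine learning. The packaged name dictionary is synthetic
and small. Full-corpus published results (overall point positions, the
"other"-category statistic, rows whose film counts were never printed) are
out of desk-reproducible reach without the original dump; the battery
computes them the moment a user supplies the corresponding counts tables.
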