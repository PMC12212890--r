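# cinemort

Quantifies how on-screen deaths misrepresent real-world mortality — overall
and by gender — by comparing a crowd-sourced corpus of film-death
descriptions against the 2021 US National Vital Statistics System (NVSS)
leading causes of death.

It is written for researchers in media epidemiology and computational social
science who have (a) a MediaWiki-style XML dump or CSV of short free-text
death entries organized per actor and (b) a per-cause, per-gender mortality
reference, and want a reproducible, fully tested pipeline from raw dump to
statistics and figures.

## The method

For each cause *c* (the 12 named NVSS leading causes plus "other"):

* **Representation ratio** — within-dataset shares
  *R_c = s_film(c) / s_ref(c)*; *R_c* > 1 means cinema overrepresents the
  cause (above the identity line of the share-vs-share scatter).
* **Gender goodness-of-fit** — observed film gender counts *(O_m, O_w)*,
  *n = O_m + O_w*, tested against the real-life male proportion
  *p_c = men_c / (men_c + women_c)*:

  *X² = (O_m − n·p_c)²/(n·p_c) + (O_w − n·(1−p_c))²/(n·(1−p_c))*,
  df = 1, upper-tail p, no continuity correction. Causes with fewer than 5
  observed film deaths are reported with a dash (test inapplicable).

Pipeline stages: XML/CSV ingestion with a per-entry grammar → medium filter
(film only by default; television/video-game entries excluded) → stem-lexicon
cause classification → name-dictionary gender classification with the
mostly-male→man / mostly-female→woman consolidation (androgynous/unknown
excluded) → comparison against the packaged, validated NVSS 2021 table.
A synthetic-corpus generator with planted cause/gender mixtures makes every
stage testable end to end. See `vignettes/mortality-representation.Rmd` for
the model, assumptions, and design choices.

## Worked example

Per-gender film death counts for four causes (men, women): heart 477/171,
cerebrovascular 50/22, suicide 1437/945, accidents 765/485.

```r
library(cinemort)
ref  <- load_reference()                    # packaged NVSS 2021 table
film <- mortality_table(
  cause = c("heart", "cerebrovascular", "suicide", "accidents"),
  men   = c(477L, 50L, 1437L, 765L),
  women = c(171L, 22L, 945L, 485L))
run_battery(film, ref)
```

```
                     Cause of death Chi-square (df) P value
                          Accidents       15.82 (1)   <.001
                  Alzheimer disease               —       —
                           COVID-19               —       —
                             Cancer               —       —
            Cerebrovascular disease       19.72 (1)   <.001
              Chronic liver disease               —       —
 Chronic lower respiratory diseases               —       —
                  Diabetes mellitus               —       —
                  Diseases of heart       87.57 (1)   <.001
             Essential hypertension               —       —
                          Nephritis               —       —
                              Other               —       —
                            Suicide      545.54 (1)   <.001
```

Reading: 73.6% of film heart-disease deaths are men versus 55.3% in real
life (X² = 87.57, p < .001) — men are overrepresented; for suicide the film
male share (60.3%) falls *below* the real-life 79.6% (X² = 545.54), i.e.
women's suicides are overrepresented on screen. Dashes mark causes with
fewer than 5 film observations, where the test is not reported.

Full pipeline from a dump:

```r
report <- run_pipeline(list(dump = "dump.xml", out_dir = "report"))
# writes year_percentiles.csv, gender_tally.csv, cause_counts.csv,
# shares.csv, battery.csv, two figures, and manifest.json
```

Synthetic end-to-end check:

```r
sim <- generate_corpus(generator_config(n_entries = 10000, seed = 1))
cr  <- classify_corpus(sim$corpus, load_lexicon())
gr  <- classify_genders(sim$corpus, load_name_dictionary())
evaluate_recovery(sim$truth, cr, gr)   # recall 1, excluded ~ 0.13
```

A CLI wrapper ships in `inst/exec/cinemort`
(`ingest`, `classify-cause`, `classify-gender`, `compare`, `synth`, `run`).

## Notes on packaged data

* `inst/extdata/nvss2021_reference.csv` — NVSS 2021 counts as published;
  the diabetes row's printed inconsistency is flagged, not corrected.
* `inst/extdata/cause_lexicon.json` — versioned stem lexicon; every report
  manifest embeds the version.
* `inst/extdata/names_synthetic.tsv` — a small **synthetic** name-gender
  dictionary; substitute any same-format dictionary for real corpora.
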