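---
title: "Triage of incidental panel findings: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of incidental panel findings: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chtriage)
```

## The problem and the model

Germline hereditary-cancer panels sequence peripheral blood leukocyte (PBL)
DNA and read any pathogenic call as constitutional. Three non-germline
processes break that assumption, each with a characteristic allele-fraction
(AF) signature across tissues:

| etiology | blood AF | skin biopsy | cultured fibroblasts / muscle / buccal |
|---|---|---|---|
| heterozygous germline | ~50% | ~50% | ~50% |
| post-zygotic mosaic | sub-het, shared | sub-het | sub-het |
| clonal hematopoiesis (CH) | low, may drift between draws | low carry-over (blood contamination) | absent |
| hematologic malignancy | any, can exceed 70% | carry-over | absent |

`chtriage` encodes the clinical workflow built on those signatures: screen
for suspicious results, grade per-tissue evidence, then walk a deterministic
first-match rule cascade. The cascade's assumptions are the laboratory's
empirical heterozygous band (30–70% AF), the preference for leukocyte-free
tissues (cultured fibroblasts, muscle, buccal swabs) as germline
surrogates, and the primacy of chart review: a documented hematologic
malignancy explains a blood clone regardless of counts, whereas an abnormal
white-cell count alone only raises a flag (`cbc_flag`) and a CBC-monitoring
follow-up, never a relabel.

## Thresholds that matter

All AF thresholds live in `threshold_config()` (percent units):

* `het_low = 30`, `het_high = 70` — the heterozygous calling band.
* `detection_floor = 1` — below this, a reported fraction is treated as
  assay noise (an 0.87% skin value is an absent call, not trace positivity).
* `trace_ceiling = 10` — detected-but-trace; the level at which direct-skin
  positivity is most plausibly blood carry-over.
* `contamination_ratio = 0.5` — a direct-skin fraction at or below half the
  patient's **maximum** blood AF is flagged as suspected contamination. The
  maximum across draws is used because blood clones wax and wane; the
  largest observed clone bounds the achievable carry-over.
* `category2_lower = 1`, `category2_upper = 28` — the low-AF screening
  band. The nominal definition of a low-AF finding is 10–30%, but the
  operative one in practice reaches the assay noise floor (validated calls
  at 5.8% and 7.2% are unambiguous low-AF findings), while fractions within
  two points of the 30% heterozygous floor behave as borderline
  heterozygous rather than low (a 29% call co-occurring with a 38% call is
  a multiple-variant pattern, not a low-AF one). Both bounds are config;
  `threshold_config(category2_lower = 10, category2_upper = 30)` restores
  the strict nominal band.
* `tumour_germline_min = 30` — a germline allele should persist in tumour;
  a tumour AF below this (or absence) counts against germline (rule D1).
* `borderline_het_max = 50` — a het-band variant strictly below the
  canonical 50% expectation is "borderline" and eligible for the
  co-occurring-variant contradiction (D3); a variant sitting exactly at 50%
  is not second-guessed on the strength of a neighbour alone.
* `wbc_normal_low = 4`, `wbc_normal_high = 11` (×10⁹/L) — the CBC flag
  band. The source workflow does not state the range it used; this default
  is the common adult reference interval and is configurable.

The Chompret evaluation (`chompret_rules()`) is data, not code: a keyword
spectrum per tumour category (so "Ductal Carcinoma In-Situ" resolves to the
breast category), age bounds for the familial (proband < 46, relative
< 56), multiple-primary (first < 46), rare-tumour and early-breast (< 31)
criteria. Missing ages never satisfy an age bound — removing information
can only keep or lose criteria, never create them — so screening is
conservative in the direction that sends more *TP53* carriers into the
workup.

## The cascade, and the choices that were genuinely open

Rules fire first-match: G1, G2 (germline), M1 (mosaic), C1–C4
(malignancy/CH), with contradiction rules D1–D4 logged whenever they hold.
Several boundaries are not forced by the published account and were decided
here; each is recorded in the evidence trail when it acts.

* **"Detected in a second tissue" (M1)** accepts any non-absent,
  non-contamination-suspected call — including trace-level and unquantified
  positivity (a variant "present in a duodenal polyp" with no AF printed is
  still a second-tissue detection). An absent high-reliability tissue
  vetoes M1: when culture contradicts the direct biopsy, culture wins.
* **Likely germline (G2)** requires a het-band blood AF *and* nothing
  pulling the other way: no high-reliability tissue available, no absent
  secondary tissue, no D rule, no chart malignancy. A het-band variant
  whose only secondary evidence is a consistent direct-skin call remains
  likely germline rather than unresolved.
* **Chart dominance (C1)** fires on a chart hematologic-malignancy
  diagnosis with any blood-detected variant, with or without secondary
  tissue. Only the structured chart field counts; the cancer-history list
  is never keyword-scanned (a remote polycythemia vera in the history must
  not convert a likely-CH patient into a malignancy case).
* **Confirmed vs likely CH (C2/C3)**: confirmation needs an informative
  negative — an absent high-reliability tissue, or absent direct skin
  corroborated by a second absent tissue. Everything thinner (nothing
  sampled, low-reliability only, or skin positivity already explained as
  contamination) is likely CH.
* **Patient-level label**: the conclusion of the variant(s) that triggered
  inclusion; several CH-family labels collapse to the most confirmed;
  mixed-family ties resolve by clinical priority (malignancy > full
  germline > mosaic > CH > likely germline). Non-triggering het-band
  variants surface as co-findings and add hereditary-surveillance and
  family-testing follow-ups.
* **Skin-limited variants** (detected in skin, explicitly absent in blood)
  are somatic events of the skin: annotated, screened as a low-AF
  secondary-tissue finding, but never classified into an etiology label and
  never allowed to influence the blood variant's conclusion.

Degenerate inputs are handled conservatively: interval AF estimates
(copy-number calls printed as ranges) act through their midpoint; "~"
values are point estimates; a quantified 0% is an explicit absent call;
ties between multiple draws of one tissue keep the highest-AF call;
patients with no firing rule end `UNRESOLVED` rather than forced into a
label.

## What the synthetic generator emulates — and what it does not

`sim_config()` draws cohorts with known etiology so every stage can be
scored against truth. It emulates: heterozygous germline variants (true AF
50 in all tissues), mosaics (one sub-het fraction shared across tissues;
cell fractions 5–30%, AF half that), CH clones (blood-restricted, cell
fractions 4–50%, multiplicative drift 0.7–1.3× between draws, direct-skin
carry-over at 0–0.5× the blood AF, chemotherapy enriched), malignancy
clones (blood AF 30–85%, log-normal high white-cell counts, chart diagnosis
set), and screen-negative controls (benign-only findings, or heterozygous
*TP53* carriers whose history satisfies Chompret). Binomial read sampling
at configurable depth (default 500×, the panel's working coverage) is the
only noise model. Germline and malignancy arms draw *TP53* because the
family-history gate is what admits an apparently ordinary heterozygous
finding into the workup at all; secondary-tissue availability is sampled
per tissue with cultured fibroblasts most likely (0.7), reflecting a cohort
managed per the workflow's own recommendation. Etiology weights follow the
reference cohort's proportions with a 20% control margin.

It does **not** emulate: clonal dynamics over time beyond a single drift
factor, UMI/error-model AF uncertainty, realistic pedigrees (relatives are
non-spectrum by construction in non-control arms), panel-wide multi-variant
genotypes, or tumour purity. Passing recovery tests therefore shows the
rules separate the *idealized* signatures at realistic depth — not that
real-world sensitivity will match, particularly for CH clones whose blood
AF drifts into the heterozygous band, which the generator shows are
misread as likely germline exactly as they are in the clinic when no
secondary tissue is taken.

Problem sizes used in the validation scripts and tests: 1000 patients at
depth 500 for recovery, 400 per depth for the 50/200/500/2000× sweep,
binomial-moment checks at 10,000 replicates.

## Known limitations

* Category assignment at the low/borderline-AF boundary is a judgment call
  in the source material; the default band reproduces its operative
  behaviour, and the strict nominal band is one config call away.
* A whole-gene deletion at the heterozygous floor co-occurring with a
  borderline-het variant is itself labelled likely germline as a
  co-finding; the cascade deliberately refuses to demote a variant solely
  because its neighbour is suspicious unless the neighbour is low-AF (D3).
* AF fluctuation between draws is reported descriptively (`FLX` in the
  evidence trail) and never decisive, since draw-to-draw variance is not
  modelled.
* Pathogenicity is an input (ACMG classification upstream); HGVS strings
  are carried verbatim, not validated against transcripts.
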