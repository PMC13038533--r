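---
title: "Disproportionality signal detection and clinical triage for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection and clinical triage for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous-report databases such as FAERS collect adverse event reports
with no denominator: we observe which drug–event pairs get reported, not
how often events occur among users. Disproportionality analysis asks
whether a pair is reported *more often than expected* if drug and event
were independent, and flags such pairs as safety signals — hypotheses for
follow-up, never incidence or causality estimates.

This package implements that workflow for an ophthalmic target drug
(atropine by ocular administration is the packaged default): ingestion of
the quarterly report tables, regulatory-style cleaning, two
disproportionality statistics with closed-form interval approximations, a
significance rule, and a semiquantitative clinical-priority rubric for
triaging the flagged signals.

## Cleaning model

Four steps, each a pure function on the table bundle:

1. **Deduplication.** Reports arrive from multiple sources; duplicates
   inflate signals. The exact variable-matching rule on
   PRIMARYID/CASEID/CASEVERSION/FDA_DT keeps, per PRIMARYID, the record
   with the latest FDA_DT (ties: largest CASEID, then CASEVERSION), and
   per CASEID only the most recent version. Residual full-key ties keep
   the last record in file order so output is deterministic. Dates are
   held as YYYYMMDD integers — ordering is all the rule needs.
2. **Suspect roles.** Only Primary Suspect and Secondary Suspect drug rows
   participate in target identification; Concomitant and Interacting rows
   are noise for an independent safety profile. Unknown role codes are
   treated as non-suspect (conservative: they cannot create a target case).
3. **Target identification.** Both free-text name fields (DRUGNAME,
   PROD_AI) are matched against generic and brand names after
   normalization (uppercase, punctuation stripped, whitespace collapsed).
   Substring containment is the default because FAERS names carry salts
   and strengths ("ATROPINE SULFATE 1%"); an exact-token mode is available
   for stricter dictionaries. A name hit only counts when the row's route
   is in the accepted set — reports with missing or unspecified routes are
   excluded, so only confirmed ocular administrations are analysed. The
   default accepted set is {OPHTHALMIC, OCULAR, INTRAOCULAR, TOPICAL
   OCULAR}: the source methodology says only "ocular administration", so
   the concrete FAERS route vocabulary is a package decision, and it is
   configurable.
4. **Event extraction.** Reactions are MedDRA preferred terms,
   whitespace-collapsed and case-folded to sentence case; each case
   contributes a *set* of PTs. Missing demographics become an explicit
   "Missing or unknown" category. Ages are converted to years (months/12,
   days/365.25) and binned into `[0,3]`, `(3,18]`, `(18,64]`, `(64,Inf)` —
   the printed strata ≤3 / 4–18 / 19–64 / ≥65 with the interior boundaries
   closed on the young side.

**Counting unit.** All contingency tables count unique (case, term)
pairs: a case contributes a term at most once. Source reports of this kind
of analysis use "records" and "cases" interchangeably; pair-level counting
avoids within-case duplication and makes the four cells partition a fixed
universe. The descriptive summary reports both conventions (case count and
case–PT pair count) so either denominator can be inspected.

## Statistics

For a term with observed pair count $N_{obs}$, drug margin $N_{drug}$,
event margin $N_{event}$ and universe size $N_{total}$:

$$N_{exp} = \frac{N_{drug}\,N_{event}}{N_{total}}, \qquad
  r = \frac{N_{obs}+0.5}{N_{exp}+0.5}, \qquad IC = \log_2 r$$

The +0.5 shrinkage stabilises the ratio for rare events; the information
component is by construction the base-2 log of the same shrunk ratio, an
identity the tests assert on every computed result. Its credible bounds
use the closed-form approximations

$$IC_{025} = IC - 3.3\,(N_{obs}+0.5)^{-1/2} - 2\,(N_{obs}+0.5)^{-3/2}$$
$$IC_{975} = IC + 2.4\,(N_{obs}+0.5)^{-1/2} - 0.5\,(N_{obs}+0.5)^{-3/2}$$

whose width decreases strictly in $N_{obs}$.

Alongside the shrunk ratio, the classical reporting odds ratio
$ROR = ad/bc$ is computed from the 2×2 cells with the Woolf interval
$\exp(\ln ROR \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$. The two estimators coexist
in separate columns (`ror` vs `ror_shrunk`) because published signal
tables print the classical ROR with Woolf CIs while methods sections
define the shrunk ratio; keeping both makes each table reproducible from
its own column. When any cell is zero the Haldane–Anscombe correction
(+0.5 to all four cells) is applied and flagged rather than failing — the
underlying methodology is silent on zero cells, and this is the standard
remedy.

**Signal rule.** A term is significant when its lower ROR bound exceeds 1
*or* its $IC_{025}$ exceeds 0, with at least three records. The "or" is
the literal published criterion; a stricter "both" variant is available by
configuration because published results in practice show both bounds
positive. Scan output is sorted by lower ROR bound (descending) with term
name as tie-break, for reproducible tables.

## Clinical priority rubric

Five dimensions, 0–2 points each: case count (>50 / 10–50 / <10), ROR
(>5 / 2–5 / 1–2), mortality proportion (>50% / 25–50% / <25%, denominator
the term's case count — the simplest reading, since the source never
defines it), DME/IME designation (DME 2, IME 1; DME wins when a term is on
both lists), and an expert-judgment evidence grade (++/+/−) supplied as a
runtime table, never computed — "++" is defined by label/RCT/systematic
review support, which is not machine-derivable. Totals map to tiers: 0–4
weak, 5–7 moderate, 8–10 strong.

Two deliberate resolutions where the printed rubric is ambiguous:

- **Boundary closure.** The printed bins are open ranges; recomputing the
  published 83-row table fixes them: exactly 50 cases scores 1 (required
  by the "Intraocular pressure increased, 50 cases, Moderate (5)" row),
  exactly 5 or 2 on the ROR scores 1, exactly 25% and 50% mortality score
  1. Boundaries without a printed witness take the lower bin.
- **Point vs lower-bound ROR.** The methods text names the lower 95%
  bound, but the published per-row scores (Bradycardia, Retinal
  detachment, Blindness, Incorrect route of product administration) only
  reproduce with the *point* estimate. The default therefore bins on the
  point estimate; `ror_mode = "lower"` gives the other reading.

Under the default configuration 82 of the 83 packaged published rows
reproduce their printed score and tier exactly. The remaining row,
"Toxicity to various agents", prints Moderate (5) but its own printed
inputs (9 cases, ROR 2.13, 2/9 deaths, no designation, ++) sum to 3 under
every reading of the rubric; the tests assert this discordance rather than
reproduce the printed value, and the tier totals consequently come out
69/14 rather than the printed 68/15.

## What the generator emulates

`generate_reports()` produces the same five-table layout the reader
parses, with ground truth: per-report exposure flags, the planted relative
reporting rates, and the injected duplicate ledger. Structure per report:
one demographic row, 1–4 drug rows, 1–3 reaction rows (skewed short), a
configurable fraction of near-duplicates (same CASEID, incremented
CASEVERSION, FDA_DT 30–90 days later, new PRIMARYID) that `deduplicate()`
must collapse to exactly one survivor each.

Defaults, chosen once as a realistic mid-size corpus: 5000 reports, 15%
carrying the target drug, role mix PS/SS/C/I = 0.5/0.2/0.2/0.1, accepted
route on 80% of target rows and missing on 10%, 10% duplicates, sex/age/
country missingness 0.10/0.25/0.05, a 24-term event vocabulary over eight
organ classes. The designed exposed fraction is thus
0.15 × 0.7 × 0.8 = 8.4% of reports.

A planted effect multiplies the event-selection probability of chosen PTs
in exposed reports and renormalizes. The recoverable estimand is therefore
not $\log_2 RR$ itself but the effective relative reporting rate after
renormalization and margin dilution, computed by `planted_ic_limit()`; the
recovery experiment reports bias against both. At the default baseline the
planted pair at RR = 20 has well over 20 expected events, and detection
($IC_{025} > 0$) occurs in every replicate. Under the null (RR = 1) the
fraction of flagged terms is asserted within the pre-registered band
[0, 0.08] — the nominal ~2.5% one-sided level of the $IC_{025}$
approximation plus sampling slack across 24 terms.

What the generator does **not** emulate: drug co-prescription correlation,
reporting trends over time, stimulated-reporting waves, country-specific
coding habits, or free-text misspellings beyond salt/strength suffixes.
Passing tests therefore validate the pipeline's logic and calibration
under clean-world assumptions, not its robustness to every real-data
pathology.

## Numerical and engineering choices

- Dates as integers, never Date objects, in the dedup path; unparseable
  dates become missing with a warning.
- Ties at every deterministic sort are broken by term or file order;
  reruns of `run_pipeline()` with the same config and seed are
  byte-identical (the manifest hashes the analysis config, excluding the
  output location, and contains no timestamps).
- All randomness flows from a single integer seed; replicate seeds are
  derived additively and kept below 2^31.
- Problem sizes in the test suite (300–12 000 generated reports, ten
  replicates per recovery grid point) were chosen to make the stochastic
  assertions stable at fixed seeds while keeping the default suite around
  twenty seconds on one CPU.
- The full-database headline statistics of the motivating analysis
  (e.g. an endophthalmitis $IC_{025}$ of 6.62 against all-FAERS margins)
  cannot be recomputed at desk scale because the database margins are not
  printed; the suite instead checks internal consistency — the IC
  reconstructed from the printed lower bound agrees with $\log_2$ of the
  printed ROR to within 0.05 bits in this tiny-expected-count regime —
  plus the hand-oracle and recovery properties above.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(n_reports = 2000, seed = 42,
                        planted_effects = c(Endophthalmitis = 20))
sim <- generate_reports(cfg)
cases <- clean_reports(sim$tables, default_drug_dictionary(cfg))
scan <- signal_scan(cases, map = default_term_map(cfg))
scan
prioritize_all(scan, events = fixture_event_list())
```

## Limitations

Signals are reporting disproportions, not risks: no denominator, no
causality, confounding by indication untouched (the optional
stratification some workflows add has no published specification here and
is out of scope). The packaged PT→SOC mapping covers only the fixture's
83 terms — users must supply a licensed MedDRA mapping for real analyses —
and the packaged IME/DME designations are frozen to the fixture rather
than to any dated EMA list version. Evidence grades are expert input and
dominate two points of the rubric; different graders will move signals
across the weak/moderate boundary.
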