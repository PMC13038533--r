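# faersignal

Pharmacovigilance signal detection and clinical triage for FAERS-style
spontaneous adverse event reports, built around ophthalmic drug safety
(atropine by ocular administration is the packaged default target).

Spontaneous-report databases have no denominator: they tell you what gets
reported, not how often events occur. Disproportionality analysis flags
drug–event pairs reported more often than expected under independence.
For a pair with observed count `N_obs` and expected count
`N_exp = N_drug * N_event / N_total` computed from the 2×2 margins, the
package computes

- the shrunk ratio `(N_obs + 0.5) / (N_exp + 0.5)` and its information
  component `IC = log2` of that ratio, with the closed-form credible
  bounds `IC025 = IC − 3.3 (N_obs+0.5)^−1/2 − 2 (N_obs+0.5)^−3/2` and
  `IC975 = IC + 2.4 (N_obs+0.5)^−1/2 − 0.5 (N_obs+0.5)^−3/2`;
- the classical reporting odds ratio `ROR = ad/bc` with the Woolf 95% CI
  `exp(ln ROR ± 1.96 √(1/a + 1/b + 1/c + 1/d))` (Haldane +0.5 on zero
  cells, flagged);
- the signal rule: lower ROR bound > 1 **or** `IC025 > 0`, with at least
  three records (a stricter "both" variant is configurable);
- a five-dimension clinical-priority rubric (case count, ROR, mortality
  proportion, EMA DME/IME designation, evidence grade; 0–2 points each)
  with weak (0–4) / moderate (5–7) / strong (8–10) tiers.

Upstream of the statistics it implements the regulatory cleaning steps for
the quarterly `$`-delimited DEMO/DRUG/REAC/OUTC/INDI tables: exact-key
deduplication on PRIMARYID/CASEID/CASEVERSION/FDA_DT, restriction to
Primary/Secondary Suspect drug roles, name matching over DRUGNAME and
PROD_AI with an ocular-route requirement, and MedDRA preferred-term event
extraction with explicit missing categories. A synthetic report generator
with planted relative reporting rates, injected duplicates and known
ground truth makes the whole pipeline testable offline.

## Worked example

```r
library(faersignal)

cfg   <- synthetic_config(n_reports = 2000, seed = 42,
                          planted_effects = c(Endophthalmitis = 20))
sim   <- generate_reports(cfg)
cases <- clean_reports(sim$tables, default_drug_dictionary(cfg))
scan  <- signal_scan(cases, map = default_term_map(cfg))
print(scan, n = 2)
```

```
Disproportionality scan at PT level (24 term(s), 3002 case-term pair(s))
Signal rule: lower ROR bound > 1 OR IC025 > 0, >= 3 records; 1 significant
            term   a n_expected    ror ror_l95 ror_u95    ic ic_025 significant
 Endophthalmitis 107     19.588 15.294  11.254  20.784 2.420  2.100        TRUE
         Pyrexia  10      8.128  1.267   0.650   2.468 0.283 -0.794       FALSE
... and 22 more term(s)
```

The planted endophthalmitis effect is the one flagged signal: 107 exposed
case–PT pairs against 19.6 expected, shrunk ratio 2^2.42 ≈ 5.4-fold
over-reporting, and both lower bounds (`ror_l95` 11.3, `ic_025` 2.10)
clear their thresholds. The remaining 23 terms stay near the null.
Piping the scan into `prioritize_all()` scores each significant signal on
the rubric; on this synthetic run endophthalmitis totals 4 (weak — 107
cases: 2, ROR > 5: 2, no deaths, no designation, no evidence), showing how
statistical strength alone does not make a clinically strong signal.

`run_pipeline()` wraps the whole flow (clean → describe → scan →
prioritize) with CSV/JSON outputs and a byte-reproducible manifest; an
annotation-only mode scores a pre-computed signal table. The packaged
83-row published signal table (`load_table4_fixture()`) reproduces its
printed priority score and tier on 82 of 83 rows under the default rubric
configuration; the single discordant row is a documented internal
inconsistency of the published table.

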