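# PMedProfiler

Personalized-medicine (PMed) drug prediction from tumor expression
profiles, built as a tested, reusable R implementation of a
comparative-oncology profiling workflow: canine tumor biopsies are
expression-profiled, standardized against a normal-tissue reference
compendium, mapped into human identifier space, and scored by six
drug-prediction methods whose calls are aggregated into a ranked
per-patient drug report. The package also implements the study
machinery around the bioinformatics: QA/QC gating of samples,
business-hours turnaround accounting, and MDS clustering of cohorts —
all exercisable end-to-end on synthetic data with planted ground truth.

## Who this is for

Groups evaluating PMed trial designs (in comparative oncology or
elsewhere) who need the full report-generation pipeline as inspectable,
testable code: the statistics behind each prediction method, the QC
gates that decide which samples are profiled, and a synthetic-data
generator that lets every component be validated without any external
download.

## The model

Each tumor sample is reduced to a z-score profile: for probe $g$ with
reference mean $\mu_g$ and standard deviation $\sigma_g$ (over ~40
normal tissues), $z_g = (x_g - \mu_g)/\sigma_g$. Probes are averaged to
genes, genes mapped one-to-one across species (ambiguous homologies
dropped), and the resulting profile scored by:

1. **Drug target expression** — rule base of drug targets; an
   over-expressed target ($z \ge +3$) indicates its antagonist, with
   $p = \bar\Phi(z)$.
2. **Biomarker rules** — curated sensitivity *and* resistance rules in
   both directions ($z \ge +3$ or $z \le -3$); resistance rules
   contraindicate.
3. **Drug response signatures** — Connectivity-Map-style inverse
   connectivity: KS enrichment of the tumor's up/down sets
   ($|z| \ge 2$) in each drug's ranked signature, combined as
   $s = (ES_{up} - ES_{down})/2$ (0 if same-signed), with permutation
   p-values (50,000 permutations by default).
4. **Drug sensitivity signatures** — per-sample parametric gene-set
   enrichment (PGSEA): a one-sample t-test on the signed z-scores of
   each drug's sensitivity signature.
5. **Network target activity** — seed the over-expressed nodes into a
   directed interaction network, build the shortest-path subnetwork
   $S$, count seed pairs routed through each node pair ($K_{ij}$)
   versus the global network ($N_{ij}$), and score pairs by a
   hypergeometric upper tail; significant pairs implicate the drug
   targets they contain.

Methods 3–5 report at $p < 0.05$; every call is scored
$-\log_{10} p$, and a drug's summary score is the sum over indicating
methods — so multi-method drugs outrank equally significant
single-method drugs. Drugs hit by a resistance rule are excluded from
the ranking and listed separately.

## Worked example

```r
library(PMedProfiler)

cfg <- simConfig(seed = 11)          # synthetic study, study-sized KBs
st  <- simulateStudy(cfg)
ref <- computeReferenceStats(st$expression$reference)

# profile one tumor into human-gene space
zp <- profileCohort(st$expression$tumors[, "TCC_01", drop = FALSE],
                    ref, st$annotation$canineAnnot,
                    st$annotation$homologs)[[1]]

report <- predictDrugs(zp, st$kb, nPerm = 2000, seed = 5)
report
```

With an EGFR perturbation of +5 z-units planted in `TCC_01` (and an
ERCC1 perturbation triggering the oxaliplatin resistance exemplar),
this prints:

```
PMedReport for sample TCC_01
52 method calls; 48 ranked drugs; 1 contraindicated
      drug     score nMethods                            methods
 cetuximab 11.247992        2 network-activity+target-expression
   drug124  9.421331        2 network-activity+target-expression
   drug050  5.415897        1                   network-activity
   ...
```

cetuximab leads because two independent methods indicate it (summed
$-\log_{10} p$ of 11.2), and `contraindications(report)` lists
oxaliplatin with its triggering marker (ERCC1, $p = 1.1\times10^{-7}$).
`renderReport(report)` writes the JSON and readable versions.

## Layout

- `R/` — S4 classes (`ZProfile`, `ReferenceStats`, `PMedReport`,
  `InteractionNetwork`, `BusinessCalendar`, `SimConfig`) and the nine
  functional modules (synthetic data, QC, turnaround, cross-species
  mapping, rule/signature/network predictors, report, clustering).
- `vignettes/pmed-workflow.Rmd` — the methods vignette: models,
  assumptions, parameter choices, calibration properties, limitations.
- `tests/testthat/` — unit, property and oracle-equivalence suites plus
  the end-to-end acceptance checks.
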