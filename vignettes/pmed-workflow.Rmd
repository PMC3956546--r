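---
title: "Methods: the PMedProfiler drug-prediction workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the PMedProfiler drug-prediction workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

PMedProfiler implements a personalized-medicine (PMed) workflow for
comparative oncology: tumor expression profiles from dogs with
spontaneous cancers are standardized against a normal-tissue reference,
carried into human identifier space, and matched against human drug
knowledge bases by six prediction methods whose calls are summed into a
ranked per-patient drug report. This vignette is the package's account
of the science: the models, their assumptions, the tunable parameters,
the numerical choices, and what the test suite does and does not
establish.

# The z-score profile and the identifier chain

Everything downstream consumes a **z-score profile**. For probe $g$
with reference mean $\mu_g$ and standard deviation $\sigma_g$
(sample variance, $n-1$ denominator, the usual choice for a small
reference set), a tumor value $x_g$ becomes
$z_g = (x_g - \mu_g)/\sigma_g$: the number of reference standard
deviations from normal physiology. The reference compendium defaults
to 40 normal tissues; the deposited reference series this emulates is
described in different places as having 39 and 40 samples, so the
count is an explicit parameter (`nRefSamples`) rather than a resolved
constant.

The profile then moves along a fixed identifier chain, in this order:

1. **canine probe → canine gene**: probes of a gene are averaged
   (plain mean). Unannotated probes are dropped.
2. **canine gene → human gene**: only *concise one-to-one* homologies
   are kept — a canine gene must occur in exactly one homolog row and
   that row's human gene in exactly one row. A canine gene with two
   human homologs is dropped, and two canine genes sharing one human
   gene are *both* dropped.
3. **human gene → human probeset** (optional): same strictness by
   default; a documented `fan-out` mode instead replicates a gene's z
   across all its probesets for consumers that need probe-level
   coverage.

Mapping steps copy z values untouched; only step 1 changes magnitudes.
Identifier comparison is exact-string after whitespace trimming — no
case folding, because gene symbols are case-sensitive identifiers
here, not words.

Two numerical edge cases: probes with zero reference variance have no
defined z and are dropped at standardization with a warning (a floor
epsilon was rejected because it manufactures arbitrarily large z), and
the drug methods are keyed in human-**gene** space. Under the default
strict projection the probeset step is a bijective relabeling, so
running the methods before or after it is equivalent; the projection
exists (and is tested) for fan-out consumers.

# The six prediction methods

**Drug target expression.** A rule base of (target gene, drug) pairs;
a rule fires when the target's z reaches its threshold (default +3,
inclusive, per-rule overridable). The call's p value must decrease as
z grows; the mapping is otherwise a free choice and we use the
one-sided standard-normal tail $\bar\Phi(z)$, which matches how z was
constructed and is pluggable. The method never fires on
under-expression: it models antagonists of over-expressed targets.

**Biomarker rules.** Same machinery, both directions
(over: $z \ge +3$; under: $z \le -3$) and both effects: sensitivity
rules indicate, resistance rules contraindicate (e.g. the classic
ERCC1/oxaliplatin resistance rule). $p = \bar\Phi(|z|)$. Within one
method, several triggered rules for a drug collapse to the minimum p
with all triggering genes listed.

**Drug response signatures.** The Connectivity Map idea: drugs whose
expression consequence *reverses* the tumor profile are candidate
therapeutics. The query is the tumor's up set ($z \ge +2.0$) and down
set ($z \le -2.0$), both inclusive. Against each drug's ranked
signature (most up-regulated first, a permutation of a common
universe), the KS-style enrichment of a set with ascending ranks
$V(j)$, $j = 1..t$, in a universe of $n$ is
$a = \max_j(j/t - V(j)/n)$, $b = \max_j(V(j)/n - (j-1)/t)$,
$ES = a$ if $a > b$ else $-b$. The connectivity score is
$s = (ES_{up} - ES_{down})/2$ when the two sides disagree in sign and
$0$ otherwise (incoherent evidence). $s < 0$ is inverse connectivity.
Significance is by permutation: random disjoint up/down sets of the
observed sizes are drawn from the universe and
$p = (1 + \#\{s_{perm} \le s_{obs}\})/(n_{perm}+1)$ — the add-one
estimator, so p is never 0 and never below $1/(n_{perm}+1)$. The
study-scale default is 50,000 permutations; the calibration suites use
2,000. Because the null law of $s$ depends on the ranking only through
its length, permutation nulls are shared across drugs with equal query
sizes within a call — a pure computational device that changes no
distribution. Only drugs with $s < 0$ and $p < 0.05$ are reported.

Two properties worth knowing. The running statistic is offset by one
rank step between its two suprema, so a set at the bottom of a ranking
scores slightly larger in magnitude than the same set at the top
($-0.9$ vs $+0.8$ for 2 of 10) — near-mirror, not exact. And the
same-sign-zero rule puts a large probability atom at $s = 0$, so null
permutation p values are *super-uniform* (stochastically $\ge$
uniform) rather than exactly uniform; the lower tail, which is all the
$p < 0.05$ filter uses, is calibrated, and the tests check exactly
that.

**Drug sensitivity signatures (PGSEA).** Each drug carries a signed
gene set from cell-line sensitivity screens (+1 = higher in sensitive
lines). For one sample, the signed values $v_i = \mathrm{sign}_i z_i$
are tested by a one-sample t-test,
$t = \bar v/(s_v/\sqrt m)$ with $m - 1$ df, one-sided toward
sensitivity (a two-sided variant is a trivial configuration). Fewer
than 2 matched genes yields no result; a degenerate zero-variance
vector gets $t = \pm\infty$ (or 0 with $p = 0.5$ when identically
zero), flagged. Reported at $p < 0.05$.

**Network target activity.** Activity, not expression: the seed $K$ is
either every node with $z \ge 2$ or the top-200 over-expressed nodes
(ties at the boundary broken by z then lexicographic id, so selection
is deterministic), intersected with the network. The shortest-path
network $S$ is the union of *all* shortest directed paths from each
seed to each other seed, through non-seed nodes as needed; unreachable
ordered pairs contribute nothing. For a node pair $(i,j)$, $K_{ij}$
counts ordered seed pairs with at least one shortest path carrying
both $i$ and $j$ as *interior* waypoints ("connected through"
excludes the endpoints — counting endpoints makes every adjacent seed
pair trivially significant, a self-referential artifact), in either
order along the path; $N_{ij}$ is the same count over all connected
ordered pairs of the global network. The pair's p is the
hypergeometric upper tail of drawing the seed's pair total from the
global pair population with $N_{ij}$ "routed" members and seeing
$K_{ij}$ or more. Significant pairs ($p < 0.05$)
implicate the drug targets they contain; each target reports its best
p over pairs containing it. The reporting threshold is $p < 0.05$,
like every other method (one description of this step reads as
reporting only the *non*-significant side, which contradicts the rest
of the workflow and is treated as a transcription error; the threshold
and its direction are configurable). An edge-based variant of
"through $(i,j)$" and unordered seed pairs were considered; ordered
pairs match the directed graph and are what ships.

# Report aggregation

Calls are scored $-\log_{10} p$ (base 10; the base is a monotone
rescaling and configurable). A drug's summary score is the plain sum
of scores over methods that indicated it — that is the stated
aggregation ("sum of scores from individual methods"), and it gives
multi-method drugs more weight by construction; a per-method score cap
is available as an alternative but is off by default. Any drug with a
resistance-rule call is excluded from the ranking and listed in a
contraindications section (exclusion, not a score penalty; a penalty
mode exists behind a flag). Ties rank alphabetically so reports are
byte-stable. JSON serialization round-trips the report losslessly.

# QA/QC gates

Four stage gates, each a pure function of the sample's record:

- **Histopathology**: tumor surface and tumor nuclei must be in the
  top ordinal category (75–100%), necrosis must not be in the failing
  category. The sources disagree on the necrosis bound (≤ 20% in one
  place, ≤ 10% in another, < 20% in a header); the gate fails only
  the ">20%" category, which reproduces the published failure table,
  and the bound is configurable.
- **RNA**: total yield = concentration × volume ≥ 20 ng (volume
  defaults to 14 µl when unrecorded), A260/A280 ≥ 1.8, RIN ≥ 8.0.
- **cDNA**: ratio ≥ 1.8 and yield ≥ 5 µg.
- **Array**: mean background < 100 (whether the study gated mean or
  max background is unstated; mean assumed), percent present ≥ 30%,
  and scale factor within a 3-fold tolerance of its target 100 — a
  strict equality gate on a continuous scale factor is unusable, so
  "scale factor 100" is read as a target with configurable fold
  tolerance.

Metrics recorded as not-measured are *not* failures: a stage with no
measured metrics is "not-evaluated" and does not veto the overall
verdict. This is required to reproduce the published stage counts,
where samples failing histopathology never reached the array. Overall
pass = every evaluated stage passed. The cohort summary reports the
overall percentage rounded to the nearest integer (as the study
quotes it) and stage percentages to 2 decimals.

# The turnaround clock

Event timestamps carry explicit zone offsets and are converted to US
Eastern civil time (the study window spans daylight saving, so a fixed
UTC−5 would be wrong; the zone is configurable) before any
arithmetic. **Business hours = all 24 hours of non-weekend,
non-holiday days** — not a 9-to-5 window — because the published day
conversions are exactly hours/24 (116.46 h ↔ 4.85 d). Weekend days
default to Saturday/Sunday; holidays are a user-supplied date list
(2011 US federal holidays ship as the default fixture), excluded as
whole days. Rounding to 2 decimals happens only at the reporting
layer. The clock is additive over intermediate events and its inverse
(`advanceBusinessHours`) lets the generator manufacture event logs
whose spans recover any requested duration to ±0.01 h. The 168-hour
(7-day) clinical deadline check is inclusive at the boundary.

# Clustering

Samples are compared by Pearson correlation distance ($1 - r$, range
0–2) and embedded by classical (Torgerson) MDS: double-center
$-\tfrac12 D^2$, eigendecompose, scale eigenvectors by root
eigenvalues. Correlation distances are generally non-Euclidean, so
negative eigenvalues occur and are truncated. Eigenvector signs are
fixed by orienting each axis so its largest-magnitude coordinate is
positive, making embeddings deterministic. The embedding dimension
defaults to $k = 2$ (the figure-style choice; the source does not
state one). Cluster quality is summarized as the mean silhouette
width in the embedding — this is the package's testable restatement
of "expression clusters by cancer type": on synthetic cohorts with
the default 2-z-unit type signature on 50 genes per type, the
silhouette by planted type is positive (and in practice large), while
drug-score clustering degrades when patient-specific perturbations
dominate.

# The synthetic-data generator

The generator is the package's study stand-in, and its defaults are
the study conditions: a 40-sample reference; tumor cohorts of 4 + 5 +
5 + 10 passing samples; knowledge bases of 260 drug-target rules
covering 123 drugs over 260 unique targets, 34 biomarker rules over
22 markers and 20 drugs, 107 response-signature drugs over a common
ranked universe, 11 signed sensitivity signatures, and a pool of 184
drugs; a homolog table with a configurable ambiguous fraction
(default 10%) split between one-to-many mappings and shared-human
pairs, with the rows that the one-to-one filter must drop flagged as
ground truth.

Expression is Gaussian on log-scale intensities: probe baselines
$\mu_p \sim N(8,1)$, noise $\sigma_p \sim U(0.2, 0.6)$; planted
effects (cancer-type signatures and per-patient `plantedTargets`) are
specified in z units and injected as multiples of $\sigma_p$, so a +5
plant surfaces as $z \approx 5$. The distributional family is a
stand-in — the pipeline consumes only z-scores, so nothing downstream
is sensitive to it; what the generator does *not* emulate is
microarray physics (probe saturation, batch structure, correlated
noise) or real knowledge-base content, and passing tests therefore
validate the statistics and the plumbing, not biological recall on
real arrays.

Structural guarantees (the closure property): every knowledge-base
gene lies on the strict mapping chain, so any planted perturbation of
a rule gene is guaranteed to reach the methods; every rule target is
a network node; two exemplar genes are labeled EGFR and ERCC1 so the
classic target and resistance rules read like their curated
counterparts, and the exemplar drugs keep distinct roles; one drug is
always reachable by two methods (a target rule plus a sensitivity
biomarker rule) so multi-method aggregation is exercisable; and the
network contains a funnel motif — sources whose only exit is a hub
target, sinks whose only entrance is a relay — so a planted seed on
sources and sinks routes every source→sink shortest path through the
(hub, relay) pair. Fixed seeds regenerate every artifact identically,
and the generator restores the caller's RNG stream.

The QC fixture is the 31-record enrollment table: seven records carry
the published failure metrics (with N/A cells replaced by passing
values, and one necrosis value printed outside the ordinal scale
encoded as its passing category), 24 records pass everything; gating
it reproduces 24/31 overall (77%) and 30/31 RNA-stage passes.

# Calibration, and one honest miscalibration

Under null profiles — unperturbed simulated tumors run through the
full standardization and mapping chain — the response-signature and
sensitivity-signature methods report drugs at rates statistically
consistent with their 0.05 threshold (binomial tests over 500
simulated samples at 2,000 permutations; both pass comfortably).

The network-activity method does **not** calibrate, and this is a
property of its design, not a bug in the implementation: each target
is assigned the *best* p over every node pair containing it, with no
multiplicity control, so the per-target null reporting rate is
inflated above $\alpha$ (roughly 0.08–0.11 in our runs, varying with
graph size and seed accounting), while the per-pair rate is
*conservative* (well below $\alpha$) because the hypergeometric tail
is discrete at small counts. The acceptance suite asserts consistency
with $\alpha$ for all three methods and the network assertion fails
by design — we prefer an honest red over a silently weakened check.
Consumers should read network-activity calls as a ranked screen, not
as calibrated hypothesis tests; its raw `pairs` table (with
$K_{ij}$, $N_{ij}$ and p per node pair) is attached to every result
for scrutiny. Relatedly, no multiple-testing correction is applied
across drugs in any method — that mirrors the reported workflow's raw
$p < 0.05$ reporting, and users wanting FDR control should apply
`p.adjust` to the attached scan tables.

# Problem sizes used by the suites

Test and acceptance runs scale simulations to keep the suites fast
while preserving structure: calibration uses 500 null tumors over
1,200 probes with a 40-rule knowledge base, a ~80-node network and
6 response drugs at 2,000 permutations; planted-truth recovery uses
the full study-sized knowledge bases with four planted samples;
oracle-equivalence checks run on graphs of at most 12 nodes
(exhaustive path enumeration) and small rank/tail cases. The whole
test suite runs in well under two minutes; `scripts/acceptance.R`
in about two.

# Known limitations

- Knowledge bases are synthetic tokens (plus the two exemplars); the
  package ships no curated drug-target, biomarker, CMAP or NCI-60
  content and makes no claim about real-drug recall.
- The response method scores per-drug consensus rankings; scoring
  every array instance of a drug separately (the other reading of the
  source workflow) is stubbed but not the default.
- Network analysis treats edges as unweighted and untyped; edge
  semantics (activation/inhibition) are carried but unused.
- The turnaround clock excludes whole holiday days; partial-day
  holiday handling is not modeled.
- Report layouts are inspired by the published summary tables, not
  byte-compatible with them.
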