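---
title: "Methods: reduced PBPK modelling of a drug cocktail in cirrhotic mice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced PBPK modelling of a drug cocktail in cirrhotic mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocktailpbpk)
```

## Scope and model structure

The package analyses the disposition of a six-drug phenotyping cocktail
(caffeine, codeine, midazolam, torsemide, pravastatin, talinolol) and its
quantified phase-I and phase-II metabolites in mice, healthy and cirrhotic.
Full whole-body PBPK platforms resolve dozens of organs; for the questions
treated here — hepatic metabolism, carrier-mediated hepatocyte export, renal
filtration — a five-compartment reduction is the smallest structure that can
express every mechanism of interest:

* **plasma** — the sampled central compartment;
* **liver blood** and **hepatocyte** — split so that sinusoidal
  (basolateral) and canalicular (apical) membrane transport are distinct
  model elements;
* **kidney** and **rest of body** — flow-limited distribution with tissue
  partition coefficients (venous return at `C_tissue / Kp`);
* three cumulative sinks: **urine**, **bile**, **unknown_sink** (lumped
  unquantified metabolites).

Each chemical species is carried in all compartments and counted
mole-per-mole as parent equivalent, so total moles match the administered
dose exactly; the test suite enforces conservation to a relative 1e-6.
Dosing is an i.v. bolus of all six drugs at t = 0; each drug family is an
independent system (no drug–drug interaction at the doses used).

### Kinetic laws

All rates act on the **unbound** concentration `Cu = fu * C` (constant
plasma-derived `fu`, the standard PBPK convention):

| process | law | location |
|---|---|---|
| enzymatic metabolism (Cyp*, Ugt) | `CL_int * Cu` | hepatocyte |
| total hepatic clearance | `CL * Cu` → unknown sink | hepatocyte |
| carrier transport (Slco1b2, Abcc3/4, Abcc2, Abcb1a) | `Vmax * Cu / (Km + Cu)` | membrane-specific |
| glomerular filtration | `GFR * fu * C_plasma` → urine | plasma |
| biliary clearance | `CL * Cu` → bile | hepatocyte |
| passive exchange | `PS * (Cu_blood − Cu_cell)` | sinusoidal membrane |

`Km` is fixed at 1000 nmol/L (1 µmol/L) by convention and is never fitted;
only `Vmax` and first-order clearances are estimable. Glucuronides are
assigned zero passive membrane permeability, so the basolateral carriers
(Abcc3/Abcc4) and the canalicular carrier (Abcc2) are their only exits from
hepatocytes — without this the "reduced biliary export" and "increased
sinusoidal export" hypotheses would collapse into one another.

### Units

Amounts nmol, volumes L, time min, concentrations nmol/L, clearances and
flows L/min, transport capacities nmol/min. Doses convert as
`nmol = mg/kg × kg × 1e6 / (g/mol)`.

## Parameter values

The mouse physiology (25 g body weight; plasma 1.0 mL, liver blood 0.3 mL,
hepatocellular water 1.0 mL, kidney 0.4 mL, rest 19 mL; hepatic flow
1.8 mL/min; GFR 0.28 mL/min) is generic rodent physiology shipped as an
editable object, scaled linearly with body weight.

**Drug-specific rate constants are synthetic placeholders**, chosen once
from standard reference ranges so that each family shows a realistic
disposition regime — parent half-lives of tens of minutes over the
two-hour sampling window, flow-limited hepatic extraction for midazolam,
uptake-limited clearance for the Slco1b2 substrates, and small (a few
percent of dose) glucuronide formation. Two structural features of the
glucuronide placeholders matter for the analyses and were fixed
deliberately:

1. **Biliary dominance in health.** Control sinusoidal export capacity
   (Abcc3 + Abcc4, Vmax 0.002 nmol/min each, i.e. ~4 µL/min intrinsic
   clearance at Km) is ~2 % of canalicular capacity (Vmax 0.15 nmol/min), so
   nearly all conjugate leaves into bile and plasma levels are low —
   the healthy phenotype the cocktail studies report.
2. **Operation near Km.** At the resulting hepatocellular conjugate
   concentrations the export carriers run in the mildly saturable region.
   In this regime the three cirrhosis hypotheses reshape the plasma
   glucuronide curve in nearly interchangeable ways, which is exactly the
   structural non-identifiability the hypothesis-discrimination workflow
   is designed to resolve; far below Km the system becomes too linear
   (plasma data alone can already separate the mechanisms via curve shape),
   far above it too saturated (H1 cannot move plasma levels at all).

These are design choices of the package, documented here so that users
replace them with fitted values (`fit_reference()`) before quantitative
use.

## Cirrhosis scenario

`apply_cirrhosis()` multiplies every CYP-attributed enzymatic clearance
**and** every lumped total hepatic clearance by `cyp_fraction`
(default 0.11 — the fraction of CYP-expressing parenchyma retained), and
scales transporter capacities gene-wise by `2^log2FC` taken from mouse
differential-expression results. UGT conjugation is deliberately **not**
reduced: phase-II activity is experimentally unchanged in this disease
model, and leaving it at healthy levels makes the reference cirrhosis
simulation under-predict blood glucuronides — the discrepancy the three
hypotheses then try to explain:

* **H1** multiplies UGT conjugation clearances by θ;
* **H2** multiplies canalicular/biliary glucuronide export by θ (θ < 1
  means reduced biliary clearance);
* **H3** multiplies sinusoidal glucuronide export by θ.

The scaling gate is a package convention: only genes passing the mouse DE
thresholds (|log2FC| ≥ 1, FDR ≤ 0.05, both inclusive) contribute a
multiplier; others default to 1 with provenance recorded. The transforms
are pure functions and commute; identity settings reproduce the reference
simulation bit-exactly.

## Estimation

The objective is log-residual least squares,
`Σ w (log(pred + ε) − log(obs + ε))²` with `ε = LOQ/2` per observation
kind; below-LOQ observations enter at LOQ/2 with weight 0.5. Log residuals
are the natural choice when analyte concentrations span four orders of
magnitude; the upstream study does not state its objective, so this is a
package decision.

Optimization is bounded and always in log-parameter space. Multi-parameter
problems use multi-start L-BFGS-B: the user start plus seeded
Latin-hypercube starts over the log bounds (default 8 starts, default
bounds 1e-3–1e3 × start), so adding starts can only improve the optimum.
Single-parameter problems (the common "fold-change only" fits) instead use
Brent's bounded search on the log interval — deterministic, start-free and
several-fold cheaper. All randomness flows from one user-visible seed.

`fit_joint_hypothesis()` fits shared reference parameters against control
data and, after applying scenario + hypothesis with free θ, against
cirrhosis data (summed objectives). An optional microsomal UGT activity
ratio (cirrhosis/control) acts as one lognormal pseudo-observation with
sd 0.3 on the log scale — each hypothesis implies such a ratio (θ under H1,
1 otherwise), which is how non-PK evidence enters the comparison, mirroring
the confrontation of model predictions with microsomal assays.

## Synthetic cohorts

`generate_paired_cohorts()` emulates the study design: i.v. cocktail bolus,
plasma samples at 15/30/60/120 min, one cumulative 24-h urine and one
cumulative 2-h bile amount per animal, for a control group (reference
model) and a cirrhosis group (scenario + true hypothesis). Noise structure:

* multiplicative lognormal measurement error, CV 20 % (typical
  bioanalytical precision; median-unbiased, `sdlog = sqrt(log(1 + cv²))`);
* lognormal inter-animal variability, CV 30 %, on hepatic process
  parameters only, independent per subject and process;
* censoring at kind-specific LOQs (0.1 nmol/L plasma; 0.01 nmol urine/bile),
  replaced by LOQ/2 and flagged.

The generator reproduces bit-exactly from its ground-truth record. What it
does **not** emulate: correlated inter-animal variability, disease
heterogeneity (every cirrhotic animal shares one scaling), time-dependent
error, drug–drug interactions, enterohepatic recirculation, or the CCl4
dosing history itself. Passing recovery tests therefore demonstrate the
estimator works under the stated error model, not that real cirrhotic mice
satisfy it.

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable — under H3 the conjugate
  formation and export rates can differ >100-fold), relative tolerance
  1e-8, absolute 1e-10 nmol; an analytic Jacobian is supplied (the system
  is linear except for the Michaelis–Menten terms, which only perturb the
  source column).
* Dose events are inserted as solver event times, so integration restarts
  cleanly at each bolus; identical inputs give bit-identical output.
* Negative states beyond 100 × the absolute tolerance raise an error;
  smaller excursions are clipped to zero.
* AUC uses the linear trapezoid on the sparse four-point design (a
  log-trapezoid gains nothing at this density); window edges falling
  between samples are interpolated so the metric is additive over adjacent
  windows, and there is no extrapolation outside the sampled range.
* Two-fold coverage counts boundary ratios (exactly 0.5× or 2×) as inside.
* Zero-predicted/zero-observed pairs contribute zero residual (both sides
  agree); the degenerate empty-dose simulation returns an all-zero course.

## Decisions on genuinely open points

* Codeine-6-glucuronide is modelled as formed **from codeine** (the
  conjugate's name fixes its parent); norcodeine glucuronide is not
  modelled. Morphine formed from codeine is itself conjugated to
  morphine-3-glucuronide within hepatocytes.
* Torsemide phase-I metabolism is attributed to Cyp2c29, following the
  established modelling assumption for this probe (flagged as an
  assumption, not a measurement).
* Renal elimination is pure glomerular filtration for every analyte; no
  active secretion is enabled by default.
* The ratio-of-means metric is oriented cirrhosis/control (the source
  tables do not fix a direction).
* Under many-to-one ortholog collapsing the log2FC is the arithmetic mean
  and the FDR the minimum of the members — the mean rule is standard, the
  min-FDR companion is a package convention.
* Cross-species correlations accept an arbitrary gene set, so users can
  choose family members or DE-flagged members; the package does not impose
  either scope.

## Problem sizes

The shipped tests and the acceptance script run at deliberately compact
sizes chosen as sufficient for their statistical purpose: recovery and
discrimination use 5 + 5 animals per cohort (the sparse-design scale of
rodent cocktail studies), 10–20 seeded replicates per property, 200
subjects for checking the noise law, and 1000 gene pairs for the
null-correlation bound. Each property was sized so that its pass/fail
decision is dominated by the property itself rather than replication
noise.

## Known limitations

* The compartmental reduction has no oral route, no enterohepatic
  recirculation, no protein-binding kinetics beyond constant `fu`, and no
  liver zonation — the CYP reduction factor is a lobule-lumped surrogate.
* Placeholder parameters are not calibrated to any dataset; quantitative
  conclusions require refitting.
* Hypothesis discrimination is by objective comparison plus auxiliary
  evidence, not by formal model-selection criteria or profile likelihood;
  the factor-2 objective-spread check is a pragmatic identifiability
  surrogate.
* DE computation (counts → log2FC/FDR) is upstream and out of scope; the
  package consumes result tables. To analyse a public expression dataset,
  produce per-gene log2FC/FDR with any standard DE tool, export columns
  `gene_symbol`, `log2fc`, `fdr` as delimited text, and load with
  `read_de_table()`.
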