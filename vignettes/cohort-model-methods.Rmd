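---
title: "Methods: a Markov cohort model for second-line therapy in advanced NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for second-line therapy in advanced NSCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsclcCEA)
```

## The decision problem

`nsclcCEA` implements a cohort state-transition (Markov) model comparing
three second-/third-line options for driver-negative advanced or metastatic
non-small cell lung cancer from the Chinese healthcare-system perspective:
tislelizumab (a domestic PD-1 inhibitor), docetaxel (conventional
chemotherapy) and nivolumab (an imported PD-1 inhibitor). The model output
is the discounted lifetime cost and quality-adjusted life-years (QALYs) of
each arm, the incremental cost-effectiveness ratios (ICERs) between arms,
and their uncertainty under deterministic and probabilistic sensitivity
analysis. The willingness-to-pay threshold is $35,663 per QALY (three times
China's 2021 per-capita GDP); costs are 2021 USD.

## Model structure

Patients start in progression-free survival (PFS) on their assigned
second-line therapy. PFS is split into two sub-states -- on therapy and off
therapy after toxicity-related discontinuation -- because discontinuation
stops drug acquisition costs without (in the trials' intention-to-treat
curves) changing survival. Progressors enter the progressive-disease (PD)
state, where a fixed proportion receives further-line anlotinib; patients
who progress again enter end-stage disease with palliative care, and death
can occur from any state:

* PFS (on/off therapy) &rarr; {PD, death}
* PD &rarr; {end-stage, death}
* end-stage &rarr; death

The cycle length is 3 weeks and the horizon 30 years, i.e.
`floor(30 * 365.25 / 21) = 521` cycles (the floor avoids a partial terminal
cycle). Direct PFS &rarr; end-stage jumps are not modelled; the published
state diagram does not show them and the data would not identify them.

## Survival and transition probabilities

All six fitted endpoints (OS and PFS for tislelizumab, docetaxel and
anlotinib) are log-logistic with

$$S(t) = \frac{1}{1 + \theta\,t^{\kappa}},$$

`t` in cycles. This parameterization is fixed because the published
$\theta/\kappa$ pairs reproduce the source trials' median survival only
under it (e.g. tislelizumab OS: $(1/\theta)^{1/\kappa} \approx 24.6$ cycles
$\approx$ 17 months). Per-cycle transition probabilities are discrete-time
hazards, $p(t) = 1 - S(t)/S(t-1)$, which telescope back to the survival
curve exactly -- the package's central consistency oracle.

Nivolumab has no head-to-head trial against tislelizumab; its curves are
derived from the tislelizumab curves through indirectly estimated hazard
ratios (OS 1.170, PFS 1.235) applied as proportional hazards on the
cumulative hazard, $S_{\mathrm{niv}}(t) = S_{\mathrm{tis}}(t)^{HR}$. That is
the meta-analytic meaning of a hazard ratio and makes composition exact; an
accelerated-failure-time variant (`hr_application: aft`) is exposed for
sensitivity exploration only.

Competing risks within PFS are split by taking deaths from the OS curve and
progressions as the PFS-exit remainder, clipped at zero -- standard practice
when only marginal OS and PFS curves exist. Within a cycle the event order
is death, then progression, then discontinuation; order effects are
$O(p^2)$, far below reporting precision.

### Post-progression clocks

Anlotinib's $\theta/\kappa$ come from a trial clocked at anlotinib start, so
PD and end-stage are tunnel states keyed on time since progression
(`pd_clock_mode: state_entry`). The tunnel tail is "sticky" at the horizon
(mass at the last index stays there) so cohort mass is conserved to 1e-9 at
every cycle -- an invariant the engine checks and the tests assert. A
`model_time` mode (probabilities indexed by model cycle) is provided because
decision-tree software sometimes clocks this way; it ages post-progression
patients faster and is a calibration lever, not the default.

No survival law exists for end-stage disease. The default continues the
time-since-progression clock on the anlotinib OS curve, which is smooth and
conservative; a fixed per-cycle probability mode exists, and a fixed
probability of zero is rejected because end-stage must be transient.

## Costs and QALYs

Per lived cycle: PFS on therapy accrues drug + routine follow-up + best
supportive care (BSC); PFS off therapy drops the drug; PD accrues follow-up
+ BSC + (subsequent-therapy proportion x anlotinib cycle cost); end-stage
accrues follow-up. Both PFS sub-states use the PFS utility (0.856); PD
0.768; end-stage 0.703. The frequency-weighted adverse-event cost and QALY
decrement are applied once at model entry: they are per-patient-course
aggregates, and re-applying them per cycle would exceed the printed totals
by an order of magnitude. Discounting is 5%/year on both costs and effects,
$(1+r)^{-t \cdot 21/365.25}$.

Drug acquisition uses vial-wastage rounding: the dose (flat 200 mg
tislelizumab; 75 mg/m^2 docetaxel at BSA 1.72; 3 mg/kg nivolumab at 65 kg)
is rounded up to whole pricing units. Nivolumab's 2-weekly schedule maps to
1.5 administrations per 3-week cycle by default -- the largest single lever
for that arm's cost; 1.0 is available in the configuration. Anlotinib is one
168 mg pack per cycle, no wastage.

### Palliative care as terminal care

The parameter table prices palliative care per cycle, but under the model's
own end-stage mechanics the cohort spends about 7--9 discounted cycles in
end-stage, and accruing $2,627.80 for each of them adds roughly $19k--24k
per arm -- 60--150% above every published arm total, which the published
arithmetic cannot contain. The package therefore applies the palliative sum
as a one-off terminal-care cost at death (`palliative_cost_mode:
one_time_death`), a standard convention in oncology cohort models; with it,
all three arm totals land within 6% of the published ones. `per_cycle` and
`one_time_entry` (once per end-stage entrant) remain available, and the
per-cycle reading is exercised in the unit tests. BSC is not accrued in
end-stage (palliative care replaces active supportive care); follow-up is
accrued in all alive states.

The half-cycle correction defaults to off, matching the source software's
convention; enabling it averages each cycle's start and end occupancy
(trapezoid) for both costs and QALYs.

## Sensitivity analysis conventions

*Deterministic:* every parameter with a printed range is swept one-way to
its bounds ($\theta/\kappa$ stay fixed); bars are ranked by width into a
tornado. The ICER outcome flags dominance instead of reporting a signed
ICER when incremental QALYs are non-positive; a net-monetary-benefit
outcome is provided for comparisons that can flip into dominance.

*Probabilistic:* 1,000 iterations; each draws every non-fixed parameter
independently (no correlation structure is published). Standard errors are
reconstructed from the printed ranges as width/3.92 (the conventional
95%-interval reading; no SEs are published). Beta parameters use method of
moments, gamma uses shape $= (m/s)^2$, anthropometrics use a raw normal
truncated at zero. Hazard ratios are drawn on the log scale despite their
"normal" tag because their printed intervals (0.509--2.683 around 1.170)
are multiplicatively, not additively, symmetric; a raw-normal option is
retained. Cost-effectiveness is classified by the sign of net monetary
benefit, which subsumes dominance. An infeasible beta moment solution falls
back to uniform on the printed range with a warning; with the shipped
parameters this never triggers.

The PSA is bit-reproducible under a seed, and collapsing every distribution
to a point mass reproduces the base case exactly (asserted in the tests).

## The synthetic-IPD generator

The published curve-fitting step digitized Kaplan-Meier figures and
reconstructed pseudo individual-patient data. Figures are not
machine-readable inputs, so the package replaces that step with a
statistical stand-in: inverse-CDF simulation from a specified law with
administrative censoring (default 35 cycles, the scale of second-line trial
follow-up) and optional exponential dropout, a product-limit estimator, and
a simplified KM-coordinate inversion (events at step drops by cumulative
rounding, survivors censored at the last coordinate -- not the full
at-risk-aware reconstruction algorithm, which figure-level fidelity would
need but statistical fidelity does not). What passing tests show is that
the fitting stage recovers known $\theta/\kappa$ within 5% at n = 5,000 and
ranks the generating family first by AIC at trial-like sizes; they cannot
show anything about digitization error in the published curves themselves.

## Numerical choices and problem sizes

* Cycle grid: 521 cycles; trace rows are cycles 0..521; costs/QALYs accrue
  over the 521 lived cycles.
* Mass conservation enforced at 1e-9 per cycle; transition probabilities
  validated into [0, 1] with the offending cycle reported.
* Unit tests run most cohort properties on a 5-year horizon (87 cycles) for
  speed; the acceptance tests run the full 521-cycle horizon and the full
  1,000-iteration PSA.
* Fitting is delegated to `flexsurv` (five families, right censoring);
  log-logistic (shape, scale) is converted to $\kappa =$ shape, $\theta =$
  scale$^{-\kappa}$. Tests cross-check the fitted likelihood against a
  direct closed-form computation.

## Known limitations

* The competing-risk split and the post-progression clocks are structural
  reconstructions; the published model's exact internals (built in
  decision-tree software) are not fully specified, and the residual 1--6%
  gaps to the published totals are of that structural order.
* Sex-specific scenarios are wired through configuration overrides, but
  only the nivolumab-vs-tislelizumab OS hazard ratios are published;
  sex-specific tislelizumab-vs-docetaxel effects must be user-supplied, so
  the published subgroup table is not reproducible from shipped inputs.
* PSA draws are independent across parameters; no value-of-information
  analysis; no societal-perspective costs; no treatment-effect waning.
* Under the documented sampling conventions the PSA concentrates more
  probability on cost-effectiveness of tislelizumab vs docetaxel than the
  published proportions suggest; the published base case and the published
  PSA proportions are not mutually consistent under any range-derived
  standard-error convention we could construct, and the package reports
  what it computes.
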