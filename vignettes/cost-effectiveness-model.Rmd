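---
title: "A Markov cohort model for prophylactic iridotomy in angle-closure suspects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for prophylactic iridotomy in angle-closure suspects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpicea)
```

## The decision problem

Primary angle-closure suspect (PACS) is an anatomically narrow anterior-chamber
angle without glaucomatous damage. A minority of suspects progress — to primary
angle closure (PAC), then primary angle-closure glaucoma (PACG) and,
ultimately, unilateral and bilateral blindness — and some suffer an acute
angle-closure crisis (AACC). Prophylactic laser peripheral iridotomy (LPI)
roughly halves the annual progression risk but costs money up front and
commits a large, mostly healthy population to treatment. `lpicea` quantifies
that trade-off for the Japanese healthcare payer: is prophylactic LPI at age
40 worth its cost per quality-adjusted life-year (QALY) gained, against a
willingness-to-pay (WTP) of 5,000,000 JPY/QALY?

## Model structure

Both arms share a yearly-cycle Markov cohort over mutually exclusive states
with irreversible progression and no death state (mortality at ages 40–59 in
Japan is low enough to ignore, and omitting it biases both arms equally):

* **LPI arm** (7 states): `PACS_y1`, `PACS`, `PAC_y1`, `PAC`, `PACG`,
  `UNIBLIND`, `BIBLIND`.
* **Observation arm** (9 states): the same plus `AACC` and `PACS_LPIOPEN`.

The `_y1` states are one-cycle *tunnels* carrying first-year costs: the LPI
procedure year (98,393 JPY vs 19,560 JPY for observation work-up) and the
PAC entry year (171,259 JPY, which bundles the lens extraction performed on
progression). A patient in the observation arm who suffers an AACC spends one
cycle in `AACC` (cost 107,167 JPY, utility 0.99) — the cost is treated as
all-inclusive for that year — then moves deterministically to
`PACS_LPIOPEN`, from which progression follows the *LPI-arm* probability: the
emergency iridotomy opens the angle exactly as the prophylactic one does.
Blindness is reachable only from PACG, and `BIBLIND` is absorbing.

Transitions allow a single step per cycle (no state-skipping). Trabeculectomy
is not a state: within PACG it is a memoryless per-cycle event entering the
rewards in expectation, `cost = c_PACG(age) + p_trab(age) * 697,008` and
`utility = (1 - p_trab) * 0.75 + p_trab * 0.74`. A cohort model cannot
remember who has already been operated on; the microsimulation (below) runs
in a `once_only` mode and shows the 20-year mean-cost difference between the
two conventions is below 0.1%, so the memoryless expectation is kept.

### Age brackets

Trabeculectomy probability and the PACG/blindness costs are tabulated for
40–49 and 50–59. Brackets are half-open on *attained* age
(`entry_age + cycle`): ages in `[40, 50)` take the younger value and all ages
`>= 50` the older one, so lifetime scenarios (to age 99) reuse the 50–59
inputs. Indexing by attained age rather than time-since-entry makes the
50–69 scenario nearly identical to the base case, which is the behaviour the
scenario sweep checks.

### Discounting and cycle accrual

Costs and QALYs are discounted at 2% per year. Rewards accrue at cycle start
with the first cycle undiscounted (annuity-due): cycle *t* contributes
`sum(occupancy[t, ] * reward) * 1.02^(-t)`. No half-cycle correction is
applied. Under this convention an event-free 20-cycle cohort accrues exactly
`(1 - 1.02^-20) / (1 - 1.02^-1) = 16.6785` QALYs, the closed form the test
suite pins down; the alternative annuity-immediate convention would give
16.35 and is not used anywhere.

## Parameters

`default_parameters()` returns all 35 inputs with their metadata;
`parameters_table()` exports them. Every varied parameter carries a one-way
range (±30% for transition probabilities, ±8% for utilities, ±20% for costs,
0–4% for the discount rate) and a probabilistic specification. Structural
inputs — the utilities of 1.0 (PACS, PAC), the AACC utility 0.99, the certain
AACC resolution, the discount rate and the analysis constants — are fixed in
the PSA. Percentages are stored as fractions once, at load; all internal
arithmetic is on fractions. Users override any value through
`load_parameters()` (YAML/JSON or a named list); unknown names and
range violations fail loudly.

## Sensitivity analyses

**Scenario sweep.** Seven entry/exit age combinations (40–59 base case;
40–54; 40–49; 50–69; 50–64; 50–59; 40–99). Shorter horizons leave less time
to amortise the up-front procedure cost, so the ICER rises steeply toward the
10-year horizons and falls far below the threshold over a lifetime.

**One-way DSA.** `one_way()` moves a single registry entry to each bound and
re-runs both arms; `tornado()` ranks all 28 varied entries by ICER span,
breaking ties by registry order (stable sort). A cost used by both arms is
one registry entry and therefore moves in both arms together; arm-specific
probabilities are separate entries. Excursions never mutate the caller's
parameter set — purity is tested. The PACS follow-up and first-year cost
parameters dominate the ranking, as expected for a model whose incremental
cost is driven by money spent on the large, never-progressing majority.

**PSA.** "Standard deviation equal to 10% (5%) of the mean" is mapped to
two-parameter fits by the method of moments: beta
(`alpha = m(m(1-m)/s^2 - 1)`, `beta = (1-m)(m(1-m)/s^2 - 1)`) for
probabilities (SD 10%) and utilities (SD 5%), gamma (`shape = (m/s)^2`,
`scale = s^2/m`, hence shape 100 at SD 10%) for costs. Draws are independent
across parameters (no correlation structure is assumed), and one draw per
parameter per iteration is shared by both arms, so the incremental deltas
reflect parameter uncertainty rather than between-arm sampling noise. The
draw order is fixed — parameters in registry order, each drawn as a block —
and, with the seed, makes results bit-reproducible; the global RNG state is
restored on exit. If a sampled observation-arm PACS row exceeds unit exit
probability (essentially impossible at these means) the row is redrawn and
counted in `resample_count`. The acceptability curve is the empirical
`P(lambda * dQ - dC > 0)` over a WTP grid; `ceac_crossing()` interpolates
the 50% threshold linearly.

## The microsimulation oracle

`simulate_patients()` walks individual patients through the identical
transition matrix with per-cycle multinomial draws, reusing the cohort
engine's reward vectors and discounting so that any disagreement isolates to
the transition logic. It is both the package's synthetic-trajectory generator
(`trajectories_table()` emits the long-format CSV) and the brute-force
validator: `validate_oracle()` reports z-scores of cohort totals against
Monte Carlo means, and `trajectories_to_trace()` compares per-cycle
occupancies. Routine tests run 30,000–50,000 patients (a few seconds);
release-level validation uses 200,000, at which the cohort engine agrees
within three standard errors. The simulation emulates only the chain — no
covariates, no heterogeneity in utilities or costs, no mortality — so
agreement validates the bookkeeping of this model, not the model's fidelity
to real patients.

## Calibration status and known discrepancies

The acceptance suite compares the package against reference tabulations of
this decision problem (base-case ICER 2,287,662 JPY/QALY; 89.4% probability
of cost-effectiveness at the 5M threshold). Computing strictly from the
tabulated inputs above, `lpicea` obtains a base-case ICER of ≈7.11M JPY/QALY
(incremental cost ≈79,443 JPY, incremental QALYs ≈0.0112) and a ≈31%
probability of cost-effectiveness, and the corresponding acceptance tests
are deliberately left failing rather than tuned. The gap is provable, not a
convention choice: with every post-first-year LPI-arm state costing at least
23,780 JPY, the 20-cycle discounted arm total cannot fall below 471,228 JPY,
yet the reference table reports 449,050; and the reference incremental QALYs
exceed what the stated two-step progression chain can produce by an amount
proportional to the discounted annuity, i.e. a constant per-cycle utility
difference no tabulated parameter generates. The reference inputs and
reference outputs are therefore mutually inconsistent; this package commits
to the inputs. All structural checks — closed-form discounting anchors,
oracle equivalence, qualitative DSA findings (PACS costs dominate the
tornado), reproducibility — pass.

## Limitations

No mortality, treatment discontinuation, cataract-surgery pathway or
bilateral-eye bookkeeping beyond the two blindness states; no efficiency
frontier beyond the two strategies; no currency inflation adjustment. The
societal perspective is supported only as a user-parameterised extension
(travel cost per visit 4,547 JPY and a 30% unilateral-blindness share of
indirect costs ship as defaults; the indirect-cost level and visit schedule
must be supplied), because payer-perspective inputs are the only complete
set built in.
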