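---
title: "Dimensioning multi-skill nursing staff per shift: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dimensioning multi-skill nursing staff per shift: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nursedim)
```

## The problem

A hospital inpatient unit must hold a permanent pool of nursing staff large
enough to deliver the legally required amount of daily care, organised in
shifts, at minimum salary cost. Two skill levels are involved: *nurses*
(the more qualified group) and *nursing technicians* (certified auxiliary
staff). The unit works a morning shift, an afternoon shift, and a 12-hour
night shift staffed by two cohorts that alternate nights ("night 1" on odd
nights, "night 2" on even nights), because labour law forbids consecutive
night work. Staff do not switch shifts during the planning horizon, so the
dimensioning decision is: how many workers of each skill to assign to each
of the four shift cohorts.

`nursedim` answers this in two phases.

## Phase I: from census to demand

The Brazilian nursing council's standard (COFEN Resolution 293/2004) maps
each inpatient to a minimum number of daily care hours by illness-severity
category:

| category | hours/patient/day | minimum nurse share |
|---|---|---|
| minimal | 3.8 | 33% |
| intermediary | 5.6 | 33% |
| semi-intensive | 9.4 | 42% |
| intensive | 17.9 | 52% |

Unclassified patients are counted as intermediary before anything else is
computed. The required daily care hours are then the census-weighted sum of
the hours coefficients — a quantity linear in the census:

$$ \mathit{hours} = \sum_c n_c \, h_c . $$

The standard also prescribes a minimum share of nurses among all nursing
workers. Its text rule takes the percentage of the *dominant* category (the
one with the most patients, ties resolved toward higher acuity). The
published eight-day case study, however, prints per-day shares of 34% and
35% for censuses whose dominant category is minimal care (33%), so the text
rule cannot be what produced them. `nursedim` therefore also implements a
*demand-weighted* rule,

$$ \mathit{prop} = \mathrm{round}\!\left(
   \frac{\sum_c n_c h_c \, p_c}{\sum_c n_c h_c}\right), $$

with rounding to the nearest integer percent, half away from zero. This
reconstruction reproduces all eight published values exactly and is the
default (`phase1(..., ratio_rule = "weighted")`); the dominant rule remains
available because it is what the standard literally says. The choice of
half-away-from-zero rounding was checked against all eight published
values; round-half-even would disagree on none of them here, but
half-away-from-zero is the convention the reproduction was validated
under.

## Phase II: the staffing model

Let $x_{is}$ be the number of workers of skill $i \in \{n, t\}$ assigned to
shift $s \in \{M, A, N_1, N_2\}$, and let $y_{iu}$,
$u \in \{M, A, N\}$, be auxiliary *pre-buffer* staff levels. With shift
lengths $L$, care-hour demand $H$, Technical Safety Index $p$ (an absence
buffer, 15% by default), nurse share $\mathit{prop}$, balance bounds
$\alpha_i$ and per-cell minima $m_{is}$, the default model is

$$ \min \; \sum_{i,s} c_{is} x_{is}
   \qquad c_{is} = L_{is}\, r_i\, (1 + \delta_{s \in \{N_1,N_2\}}\,\pi) $$

subject to

1. **demand** — pre-buffer staff deliver the required hours, with the
   night column counted for both cohorts:
   $\sum_i \left( L_{iM} y_{iM} + L_{iA} y_{iA} + 2 L_{iN} y_{iN} \right) \ge H$;
2. **absence buffer (TSI)** — staffed levels exceed pre-buffer levels by
   the buffer: $x_{iM} \ge (1+p)\,y_{iM}$, $x_{iA} \ge (1+p)\,y_{iA}$,
   $x_{iN_1} + x_{iN_2} \ge (1+p)\,2\,y_{iN}$;
3. **skill mix** — $\sum_s x_{ns} \ge \mathit{prop} \sum_{i,s} x_{is}$,
   entered as an exact linear inequality (no rounding);
4. **balance** — $|x_{iM} - x_{iA}| \le \alpha_i$ per skill;
5. **night parity** — $x_{iN_1} = x_{iN_2}$;
6. **minimum cover** — $x_{is} \ge m_{is}$.

All $x$ are non-negative integers; the $y$ are non-negative and continuous
by default. Salary rates default to 1 monetary unit per nurse hour, 0.6
for technicians, with a 37.5% premium on night hours; both night cohorts
are salaried, which is why the night column appears twice in the
objective. Under these defaults the cost per *delivered* hour orders the
four worker types as day technician (0.6) < night technician (0.825) <
day nurse (1.0) < night nurse (1.375) — the ordering the solver's bound
exploits.

### The variant system

The published description fixes the six constraint *families* but not
every detail of their algebra (the exact formulation lives in a
supplementary file that is not part of the text). Four readings are
genuinely open, and `model_variant()` exposes each as a flag:

* `tsi_scope` — whether the buffer links staff to pre-buffer levels per
  skill-and-shift cell (default), per skill, or globally;
* `aux_integrality` — continuous (default) or integer pre-buffer levels;
* `night_demand_hours` — whether pre-buffer night staff hours count for
  both cohorts (default) or one;
* `prop_counting` — whether the skill mix counts all pool members
  (default) or only the staff present on a given day (one night cohort).

The default combination is the only one examined under which **all eight**
published per-day staffing vectors are feasible for their printed demand;
that empirical fact, checked in the test suite, is the reason it is the
default. None of the examined combinations makes the published vectors
*optimal* — several published days staff two nurses per night cohort where
a cheaper feasible configuration exists — so the package treats the
published vectors as a feasibility reference, not as solver targets, and
reports model optima separately.

## The solver

The instance is tiny (eight integer variables) but must be solved exactly
and deterministically, thousands of times in sweeps and tests, so
`solve_staffing()` is a bespoke depth-first branch-and-bound:

* **Parity substitution.** $x_{iN_1} = x_{iN_2}$ is substituted out before
  search: one night variable per skill, halving the dimensionality to six.
* **Branch order.** Skills then shifts, by decreasing cost per delivered
  hour (nurse night, nurse morning/afternoon, technician night, technician
  morning/afternoon); values ascend from the forced minimum.
* **Bound.** Cost of the partial assignment, plus the forced minima of the
  unassigned cells, plus the residual demand costed at the cheapest
  remaining rate per delivered hour (rates include the $(1+p)$ buffer, so
  the continuous relaxation is never optimistic about hours).
* **Incumbent.** A greedy warm start fills demand with day technicians and
  repairs the skill mix with day nurses, giving the bound something to cut
  against from the first node.
* **Search bounds.** Each cell is capped at
  $m_{is} + \lceil (1+p) H / \min L \rceil$, a generous envelope; an
  instance with no feasible point inside it raises a typed
  `staffing_infeasible` condition carrying the tightest violated
  constraint family (deliberately a signal, not a crash).
* **Tie-break.** Equal-cost optima are ordered lexicographically by
  (cost, total staff, nurse vector, technician vector), so repeated solves
  return byte-identical solutions.

`solve_oracle()` is the independent check: it enumerates *every* integer
point within the bounds (vectorised, refusing instances whose per-cell
bound exceeds `cap = 8`), applies the same feasibility test, and returns
the optimum under the same tie-break. The test suite asserts objective
equality between the two on 200 seeded random instances spanning all
variant combinations, plus cost monotonicity (non-decreasing in demand,
minima and TSI; non-increasing in the balance bound) and feasibility of
every returned solution.

## What the synthetic generators emulate

`random_census()` draws per-category counts uniformly from ranges sized
like the case-study unit (a medium general ward: 10–25 minimal, 4–12
intermediary, 0–4 semi-intensive, 0–2 intensive, 0–3 unclassified).
`random_instance()` draws small Phase II instances — demand up to 15
hours, TSI in {0, 0.1, 0.15, 0.2}, nurse share up to 0.4, minima 0–1,
balance 0–2, random variant flags — sized so the enumeration oracle's
default cap admits every instance; 200 of them solve in well under a
minute. Neither generator models admission seasonality, correlated
day-to-day occupancy, or per-shift demand peaks; passing tests therefore
demonstrate correctness of the arithmetic and the optimization, not
calibration to any real unit's demand process.

## Numerical choices and degenerate inputs

Care hours are plain doubles compared at `1e-9`; monetary values at
`1e-6`, which is also the feasibility tolerance (slacks smaller than a
millionth of a worker are noise, not violations). Zero demand with zero
minima yields the all-zero staffing at cost 0. A census with no patients
is a demand of 0 hours but has no defined nurse ratio, so `phase1()`
refuses it. TSI = 0 collapses the buffer link to $x \ge y$. The weighted
ratio of a single-category census is that category's percentage exactly.

## Problem sizes used by the shipped checks

The test suite solves the eight case-study days (demand 98–164 h, bounds
≈ 33 per cell, each a few hundredths of a second), a 3×3 sensitivity
grid, and several hundred oracle-sized random instances; the whole suite
runs in a few seconds. These sizes were chosen as the smallest that
exercise every constraint family and both solver routes.

## Known limitations

* The skill-mix share enters as printed (an integer percent / 100); units
  whose regulator prescribes fractional shares can pass `prop` directly.
* Demand is daily; the model does not split required hours across shifts
  beyond the minimum-cover mechanism, mirroring its source.
* The floating pool (tactically dimensioned relief staff) is out of
  scope; the comparison utilities only measure the permanent pool against
  a constant actual roster.
* The branch-and-bound is exact *within its bound envelope*; for extreme
  parameter corners (e.g. a nurse share approaching 1 with forced
  technician minima) it reports infeasibility-within-bounds rather than
  searching an unbounded lattice.
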