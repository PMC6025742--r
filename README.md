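# nursedim

Strategic dimensioning of the permanent nursing pool of a hospital
inpatient unit: how many **nurses** and **nursing technicians** to assign
to the **morning**, **afternoon** and two alternating **night** cohorts so
that the legally required daily care is delivered at minimum salary cost.

The package is aimed at hospital management and health-workforce analysts
working under nurse-to-patient standards such as Brazil's COFEN Resolution
293/2004, and at operations-research practitioners who want a small, exact,
fully testable staffing model rather than a spreadsheet.

## The method

**Phase I** converts a severity-stratified census into demand. With
$n_c$ patients in category $c$ (minimal, intermediary, semi-intensive,
intensive; unclassified patients count as intermediary) and COFEN hours
$h_c = (3.8, 5.6, 9.4, 17.9)$:

$$\mathit{hours} = \sum_c n_c h_c,$$

plus a minimum nurse share $\mathit{prop}$ of the workforce — either the
standard's dominant-category rule or (default) a demand-weighted average of
the category percentages $(33, 33, 42, 52)\%$, which is the rule that
reproduces the published case-study values.

**Phase II** solves the integer program

$$\min \sum_{i,s} L_{is}\, r_i\, (1 + \pi\,[s\ \text{night}])\; x_{is}$$

over integer staff counts $x_{is}$ (skill $i$, shift $s$) subject to:
demand coverage through pre-buffer levels $y$, the Technical Safety Index
$x \ge (1+p)\,y$ (a 15% absence buffer), the skill mix
$\sum_s x_{ns} \ge \mathit{prop} \sum_{i,s} x_{is}$, a morning/afternoon
balance bound $|x_{iM} - x_{iA}| \le \alpha_i$, night parity
$x_{iN_1} = x_{iN_2}$, and per-shift minimum cover. Defaults: nurse
1 m.u./hour, technician 0.6, night premium $\pi = 37.5\%$, shifts
6/6/12 h, minimum 1 worker per skill and shift, $\alpha = 1$.

The model is solved exactly by a deterministic depth-first
branch-and-bound (`solve_staffing()`), verified against an
exhaustive-enumeration oracle (`solve_oracle()`). See the vignette
`vignettes/nurse-staffing-methods.Rmd` for the model, the solver design
and the open algebraic choices exposed by `model_variant()`.

## Worked example

One day of a medium inpatient unit — 17 minimal, 7 intermediary and 1
semi-intensive patient:

```r
library(nursedim)

demand <- phase1(patient_census(minimal = 17, intermediary = 7,
                                semi_intensive = 1))
demand
#> Demand profile: 113.2 care hours/day, 34% minimum nurses (weighted rule)

solve_staffing(build_instance(demand))
#> Staffing solution (morning, afternoon, night1, night2):
#>            morning afternoon night1 night2
#> nurse            2         3      1      1
#> technician       4         5      1      1
#> Objective cost: 115.2 m.u.
```

Reading: the unit needs 113.2 care hours per day and at least 34% nurses.
The cheapest compliant pool is 7 nurses and 11 technicians — 2/3 nurses
and 4/5 technicians on morning/afternoon, one of each per night cohort —
costing 115.2 monetary units of salary per day.

The packaged eight-day Hospital São José census reproduces the published
Phase I column exactly and solves all eight days:

```r
rep <- staffing_multiday(hsj_eight_days()$census)
rep[, c("date", "care_hours", "nurse_ratio", "total_staff", "total_cost")]
#>         date care_hours nurse_ratio total_staff total_cost
#> 1 2016-09-07      164.0          35          28      158.4
#> 2 2016-09-08      120.6          34          20      122.4
#> 3 2016-09-09      124.4          34          20      122.4
#> 4 2016-09-10       98.0          34          15      102.0
#> 5 2016-09-11      109.4          35          17      109.2
#> 6 2016-09-12      113.2          34          18      115.2
#> 7 2016-09-13      154.8          34          26      148.8
#> 8 2016-09-14      164.0          34          28      158.4
```

`staffing_sweep()` reproduces the sensitivity layout (minimum staff ×
balance grid), `compare_actual()` measures any staffing table against a
constant real roster, and `check_feasibility()` audits a hand-written
staffing vector constraint by constraint.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/nursedim multiday --census inst/extdata/hsj_table2.csv
Rscript inst/cli/nursedim sweep --census inst/extdata/hsj_table2.csv \
    --date 2016-09-12 --min-staff 1,2,3 --alpha 1,2,3
```

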