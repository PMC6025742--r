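# nursedim configuration schema, shown with the shipped defaults.
# Every key is optional; omitted keys keep these values.

care_standard:
  hours_per_patient:        # daily care hours per patient, by severity
    minimal: 3.8
    intermediary: 5.6
    semi_intensive: 9.4
    intensive: 17.9
  nurse_pct:                # minimum nurse percentage, by severity
    minimal: 33
    intermediary: 33
    semi_intensive: 42
    intensive: 52
  tsi: 0.15                 # Technical Safety Index (absence buffer), fraction

shift_structure:            # shift lengths in hours (night covers both cohorts)
  morning: 6
  afternoon: 6
  night: 12

cost_schedule:
  nurse_rate: 1.0           # monetary units per hour
  technician_rate: 0.6
  night_premium: 0.375      # fractional premium on night hours

model_parameters:
  prop: null                # nurse fraction override; null = take Phase I output
  alpha:                    # max morning/afternoon headcount difference
    nurse: 1
    technician: 1
  min_staff: 1              # scalar, or nested nurse/technician per-shift lists

variant:                    # algebraic reading of the TSI/demand constraints
  tsi_scope: per_cell       # per_cell | per_skill | global
  aux_integrality: continuous   # continuous | integer
  night_demand_hours: both_cohorts  # both_cohorts | single_cohort
  prop_counting: all_employees      # all_employees | per_day_staff

solver:
  oracle_cap: 8             # enumeration oracle refuses larger per-cell bounds
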