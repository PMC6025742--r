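Package: nursedim
Title: Multi-Skill Nurse Staffing and Shift Dimensioning for Hospital Units
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dimensions the permanent pool of nurses and nursing technicians
    of a hospital inpatient unit from a severity-stratified patient census.
    Phase I converts the census into required daily nursing care hours and a
    minimum nurse-to-staff percentage following the Brazilian COFEN 293/2004
    care standards; Phase II solves an integer program that assigns nurses
    and technicians to morning, afternoon and alternating night shifts at
    minimum salary cost, subject to demand coverage, a Technical Safety
    Index absence buffer, skill-mix, morning/afternoon balance, night-parity
    and minimum-cover constraints. Includes an exact branch-and-bound
    solver, an exhaustive-enumeration oracle, parameter-sweep and multi-day
    reporting utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
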