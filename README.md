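# dfrcest

Model-based estimation of PEEP-induced dynamic functional residual
capacity (dFRC) from mechanical-ventilation pressure–flow waveforms.

## The problem

Ventilated ARDS patients receive positive end-expiratory pressure (PEEP)
to keep collapsed lung recruited. The end-expiratory volume retained above
the resting functional residual capacity — the dynamic FRC — tells the
clinician what the applied PEEP is achieving, but direct measurement
(deflation to zero PEEP, gas washout, CT) interrupts ventilation. This
package is for respiratory-mechanics researchers and physiological
modellers who want dFRC estimated non-invasively from quantities a
ventilator already records, and who need a controlled synthetic test bed
for such estimators.

Four estimators are implemented:

| Method | Needs | Estimate |
|---|---|---|
| SSMB | measured dFRC at ≥ 2 PEEP steps, β-table | dFRC = (ΔdFRC/ΔPEEP) · β(PEEP) |
| SSSB | one breath at one PEEP, β₁-table | dFRC = β₁(PEEP) · V_t² / ΔP_aw |
| SCSB | one breath, no population constant | V_Po = PEEP / E_rs (a dFRC proxy) |
| CM | whatever is available so far | SSSB with 1 level, SSMB with ≥ 2 |

Respiratory elastance `E_rs` comes from an integral-based least-squares
fit of the single-compartment equation of motion
`P_aw = E_rs·V + R_rs·Q + P_0` to the inspiratory portion of a breath.
The per-PEEP population constants β (cmH2O) and β₁ (cmH2O/L) are
calibrated as per-PEEP medians over a cohort with measured dFRC.

The package also provides waveform CSV reading with unit conversion,
breath segmentation and zero-flow plateau detection, a synthetic
ventilated-patient simulator with known ground-truth recruitment (logistic
in PEEP, with auto-PEEP support), leave-one-out calibration, agreement
reporting (trend R², non-parametric error statistics), and a command-line
pipeline (`inst/cli/dfrc.R`: simulate / calibrate / estimate / evaluate).

## Worked example

Simulate a reference cohort (10 virtual patients, stepwise PEEP 5/10/15
cmH2O, heterogeneous mechanics and recruitment, measurement noise),
calibrate the multiple-breath constant, and estimate one patient's dFRC:

```r
library(dfrcest)

co   <- simulate_cohort(reference_cohort_spec(42))
ssmb <- calibrate_beta_ssmb(co)
ssmb
#> <beta_table SSMB> beta per PEEP [cmH2O]
#>  peep median_value n_patients      min      max      iqr
#>    10     11.63532         10  5.51076 16.35074 3.195816
#>    15     17.17290         10 12.08282 69.50973 4.487880

estimate_ssmb(co[[1]], ssmb, 15)
#> <dfrc_estimate SSMB> 1.788 L at PEEP 15.0 cmH2O (beta 17.17 cmH2O)
```

The table rows are the per-PEEP medians of the patient-wise constants with
their dispersion; the estimate multiplies this patient's measured volume
responsiveness over the 10→15 step by the population constant at 15 cmH2O,
giving 1.79 L of PEEP-retained volume.

Running all four estimators against the cohort's measured dFRC and ranking
by pooled trend agreement:

```r
prs     <- evaluate_cohort(co)
reports <- lapply(names(prs), function(m) compute_agreement(prs[[m]], m))
rank_methods(reports)
#>   method n_pairs r_squared  median_error iqr_error
#> 1   SSMB      20 0.9086883  0.0020023059 0.2070343
#> 2     CM      30 0.8868876 -0.0001259021 0.2255235
#> 3   SSSB      30 0.6719653  0.0002835639 0.6406915
#> 4   SCSB      30 0.2000559 -0.4517371071 0.8738469
```

The responsiveness-based methods (SSMB, CM) track measured dFRC closely;
the single-breath stress–strain method is moderate; the uncalibrated
single-compartment proxy trails and shows a systematic offset (its median
error is its unscaled-proxy nature, not a bug). Errors are estimated −
measured, in litres, so overestimation is positive.

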