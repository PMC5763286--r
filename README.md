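# pbpkcnm

Whole-body physiologically based pharmacokinetic (WB-PBPK) modelling of
irinotecan with Cluster Newton ensemble parameter estimation, for
pharmacometricians studying which drug-related parameters are
*identifiable per patient* from sparse excretion data.

## The problem and the method

Irinotecan (CPT-11) and its metabolites SN-38, SN-38G, NPC and APC are
tracked through 16 circulatory compartments plus a biliary
transit / gut-lumen elimination chain with enterohepatic recirculation.
Each organ is perfusion-limited — exchange at
`Q_i (C_in − C_i / Kp_i)` — and the liver hosts the metabolic cascade
(CES2: CPT-11→SN-38, NPC→SN-38; CYP3A4: CPT-11→APC, CPT-11→NPC; UGT1A:
SN-38→SN-38G). Per patient, 13 observables are available (urinary and
fecal recovery, % of dose, and Cmax in µg/ml), but the model carries 105
drug-related parameters (70 tissue–plasma partition coefficients Kp, 10
clearances, 5 metabolic clearances, 20 rate constants): the inverse
problem is underdetermined.

The **Cluster Newton Method** estimates the *solution set*: a cluster of
parameter vectors (log-uniform in the prior box) is iteratively moved by
minimum-norm Newton steps on a globally fitted affine surrogate
`y ≈ A log θ + b`, each point toward its own randomized copy of the
target, with step damping `dS = 0.2`. Fit quality is the sum of squared
relative residuals (SSR).

The **three-step constraint-based analysis** then asks what becomes
identifiable when drug-physicochemistry is shared across patients:

1. unconstrained CNM per patient (all 105 parameters, 10 iterations);
2. fix each Kp at its median over all parameter sets with SSR ≤ 0.03,
   pooled across patients;
3. Kp-constrained CNM per patient (35 free parameters, 15 iterations),
   then flag parameters whose ensemble coefficient of variation
   (CV = sd/mean) is ≤ 0.3 as strongly converging.

Under the constraint, the renal clearance of CPT-11 (#71), the biliary
clearance of CPT-11 (#76) and the CPT-11→APC metabolic clearance (#83)
converge strongly in every patient.

## Worked example

```r
library(pbpkcnm)

study <- loadPackagedStudy()          # the seven analyzed patients
p1    <- study$patients[["patient_1"]]
p1
#> <patient_physiology> patient_1
#>   M, 73 y, 171.6 cm, 109.1 kg (BMI 37.1)
#>   dose 1000 ug/kg over 90 min infusion
#>   cardiac output (lung flow) 54.9 ml/min/kg, liver total 14.9

# forward simulation at an interior parameter set
theta <- makeTruthParameters(seed = 3)
round(computeObservables(simulatePBPK(p1, theta)), 3)
#>      urine_CPT11       urine_SN38      urine_SN38G        urine_NPC
#>           38.201            2.325           29.081            0.457
#>        urine_APC      feces_CPT11 feces_SN38_SN38G        feces_NPC
#>            0.972           11.654            9.295            0.217
#>        feces_APC       cmax_CPT11        cmax_SN38       cmax_SN38G
#>            7.793            0.825            0.152            0.206
#>         cmax_APC
#>            0.049
```

Urinary/fecal entries are % of dose at 21 days; Cmax is the venous-blood
peak in µg/ml. At this random parameter set ~99.9% of the dose is
recovered (mass balance is enforced to 1e-6 × dose) but the split does
not match patient 1's data — that is what the estimator is for:

```r
one  <- studyInputs(study$patients[1], study$objectives[1, , drop = FALSE],
                    study$bounds)
pipe <- runPipeline(one, cnmPreset("reduced", stage = 1, seed = 1))
min(pipe$stage1[[1]]$final$ssr, na.rm = TRUE)   # best stage-1 fit
#> [1] 0.00966
nrow(pipe$selected$points)                      # sets with SSR <= 0.03
#> [1] 22
round(pipe$cv2$cv[1, c(71, 76, 83)], 3)         # stage-2 CVs
#>   CLr_CPT-11 CLbile_CPT-11     CL_3A4_1
#>        0.112         0.122        0.144
round(pipe$cv1$cv[1, 71], 3)                    # same parameter, stage 1
#> [1] 0.219
```

The best stage-1 fit reproduces all 13 observables to ~2.7% on average
(SSR 0.0097). After fixing Kp, the renal clearance of CPT-11 tightens
from CV 0.22 to CV 0.11 — the constrained ensemble pins it down even
though the unconstrained one could trade it against Kp freely.

Synthetic studies with known ground truth quantify recovery end to end:

```r
st  <- makeSyntheticStudy(n_patients = 1, noise_cv = 0, seed = 11)
rec <- recoveryExperiment(st)
rec$ratio[1, 71]      # stage-2 cluster median / truth for parameter #71
#> [1] 1.043
```

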