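# ucmreach

Uncontrolled manifold (UCM) analysis of tool-extended reaching movements.

When a person points at a target — with the index finger or with a rod held
as a tool — the arm's nine relevant joint angles (three shoulder, elbow
flexion, forearm pronation, two wrist, two finger) are redundant with
respect to the 3-D tip position. `ucmreach` quantifies how that redundancy
is used: it splits the inter-trial joint-angle covariance `C` at a movement
instant into variance along the manifold of configurations that leave the
tip fixed (goal-equivalent variability, GEV) and variance orthogonal to it
(non-goal-equivalent variability, NGEV), using the null space and row space
of the tip Jacobian `J` at the mean configuration:

```
NGEV    = trace( orth(Jᵀ)ᵀ C orth(Jᵀ) ) / d        d = 3
GEV     = trace( null(J)ᵀ  C null(J)  ) / (n − d)   n = 9
V_Ratio = GEV / NGEV
```

each normalized per dimension of its subspace and log-transformed before
aggregation. `V_RatioLog > 0` means the tip position is stabilized by
flexible joint covariation.

The package provides, for anyone studying motor redundancy in reaching or
tool use:

* **arm model** — forward kinematics and finite-difference Jacobian of the
  9-DOF arm-plus-rod chain, with SVD null/orthogonal subspace bases;
* **ucm** — the GEV/NGEV/V_Ratio decomposition plus an independent
  brute-force projection oracle;
* **kinematics** — the endpoint battery: tangential velocity,
  velocity/radius movement-bounds detection (25 mm/s, 10 mm), peak velocity,
  acceleration/deceleration times, horizontal/vertical path curvature,
  absolute and variable error, and 100-point time normalization;
* **synthetic data** — a generator emulating an eight-condition design (rod
  0/10/20/30 cm × participant displaced or not, 25 trials each, 100 Hz):
  minimum-jerk reference paths, damped least-squares inverse kinematics, and
  smooth joint-space noise injected isotropically in the Jacobian null space
  (std `sigma_gev`) and its complement (`sigma_ngev`), so the ground-truth
  GEV/NGEV are known exactly;
* **pipeline** — YAML-configured orchestration producing per-condition JSON
  records, summary CSV tables, and a failure log, byte-identical across
  reruns; a thin CLI lives at `inst/cli/ucmreach.R`
  (`simulate` / `analyze` / `run` / `summarize`).

## Worked example

```r
library(ucmreach)

cond  <- condition_spec(rod_length = 200, displaced = FALSE)  # 20 cm rod
model <- variability_model(seed = 42)   # sigma_gev 2 deg, sigma_ngev 0.5 deg
ens   <- generate_condition_dataset(cond, model = model)
res   <- analyze_ensemble(ens)
res
```

```
Condition rod200_fixed: 17/25 trials analyzed (8 detection failures)
  absolute error 7.06 mm, variable error 2.80 mm
UCM decomposition (n = 9 joint dims, d = 3 task dims)
  GEV  = 0.00127193 rad^2/dim (log -6.667)
  NGEV = 4.17421e-05 rad^2/dim (log -10.08)
  V_Ratio = 30.4712 (log 3.417)  -> tip position stabilized
```

Read: of 25 simulated pointing trials, 17 passed movement-bounds detection;
the 8 failures (trials whose perturbed tip never simultaneously satisfied
the 25 mm/s and 10 mm landing predicates — a long rod amplifies joint noise
at the tip) are logged, not dropped silently. At the end of the movement the
joint-angle variance per null-space dimension (GEV, 1.27e-3 rad²) far
exceeds the variance per orthogonal dimension (NGEV, 4.2e-5 rad²);
V_RatioLog = 3.42 > 0, so the rod tip is stabilized by joint covariation —
as injected, since the generator used a 4:1 GEV:NGEV standard-deviation
ratio. Endpoint accuracy (absolute error ~7 mm against a target 300 mm away)
is of the order seen in seated pointing.

The full study pipeline:

```r
write_default_config("config.yaml", seed = 1)
run <- run_pipeline("config.yaml", "output")   # 8 conditions x 25 trials
run$summary$ucm[, c("condition", "gev", "ngev", "v_ratio_log")]
```

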