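# dissopt

Neural-network surrogate optimization of sustained-release matrix
formulations against a target dissolution profile.

## The problem

Sustained-release hydrophilic matrix tablets control drug release
through the levels of gel-forming polymers in the tablet. Finding the
composition whose *in vitro* dissolution profile matches a reference
product is expensive when every candidate must be granulated, compressed
and run through a 12-hour dissolution test. `dissopt` implements the
in-silico alternative for a four-factor system — Methocel K100M (HPMC,
x₁, mg), xanthan gum (x₂, mg), Carbopol 974P (x₃, mg) and the
concentration of Surelease ethylcellulose dispersion used as granulating
fluid (x₄, % w/w):

1. **Design** — a four-factor central composite design (16 factorial +
   8 axial + 6 center runs = 30 formulations) spans the composition
   domain and defines the training corpus.
2. **Surrogate** — a single-hidden-layer perceptron maps the four
   factor levels to the percent released at 1, 2, 4, 6, 8 and 12 h
   (180 = 30 × 6 scalar input–target pairings). Inputs and targets are
   min–max scaled to [−1, 1]; the hidden layer uses the logistic
   sigmoid 1/(1+e^(−Σ)), the output layer is linear. Training is
   Levenberg–Marquardt least squares on the scaled MSE with a 67/33
   train/held-out split (67% of the held-out records form a validation
   set), best-validation checkpoint restore, and stopping after 800
   epochs or 200 validation failures. The hidden-layer size is chosen
   by sweeping 3–10 nodes and comparing held-out predicted-vs-observed
   R² per time point.
3. **Optimization** — every composition on a grid over the domain
   (42,525 candidates by default) is pushed through the surrogate and
   scored against the reference profile with the f2 similarity factor

   f₂ = 50·log₁₀( 100·[1 + (1/n)·Σₜ(Rₜ−Tₜ)²]^(−½) ),

   where Rₜ and Tₜ are the percent dissolved at time t for the
   reference and test profiles. f₂ = 100 means identical profiles; a
   uniform 10-point gap gives ≈ 50, the conventional similarity
   cutoff. The candidate with the highest f₂ wins.

Because the original dissolution measurements exist only as published
figures, the package ships a synthetic study generator: a
composition-dependent Weibull release model, y(t) = 100·(1 −
exp(−(t/τ)^β)), with τ log-linear in the scaled composition and small
Gaussian measurement noise, calibrated so the 30-run corpus releases
roughly 25–50% at 1 h and ≥ 80% at 12 h with release retarded by every
polymer. That makes the entire pipeline runnable and testable end to
end.

## Worked example

```r
library(dissopt)
res <- run_pipeline(pipeline_config(seed = 42))
print(res$sweep)
print(res$optimization)
```

```
Hidden-node sweep (held-out R^2 per time point):
 n_hidden r2_t1h r2_t2h r2_t4h r2_t6h r2_t8h r2_t12h mean_r2 n_successful
        3 0.7005 0.8179 0.7946 0.7634 0.7561 0.22879  0.6769            1
        ...
        5 0.7325 0.7928 0.8184 0.7209 0.7706 0.24216  0.6796            1
        ...
Selected hidden nodes: 5
Optimized formulation (f2 = 98.6 over 42525 candidates):
Formulation: Methocel 0 mg, xanthan 45 mg, Carbopol 12.5 mg, Surelease 12% w/w
Dissolution profile (% released):
  1 h   2 h   4 h   6 h   8 h  12 h 
44.17 62.12 79.26 88.18 92.87 97.29
```

The sweep table reports, for each candidate hidden-layer size, the
squared correlation between predicted and observed release on the
held-out records at each sampling time; 5 nodes win here on mean R².
The optimizer then returns the grid composition whose simulated profile
is most similar (f₂ = 98.6) to the synthetic reference profile — here a
reference generated at 45 mg HPMC / 30 mg xanthan / 5 mg Carbopol / 10%
Surelease, whose true profile (43.7, 61.6, 79.7, 88.4, 93.0, 97.2% at
1–12 h) the winning candidate's prediction tracks within about half a
percentage point. Note that the winning *composition* is far from the
reference composition even though the *profiles* match closely: many
compositions in this system produce nearly identical release curves
(see the methods vignette on identifiability).

Individual stages are available as plain functions:
`generate_ccd()`, `generate_study()`, `train_mlp()`, `node_sweep()`,
`retrain_full()`, `f2_similarity()`, `optimize_formulation()`, with
`read_dataset()`/`write_dataset()` and
`read_surrogate()`/`write_surrogate()` for the CSV corpus and JSON
model formats.

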