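# thrustwake

Fish swimming directly behind a flapping body sit in a *thrust wake*: a
reverse Kármán vortex street whose time-averaged centerline flow is *faster*
than the free stream. Whether live fish exploit such wakes is studied by
letting them hold station behind a robotic flapping foil and comparing their
kinematics and the pressure around their head against free-stream swimming.
`thrustwake` implements the computational side of that experimental
programme for researchers in fish biomechanics and biological fluid
dynamics:

- **Foil kinematics** — the two-degree-of-freedom motion program
  `y_sway(t) = a_sway sin(2πft)`, `φ_yaw(t) = a_yaw sin(2πft − π/2)`, the
  posed NACA 0012 outline, the trailing-edge excursion, and the
  nondimensional numbers `St = A·f/U` and `Re = U·L/ν`.
- **Midline kinematics** — from digitised midline tracks (markers × frames):
  spline resampling to equal-arclength stations, tail-beat frequency from
  peak intervals, joint angles over N = 20 equal-length segments,
  intersegmental phase lags `Δφᵢ = 2π·lag(φᵢ, φᵢ₊₁)/T` by circular
  cross-correlation, the overall phase lag `ΔΦ = Σ Δφᵢ` and body wavelength
  `λ = 2π/ΔΦ` (in body lengths), PCA-based amplitude envelopes, and the
  foil–fish phase difference as a function of gap distance.
- **Pressure fields** — reconstruction from sequential planar velocity
  fields via the Eulerian momentum balance
  `∇p = −ρ(∂u/∂t + (u·∇)u) + μ∇²u`, integrated by median polling over eight
  families of boundary-seeded straight paths with solid-mask blocking, and
  the mean head pressure in a snout box (0.1 BL × body width), whose product
  with the frontal area estimates pressure drag (`F = p·S`).
- **Statistics** — Welch t-tests (Satterthwaite df, explicit one-sided
  directions) and OLS fits with R² for the phase–distance relationship.
- **Synthetic data** — seeded generators for traveling-wave swimmers
  (`y(s,t) = A(s) sin(2πft − 2πs/λ + φ₀)` on an inextensible body),
  Lamb–Oseen reverse/classical Kármán streets, analytic oracle flows,
  body masks, and wake-locked in-line followers, so the entire pipeline runs
  and is tested without laboratory data.

## Worked example

Simulate a noisy digitised swimmer (2 Hz, one body length of wave, 0.19 m
body), run the kinematic chain, and read off the recovered parameters:

```r
library(thrustwake)

trk <- simulate_swimmer(swimmer_spec(
  f = 2, lam = 1.0, a_head = 0.019, a_tail = 0.019,
  n_markers = 33, duration = 3, noise_sd = 5e-4, seed = 1))
rs    <- resample_midline(trk, n_out = 33, keyframe_stride = 1, smooth = TRUE)
f_hat <- tailbeat_frequency(rs)
f_hat
#> [1] 1.99
phase_lags(joint_angles(rs), T = 1 / f_hat)
#> <phase_lag_result> overall 6.113 rad (0.973 cycles), wavelength 1.028 BL
tail(amplitude_profile(rs), 1)
#> # A tibble: 1 × 2
#>    s_bl amplitude_m
#>   <dbl>       <dbl>
#> 1  1.00      0.0200
```

The recovered frequency (1.99 Hz vs 2), overall phase lag (6.11 rad vs 2π,
i.e. wavelength 1.03 BL vs 1.0) and tail amplitude (20.0 mm vs 19 mm + noise)
are all within a few percent of the generator's ground truth. The bundled
demonstration pipeline chains the follower experiment on top:

```r
out <- run_pipeline(demo_config(seed = 1), "run1")
#> pipeline seed 1 done in ... s: f = 2.011 Hz, slope = 38.11 rad/m, R^2 = 1.000
round(100 * out$te_peak_to_peak_m)  # foil trailing-edge excursion, cm
#> [1] 4
```

The phase–distance slope of ten wake-locked followers, 38.1 rad/m, equals
`2π/λ_w` for the default vortex spacing `λ_w = 0.165 m`, and the fit is
essentially perfect for noiseless followers — the synthetic analogue of the
linear phase–distance relationship observed behind the foil. Condition
comparisons use the statistics layer directly:

```r
welch_t(c(2.9, 3.4, 3.1, 3.0), c(2.1, 2.2, 1.9, 2.3), alternative = "greater")
#> <welch_t> t = 7.081, df = 5.697, p = 0.0002498 (greater)
```

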