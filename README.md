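# nucbreathe

Quantitative analysis of nucleosome conformational dynamics for
structural biologists and simulators studying how DNA-binding proteins —
in particular pioneer transcription factors like Oct4 — engage
nucleosome-wrapped DNA. The package measures *nucleosome breathing* (the
spontaneous opening of the linker DNA arms) and protein–DNA contact
statistics from molecular-dynamics trajectories or idealized models, and
implements the collective variables and bias protocols used to steer
such simulations.

## What it computes

Given a structure/trajectory and a chain-role configuration (which chains
are the two DNA strands, the eight histones, an optional TF):

* **Breathing angles.** An orthonormal frame XYZ is anchored on the dyad
  of a reference structure: X along the dyad axis, Z along the
  superhelical axis, Y completing the frame. For each linker arm
  direction v (best-fit axis of the 11-bp L-DNA),

  γ₁ = atan2(v·X, v·Z),  γ₂ = atan2(v·X, v·Y),

  the out-of-plane and in-plane opening angles in degrees.
* **Mass-weighted radius of gyration** of the DNA,
  Rg = √(Σmᵢ‖rᵢ−r̄‖²/Σmᵢ), after a rigid-body fit of each frame onto the
  histone core (tails excluded).
* **Contacts.** Two heavy atoms closer than 4.5 Å (strict) form a
  contact; counts are reported per atom pair or per (residue, base pair).
  A residue–bp contact is *stable* if present in more than 75% of the
  analyzed frames (strictly). Region bookkeeping uses the standard 168-bp
  partitions: 146-bp core with 11-bp linkers, and 88-bp inner gyre with
  40-bp outer gyres; TF subdomains (POU_S, POU_HD) are crossed with DNA
  bases/backbone per gyre and summarized as median (5th–95th percentile).
* **Collective variables.** The weighted minimum distance
  d⁽ⁿ⁾ = (⟨(1/‖dᵢⱼ‖)ⁿ⟩)^(−1/n) with n = 100, and the coordination number
  C = Σ (1−(r/d₀)⁶)/(1−(r/d₀)¹²) with d₀ = 4 Å — plus declarative
  harmonic-wall and steered-ramp protocols (force constant 10
  kcal·mol⁻¹·Å⁻², ramps such as 5→15 Å over 250 ns) evaluable over
  trajectories and exportable as Colvars-style configuration text.
* **A synthetic nucleosome generator** (idealized superhelix, 41.9 Å
  radius / 25.9 Å pitch / 1.65 turns, pseudo-histones with literal tail
  definitions, optional two-domain pseudo-TF) that emits breathing
  trajectories with exact ground truth, used to validate every estimator.

## Worked example

Generate a 50-frame synthetic breathing trajectory in which the 3' arm
opens by 40° while the 5' arm stays closed, then measure it:

```r
library(nucbreathe)

p <- synthetic_params(seed = 1, frames = 50,
                      opening = list(arm = "3p",
                                     dgamma1 = c(0, 40), dgamma2 = c(0, 0)))
synth <- generate_breathing_trajectory(p)
ser <- analyze_trajectory(synth$trajectory, synth$topology,
                          reference = synth$reference)
head(ser[, c("frame", "Rg_A", "gamma1_3p_deg", "intergyre_min_A")], 3)
#>   frame  Rg_A gamma1_3p_deg intergyre_min_A
#> 1     1 45.66         83.70            6.07
#> 2     2 45.67         82.88            6.07
#> 3     3 45.68         82.07            6.07
```

The closed nucleosome starts at γ₁(3') = 83.7° and Rg = 45.66 Å; by frame
50 the arm has opened to γ₁ = 43.7° (exactly the generator's ground-truth
target for that frame) and Rg has grown monotonically to 46.01 Å — the
opening↔Rg correspondence the angle was designed to capture.
`intergyre_min_A` is the minimal phosphate separation between the inner
and outer DNA gyres, 6.07 Å for this stacked geometry. Summaries follow
the median (p5–p95) table convention:

```r
format_summary(summarize_series(ser$gamma1_3p_deg))
#> [1] "63.7 (45.7–81.7)"
```

Evaluating the `tail_release` preset on the closed reference shows why a
bias is needed to detach the tails — both walls are strongly violated at
frame 0 (the tails sit on the outer gyre, minimal distance 3.4 Å against
a 12 Å wall, coordination 40.6 against an upper wall at 0):

```r
f <- tempfile(fileext = ".pdb")
write_structure(synth$reference, f)
ref_traj <- read_trajectory(f, synth$topology)
ev <- evaluate_protocol(ref_traj, bias_protocol_preset("tail_release"),
                        synth$topology)
round(ev[, c("value", "target", "energy_kcal_mol")], 2)
#>                        value target energy_kcal_mol
#> wall_dmin_tails_outer   3.43     12          367.01
#> wall_coord_tails_outer 40.57      0         8230.00
```

`export_bias_config(bias_protocol_preset("pou_hd_insertion"))` writes the
corresponding Colvars-style configuration (three steered ramps 5→15,
32→12, 58→28 Å over 250 ns plus guard walls at 30/0/20).

A command-line wrapper covers the same pipeline
(`inst/exec/nucbreathe fixture|analyze|contacts|colvar|report`, or
`nucbreathe_cli()` from R).

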