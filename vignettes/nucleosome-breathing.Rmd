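---
title: "Quantifying nucleosome breathing, tail-DNA contacts and bias protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleosome breathing, tail-DNA contacts and bias protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucbreathe)
```

## The measurement problem

Nucleosomal DNA is not statically wrapped: the two ends ("linker" or L-DNA
arms) of the superhelix detach and re-attach spontaneously. This *breathing*
controls how much of the wrapped sequence is transiently readable by DNA
binding proteins, and it is the motion that pioneer transcription factors
such as Oct4 exploit when they engage their motifs on nucleosome-occupied
DNA. `nucbreathe` implements the quantitative observables used to analyze
such systems from molecular-dynamics trajectories or idealized models:

* a dyad-anchored coordinate frame and the two breathing angles
  $\gamma_1$ (out-of-plane) and $\gamma_2$ (in-plane) of each linker arm;
* the mass-weighted radius of gyration $R_g$ of the DNA, a scalar proxy for
  openness;
* heavy-atom contact statistics between histone tails or TF subdomains and
  DNA regions, including residue-resolved *stable-contact* profiles;
* the two collective variables used to bias such simulations --- the
  weighted minimum distance (`distanceInv`) and the coordination number ---
  together with declarative harmonic-wall and steered protocols and their
  Colvars-style export;
* a seeded synthetic nucleosome generator that produces idealized
  structures and breathing trajectories with exact ground truth, so that
  every estimator in the package can be validated end to end.

## Geometry: regions, frame, angles

A 168-bp construct is partitioned twice, on the base-pair axis of the
reference strand (5'→3'): 146 bp of *core* DNA centered on the dyad with
11-bp linkers on each side, and, independently, a central 88-bp *inner
gyre* flanked by two 40-bp *outer gyres* (the terminal stretches of the
superhelix). Base pairs are 1-based and pair as $i \leftrightarrow
n_{bp}+1-i$ across strands; internal arithmetic is 0-based half-open to
avoid mirror-pairing off-by-ones. For an even number of base pairs the
dyad sits between the two central pairs and an even core splits 73/73
around it; any odd remainder of a partition is assigned to the 3' side.

The breathing frame is built **once** from the fitting reference and
reused for every frame --- recomputing it per frame would absorb the very
motion being measured. Its construction (`build_dyad_frame()`):

* origin: centroid of the heavy atoms of the dyad base pair(s);
* $X$: unit vector from the core-DNA centroid to the origin (the dyad
  axis);
* $n$: normal of the best-fit plane of the per-bp phosphate centers of the
  core. The raw least-squares plane of a superhelical *ramp* is tilted by
  the pitch (the linear rise correlates with the in-plane coordinates), so
  the linear trend along the path is removed before the fit; on ideal
  geometry the detrended normal coincides exactly with the superhelix
  axis. Its sign is fixed against the winding sense of the DNA path so
  that $Z$ points along the superhelical axis;
* $Y = X \times n_\perp$, $Z = X \times Y$ (right-handed, orthonormal to
  $10^{-8}$).

Each linker direction $v_5$, $v_3$ is the principal axis of the per-bp
centroids of the linker, oriented outward (core-proximal → terminal bp).
By default **all** heavy atoms enter the per-bp centroids: the two strands
sit at antipodal phases around the duplex axis, so on clean geometry the
centroids fall exactly on the arm axis, while under coordinate noise the
averaging over ~18 atoms/bp is what keeps the angle estimate inside its
stated tolerance (a phosphate-only fit is available via `elety = "P"`,
and an endpoint-difference variant via `method = "endpoints"`). Then

$$\gamma_1 = \operatorname{atan2}(v \cdot X,\; v \cdot Z), \qquad
  \gamma_2 = \operatorname{atan2}(v \cdot X,\; v \cdot Y),$$

in degrees, i.e. the signed angles from $Z$ (in the XZ plane) and from $Y$
(in the XY plane) to the respective projections of $v$, with positive
rotation about $+Y$ and $+Z$. The sign convention is this package's own
choice (reported angle distributions do not define one) and both signs can
be flipped per axis via the `flip` argument. A projection with near-zero
norm is reported as `NA` for that frame.

Superposition (`superpose_to_reference()`) is a least-squares rigid-body
fit over the C$\alpha$ atoms of the non-tail histone residues --- the
histone core, excluding the mobile tails --- against the reference
structure, delegated to `bio3d::fit.xyz()`. $R_g$ is
$\sqrt{\sum_i m_i \lVert r_i-\bar r\rVert^2 / \sum_i m_i}$ over the DNA
heavy atoms by default.

## Contacts

A contact is two non-hydrogen atoms **strictly** closer than 4.5 Å.
Counts are reported either as atom pairs or at (residue, base-pair)
granularity ("at least one contacting atom pair"); per-gyre counts add up
exactly to the all-DNA count because the gyre regions partition the base
pairs. A (residue, bp) contact is *stable* when its occupancy --- the
fraction of analyzed frames in which it is present --- **strictly
exceeds** 0.75; occupancy exactly 0.750 is not stable. The analyzed
window is whatever trajectory slice the caller passes (`--begin/--end`
and `stride` in the CLI); no implicit equilibration trimming is applied.
Residue-bp granularity is the default for stability (residue-resolved
profiles against bp position are the standard display); atom-pair-level
stability is available by building the profile on singleton selections.
Contact counting is a vectorized exact computation, arithmetic-identical
to the brute-force double loop that ships in the test suite as the
oracle; no approximate neighbor search is used.

The TF-subdomain table (`subdomain_gyre_contact_table()`) crosses POU_S
and POU_HD with DNA bases vs backbone and inner gyre / outer gyres / all
DNA, summarizing per-frame atom-pair counts as median (5th--95th
percentile). Atom-pair granularity is the default because tabulated
per-simulation contact numbers of this kind (tens to hundreds) are atom
pair counts; sugar atoms including C1' count as backbone together with
the phosphate, and the glycosidic nitrogen opens the base set --- the
conventional phosphodiester-plus-sugar backbone definition.

## Collective variables and bias protocols

The weighted minimum distance between groups 1 and 2 is

$$d^{[n]}_{1,2} = \left(\frac{1}{N_1 N_2}\sum_{i,j}
  \left(\frac{1}{\lVert d^{ij}\rVert}\right)^{n}\right)^{-1/n},$$

with $n$ an even integer (default 100), evaluated overflow-safely by
factoring the minimal distance out of the power sum. It decreases
monotonically toward the true minimum as $n$ grows and is bounded by
$d_{\min} \le d^{[n]} \le d_{\min}(N_1 N_2)^{1/n}$: the upper factor is
the cost of the $1/(N_1N_2)$ normalization when a single pair dominates.
At $n = 100$ that factor is $e^{\ln(N_1N_2)/100}$, about 1.05--1.09 for
group sizes of tens of atoms, i.e. a few tenths of an Ångström at contact
distances --- close enough to track the minimum smoothly, which is why
$n = 100$ is the default. Coincident atoms across groups drive the power
sum to infinity; the implementation returns the limit 0 with a warning.

The coordination number uses the standard rational switching function

$$C = \sum_{i \in g_1}\sum_{j \in g_2}
 \frac{1-(r_{ij}/d_0)^n}{1-(r_{ij}/d_0)^m},$$

with $d_0 = 4.0$ Å, $n = 6$, $m = 12$. Because $m = 2n$ the ratio
factorizes to $1/(1+(r/d_0)^6)$, which is free of the removable
singularity at $r = d_0$ and evaluates to exactly $1/2$ there; the
generic form with the analytic limit $n/m$ is used for other exponent
pairs. $C$ is continuous, strictly decreasing in distance, and bounded by
$N_1 N_2$.

Bias terms are declarative. A harmonic wall stores one or two bounds and
evaluates $E = \tfrac{k}{2}\,\Delta^2$, where $\Delta$ is the violation
depth (zero inside the allowed region) --- the $1/2$ convention is this
package's documented choice, with $k = 10$ kcal mol$^{-1}$ Å$^{-2}$ as
default force constant; "keep $C$ equal to 0" is realized as an upper
wall at 0 with the same $k$, and no extra wall-width parameter is used. A
steered term ramps its center linearly from start to end over its
duration and clamps thereafter. Two literal presets ship with the
package:

* `tail_release` --- walls keeping the H3/H2A tail to 3'-outer-gyre
  $\delta_{\min} > 12$ Å and the corresponding $C$ at 0 (the preset
  selects the whole tails of the proximal H3 and H2A copies; restrict the
  H2A selection to its C-terminal residues if only the H2A-C tail should
  be biased);
* `pou_hd_insertion` --- steered ramps POU_HD--inner gyre 5→15 Å,
  POU_HD--outer gyre 32→12 Å, POU_HD--3' L-DNA 58→28 Å over 250 ns, with
  guard walls: tails--outer gyre $\delta_{\min} > 30$ Å and $C = 0$, and
  inter-gyre $\delta_{\min} > 20$ Å.

CV groups default to C$\alpha$ (protein) and P (DNA) atoms and are
overridable. `evaluate_protocol()` reports per frame and term the CV
value, the instantaneous target and the restraint energy, flagging terms
as *effectively active* above $10^{-3}$ kcal/mol (a strict $>0$ flag
would always fire for coordination walls, whose value is positive at any
finite distance). `export_bias_config()` writes a deterministic
Colvars-style text block per variable and bias; `parse_bias_config()`
reads the same dialect back, and export→parse→export is a byte-level
fixpoint.

## The synthetic nucleosome and what it does (not) emulate

The generator builds an idealized 168-bp nucleosome from canonical
superhelix parameters --- radius 41.9 Å, pitch 25.9 Å, 1.65 turns for the
146-bp core --- with straight B-DNA-like linker arms (3.4 Å rise) leaving
the core tangentially. These are textbook nucleosome dimensions chosen so
that arc lengths and the DNA $R_g$ come out realistic; they are generator
parameters, not measurements. Each nucleotide carries nine heavy
pseudo-atoms (P, OP1, OP2, O5', C4', C1' backbone; N1, C2, C4 base) at
fixed radii from the duplex axis on a 36°/bp twisted two-strand lattice.
Nine is deliberate: it exercises the base/backbone partition and gives
per-bp noise averaging comparable to real DNA (~20 heavy atoms per
nucleotide), while the two strands sit at antipodal phases so per-bp
centroids lie exactly on the duplex axis and noise-free angle recovery is
exact. Masses are standard atomic masses, so mass-weighted $R_g$ is
exercised; the closed-state DNA $R_g$ of the default geometry is 45.7 Å.

Pseudo-histones are eight chains of C$\alpha$ beads: a rigid random
cluster (ball radius 24 Å) at the superhelix center serves as the
globular core --- and as the superposition selection --- plus tails with
the literal human or Drosophila residue ranges. In `wrapped` mode the H3
and H2A-C tails of the proximal copy hug the radially outward phosphates
of the 3' outer gyre (placement 3.5 Å from a P atom, away from the linker
junction so that arm motion does not mix into the tail signal); other
tails, and all tails in `released` mode, are seeded, mildly
self-avoiding walks that leave along the superhelical axis and stay
beyond contact range of the DNA. An optional two-domain pseudo-TF places
a POU_S cluster on a chosen site (approaching bases or backbone) and a
POU_HD cluster that is free, docked on the inner gyre, or bridging both
gyres through the inter-gyre gap.

Breathing trajectories rotate each arm rigidly about its core junction so
that its axis hits per-frame absolute $(\gamma_1, \gamma_2)$ targets; the
user-facing schedule is expressed as opening magnitudes relative to the
closed baseline ($\gamma_1 \approx 84°/96°$, $\gamma_2 \approx 63°/117°$
for the 3'/5' arms under this frame), applied in the sense that moves the
arm away from the DNA body --- the generator determines that sign
empirically from a 5° trial rotation, so "opening" always increases
$R_g$. Because the two projection angles jointly determine an axis only
on the $+X$ half-space, absolute targets must stay within (0°, 180°);
the default sweeps (tens of degrees around the baseline) are far from the
degeneracy. Ground truth records the exact per-frame targets, the tail
vs outer-gyre contact counts (recomputed, not assumed, by an independent
direct pair count --- accidental contacts are therefore part of the
truth), TF contact tables, and any release event; optional isotropic
Gaussian noise is layered on top, and all randomness flows from the
single seed (equal seeds give byte-identical output).

What passing on this generator shows --- and what it does not: the
estimators recover imposed rigid arm motions exactly and degrade
gracefully under isotropic coordinate noise, and all contact bookkeeping
is exact. Real trajectories add correlated thermal motion, DNA
deformation within the arms (the generator's arms are rigid and
straight), sequence-dependent geometry, and imperfect core superposition;
recovery tolerances measured here (±0.5° noise-free, better than ±2° at
σ = 1 Å per coordinate over 500-frame runs) are therefore best-case
calibrations of the pipeline, not error bars for real data.

## Reporting conventions

Series summaries are median with 5th--95th percentiles by linear
interpolation (the type-7 rule, fixed and documented since the convention
is otherwise ambiguous), formatted as `49.2 (48.3–51.0)`; `parse_summary()`
inverts the format. 2D $(\gamma_1, \gamma_2)$ histograms default to 1°
bins with display contours at 1 and 100 counts; multiple ensembles (free
vs TF-bound) are binned on a shared grid and kept separate. The CLI
(`nucbreathe_cli()`, wrapped by `inst/exec/nucbreathe`) histograms each
arm separately by default rather than pooling arms --- pooling is a
caller's choice when exporting.

## Numerical choices and edge cases

* Contact and minimum-distance computations compare squared distances
  assembled as $dx^2 + dy^2 + dz^2$ in plain double arithmetic, making
  them bit-identical to the naive double loop (no extended-precision
  accumulation, no approximate neighbor lists).
* `distance_inv` factors the minimum out of the $n$-th power sum, so
  $n = 100$ cannot overflow.
* Degenerate inputs fail loudly: empty groups, collinear core phosphates,
  linkers shorter than 3 bp, zero-width histogram bins, strand-length
  mismatches, unknown chain roles, out-of-range TF sites.
* Unrecognized DNA atom names are an error by default; a logged
  `backbone` fallback is available (`strict = FALSE`).
* Structure and trajectory I/O (PDB, multi-model PDB, mmCIF, DCD) and the
  rigid-body fit are delegated to `bio3d`; element and mass inference
  falls back from the element column to atom-name mapping with standard
  atomic masses. XTC is not supported (no installed reader); DCD input
  requires an accompanying structure for its atom table.
* Problem sizes used by the shipped tests and acceptance script: 500-frame
  noise-free and 100-frame noisy recovery runs of the ~4,000-atom
  synthetic system, 100 seeded random configurations per oracle check.
  These sizes make the whole validation run in well under a minute on one
  CPU while leaving the statistical headroom the tolerances need.

## Known limitations

* The generator's arms are rigid and straight; partial unwrapping
  (bp-resolution peeling) and DNA elasticity are not modeled.
* The breathing-angle sign convention and the dyad-frame realization are
  package choices; compare distributions, not raw signs, across tools.
* `distanceInv` carries the normalization bias described above; treat
  $d^{[100]}$ as a smooth upper envelope of the minimum distance, a few
  percent above it for realistic group sizes.
* Periodic-boundary treatment is out of scope: input frames are assumed
  pre-imaged (whole molecules), as is conventional for deposited,
  analysis-ready trajectories.
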