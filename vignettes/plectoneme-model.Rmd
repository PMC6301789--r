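---
title: "Predicting plectoneme pinning from DNA sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting plectoneme pinning from DNA sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plectoneme)
```

## The physical picture

When torsionally strained DNA converts twist into writhe it forms
plectonemes: intertwined loops whose tip is a sharply bent arc of roughly
240°, the angle needed to match the crossing duplexes in the plectoneme stem.
Forming that tip is the dominant energetic cost of nucleating a plectoneme,
and the cost depends on sequence: a segment that is already intrinsically
curved, in the right direction, is cheaper to close into the tip. The package
turns this observation into a parameter-free per-base prediction of where
plectonemes pin.

Two closed forms anchor the model. For a loop of $N$ base pairs under tension
$F$ (pN), pulling in the contour costs work $C N$ with $C = F/12.16$ (this
pins $k_BT$ to $0.334\,\mathrm{nm} \times 12.16\,\mathrm{pN} \approx
4.06\,\mathrm{pN\,nm}$), and worm-like-chain bending of a full circle costs
$B_{360}/N$ with $B_{360} = 2\pi^2 A/r \approx 2955$ ($A = 50$ nm bulk
persistence length, $r = 0.334$ nm rise). Minimizing $C N + B/N$ gives
$N^* = \sqrt{B/C}$: 109 bp for a 360° loop at 3 pN and, with the
$(240/360)^2$ scaling of a partial arc, 73 bp for the 240° tip:

```{r closed-forms}
optimal_loop_size(3, 360)
optimal_loop_size(3, 240)
```

Bending a straight 73 bp segment into the 240° tip costs about 18 $k_BT$;
a segment carrying 60° of aligned intrinsic curvature saves about 8 of them
via the $(1-\theta/240°)^2$ reduction — the energy scale that makes pinning
strongly sequence specific:

```{r tip-energy}
bend_energy(73, 50, 0)
bend_energy(73, 50, 0) - bend_energy(73, 50, 60)
```

## From sequence to density

1. **Ground-state path.** Each dinucleotide step applies fixed tilt/roll/
   twist wedge rotations to the material frame (twist about the tangent,
   then roll about the normal, then tilt about the binormal — the order is a
   documented package convention; the observable predictions absorb it into
   the calibration of the shipped parameter set) and advances 0.334 nm along
   the tangent.
2. **Curvature and bend direction.** Tangents are chords over an 11 bp
   window (one helical turn) so intra-turn wobble cancels. For a candidate
   tip of $N$ bp centered at $i$, $\theta(N,i)$ is the angle between the end
   tangents, and $\phi_B(N,i)$ is the azimuth — in the (normal, binormal)
   plane of the frame at $i$ — of the end-tangent change projected
   perpendicular to the mid-tangent. The mid-loop frame (rather than the
   loop-start frame) is the package's choice of angular origin; it makes
   $\phi_B$ and the stiffness machinery share one frame by construction.
3. **Direction-dependent stiffness.** Per-step tilt/roll covariance matrices
   are co-rotated by the accumulated twist and summed over the loop. Mapping
   a (tilt, roll) fluctuation to its tangent deflection $(\delta t, -\delta
   r)$ keeps this covariance in the same angular frame as $\phi_B$. The
   worm-like-chain conversion $A(N,i,\phi) = r N / (\hat u^\top \Sigma \hat
   u)$ is the unique choice for which per-plane variance $L/A$ over contour
   $L$ reproduces the bulk persistence length when the table is isotropic
   with variance $r/A$ per step. A ceiling of 1000 nm guards the degenerate
   zero-variance direction.
4. **Boltzmann summation.** For each center the model sums
   $W = \exp(-E_\mathrm{total})$ over loop sizes 40–120 bp in 8 bp steps and
   eight bend directions at every 45° starting from $\phi_B$, where
   $E_\mathrm{total} = C N + (2/3)^2\, 2\pi^2 A /(r N)\,
   [1 + (\theta/240)^2 - 2(\theta/240)\cos(\phi-\phi_B)]$
   (the law of cosines between imposed and intrinsic bend). $W_{tot}(i)$
   normalized to mean 1 over the molecule is the predicted plectoneme
   density, matching the normalization convention of measured single-molecule
   density profiles; $-\ln W_{tot}$ is the free-energy landscape in $k_BT$.
   The Boltzmann shorthand $P_B = \exp(-E_{loop})$ sometimes used for a
   single optimal loop is subsumed by this grid summation, which is the
   operational definition implemented here.

On a linear molecule the outer 65 bp have no full 120 bp loop support and
are reported `NA`, never zero — zeros would fabricate pinning deserts. On
circular molecules (bacterial chromosomes, plasmids) every window wraps.

```{r density-demo}
fx <- make_fixture("insert_in_backbone",
                   insert = make_fixture("phased_tract", length = 75,
                                         period = 10.5),
                   backbone_length = 2000, insert_position = 1000, seed = 5)
prof <- gaussian_smooth(plectoneme_density(fx), fwhm = 1600)
glance(prof)
```

## The dinucleotide parameter set

The geometry table (tilt/roll/twist per step, degrees in files, radians
internally, converted exactly once at load) and stiffness table (tilt/roll
covariance per step, rad²) are data, not code: plain-text files under
`inst/extdata/params/` with provenance headers, loadable alongside
user-supplied alternatives.

The shipped default, `wedge_synthetic`, is a synthetic composite wedge-style
set. Published wedge tables are scattered across supplements with differing
axis conventions, so the package freezes its own set, constructed once
against external macroscopic benchmarks and not revisited:

* strand-complement symmetry and a mean twist of 33.9°/step (10.6 bp
  helical repeat);
* phased A-tract macrocurvature of ~17°–24° per helical turn (the package's
  `phased_tract` fixture measures 17.3°/turn through the model itself);
* wedge-dispersion ("static") persistence length of several hundred nm,
  i.e. sequence heterogeneity subordinate to thermal bending.

The stiffness table centres the per-plane per-step variance on
$r/A = 0.334/50 = 0.00668$ rad² (per-step SD ≈ 4.7°) with mild
step-dependent variation — pyrimidine–purine steps softest, A-tract steps
stiffest and isotropic — so random-sequence DNA averages back to the 50 nm
bulk constant that also fixes $B_{360}$; keeping the two consistent is a
deliberate design constraint. A second set, `smooth_synthetic` (wedges
halved), exposes how predictions vary with the geometry set: curvature
contrast, and hence peak contrast, drops roughly fourfold in energy.

Because the set is synthetic, absolute peak heights for any specific natural
sequence are not expected to match a particular published scan; the
structural behavior (A-tract pinning, phasing sensitivity, GC-rich curved
pinning, ~1 $k_BT$ landscape roughness on random sequence) is what the
calibration targets and what the tests assert.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `tension` | 3 | pN | stretching force; enters $C = F/12.16$ |
| `bend_angle` | 240 | degrees | tip arc; $(angle/360)^2$ scales $B_{360}$ |
| `rise` | 0.334 | nm/bp | contour per base pair |
| `bulk_persistence_length` | 50 | nm | bulk WLC stiffness |
| `loop_sizes` | 40–120 by 8 | bp | grid spanning the 73 bp optimum |
| `n_directions` | 8 | — | bend directions anchored at $\phi_B$ |
| `fwhm` | 1600 | bp | Gaussian smoothing matching optical resolution |
| `smooth_window` | 51 | bp | boxcar for TSS meta-profiles |
| `max_A` | 1000 | nm | ceiling for degenerate directional stiffness |

Predictions are stable under densifying the (N, φ) grid; what matters is
that the spanned range brackets the isotropic optimum, not its granularity.

## Genome scanning and TSS meta-profiles

`scan_genome()` evaluates chromosomes in overlapping chunks; every model
quantity looks at most ±65 bp from its center, so tracks are independent of
the chunking (asserted to 1e-9 in the tests). Densities are normalized per
chromosome. `tss_metaprofile()` extracts windows around annotated TSS,
reverses minus-strand windows so negative offsets are always upstream on the
gene's strand, averages one window per site, and smooths with a centered
51 bp moving average — a plain reading of "smoothed over a 51 bp window",
kept swappable. Meta-profiles use the *unsmoothed* density: a 1600 bp kernel
would erase the ~100 bp upstream features the meta-profile exists to show.
Choosing the most representative TSS per gene is left to the user's
annotation; the tool never picks among alternatives.

## Numerical choices

* Angles live in radians internally; degrees at every file boundary.
* The twist origin of the covariance sum is the loop start (a single-step
  loop is unrotated), then the whole sum is conjugated into the center
  frame.
* Gaussian smoothing uses $\sigma = \mathrm{FWHM}/\sqrt{8\ln 2}$, a ±4σ
  truncated kernel with edge renormalization on linear molecules (the mean
  over defined positions is then restored exactly), and a wrapped, aliased
  kernel on circular molecules.
* `phi_b` is 0 by convention where curvature vanishes; the energy is then
  direction-independent, so the convention is unobservable.
* Ambiguity codes are rejected by default with the offending offset;
  `ambiguity = "substitute"` maps IUPAC codes to fixed representative bases
  with a warning, for genomes with N runs.
* Coordinates are 1-based in every user-facing table; bedGraph export is
  0-based half-open as that format requires.

## What the fixtures do and do not show

`make_fixture()` emulates the *design rules* of published single-molecule
constructs (phased A-tracts at 10.5 bp, GC-rich curved repeats, flat
random controls avoiding ≥4 bp homopolymer runs) rather than any literal
published sequence. Passing tests therefore demonstrate the model's
mechanics — pinning at designed curvature, phasing sensitivity,
translation equivariance, planted-TSS recovery — on synthetic molecules.
They do not reproduce measured intercalation-assay density profiles, which
require the experimental data and exact construct sequences. Note that
"flat" random backbones still carry accidental curvature hotspots (the
~1 $k_BT$ landscape roughness is real signal, exponentiated); the tests
assert where peaks are, not that random DNA is featureless.

Problem sizes used by the test suite and acceptance script — 20 kb for
landscape roughness, ≤11 kb genomes for scanning and meta-profiles, 250–300
bp for oracle equivalence — were chosen as the smallest molecules on which
each property is well-posed and stable.

## Known limitations

* Only tip-loop nucleation energetics: no plectoneme size/number/dynamics,
  no multi-plectoneme statistical mechanics, no linking-number dependence.
* No negative-supercoiling duplex melting; predictions apply to positive
  supercoiling or where melting is not the dominant relaxation mode.
* Nearest-neighbor (dinucleotide) parameterization only; beyond-nearest
  effects are a known source of false negatives for this model family.
* No twist stiffness, stretch, or twist–bend coupling in the stiffness
  accumulation.
* The shipped geometry set is a calibrated synthetic composite (above), not
  a transcription of a specific published table.
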