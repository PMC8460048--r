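---
title: "A stochastic, monomer-resolved model of microfibril saccharification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic, monomer-resolved model of microfibril saccharification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacchsim)
```

## The model

`sacchsim` simulates the enzymatic saccharification of a single plant cell
wall cellulose microfibril, resolved monomer by monomer in three dimensions.
The substrate is a bundle of 36 parallel cellulose chains (configurable; the
36-chain quasi-hexagonal cross-section mimics grass microfibrils) of 200
glycosidic bonds each, surrounded by up to four shell layers in which
hemicellulose (xylan) and lignin polymers are laid down with random gaps.
Composition is specified as monomer-count fractions of glucose, xylose and a
representative monolignol.

Digestion is carried out by four strictly distinct enzyme classes:

* **EG (endoglucanase)** cuts any exposed internal cellulose bond, but never
  the two outermost bonds at either end of a polymer or fragment.  EG alone
  therefore never releases glucose or cellobiose, and cellotriose is the
  shortest fragment it can leave behind.
* **CBH (cellobiohydrolase)** attaches to exposed chain ends at a rate
  `k_CBH_attach` and processively cleaves cellobiose at `k_CBH = N_steps /
  t_CBH` (50 steps in 90 s, i.e. about 0.56 s⁻¹ or 2000 h⁻¹).  Residence
  times are drawn from a truncated normal around `t_CBH`; while attached, a
  steric exclusion zone of radius `2 * R_CBH` (8.5 nm) suppresses all other
  digestion reactions near the working position.
* **BGL (β-glucosidase)** cleaves free cellobiose into two glucose.  Glucan
  conversion counts free glucose only, so BGL is required to complete
  saccharification.
* **XYL (xylanase)** cuts any exposed xylan bond; single xylose monomers are
  released as soon as both of their bonds are gone.

Lignin is not digestible and acts twice.  *Structural blocking*: each lignin
polymer draws a covering fraction from Normal(μ, σ) truncated to [0, 1], and
that fraction of its monolignols permanently occludes the bonds beneath them;
the remaining monolignols are treated as branched material pointing away from
the fibril and never block.  *Adhesion*: a finite pool of monolignols
(initially all of them) irreversibly binds free enzymes at rate `k_bind` per
free enzyme, the victim class drawn in proportion to free abundances; every
binding consumes roughly `N_lignols_bound` monolignols, so low lignin
contents saturate quickly (a plateau) while high contents can bind the whole
cocktail and halt digestion.

Crystallinity splits every cellulose and hemicellulose chain into an easily
digestible amorphous part and a central, contiguous crystalline run covering
`round(frac * bonds)` bonds, whose digestion rates are multiplied by the
ratio `r_c,a = d_crystalline / d_amorphous` in [0, 1].  At 19% crystallinity
and 200 bonds this gives 38 central crystalline bonds with 81 amorphous bonds
on each side, which is why processive digestion from both ends stalls at
38-bond intermediates and one-ended digestion at 119-bond intermediates.

## Accessibility rules

A bond can only react if it is exposed: either some laterally neighbouring
lattice site is open medium (or its occupant monomers have been released, or
is non-covering lignin) at both of the bond's axial positions, or one of its
two along-chain neighbouring bonds has already been digested.  Covering
monolignols never release, so bonds beneath them are reachable only along
the chain.  Chain ends are *not* intrinsically exposed: a core chain whose
surroundings are intact cannot be attacked from the fibril end faces.  With
`structured = FALSE` every bond is treated as exposed from the start (freely
floating polymers); this is the reference scenario for asking what the
three-dimensional arrangement itself contributes.

## The simulation algorithm

All Markovian channels (EG cuts, XYL cuts, BGL cleavages, CBH attachments and
processive steps, lignin adhesion) are drawn with the Gillespie direct
method: exponential waiting times at the total propensity, channel selection
by a cumulative scan in fixed channel order.  CBH *detachments* are not
exponential — residence times are normally distributed — so each attachment
carries a scheduled deadline in a priority queue that preempts the direct
draw when earlier, a standard hybrid of the direct and next-reaction
methods.  Per-bond weights (accessibility × steric × crystallinity factor)
live in Fenwick trees, so events cost `O(log n)` plus a local accessibility
update; the steric zone of a stepping CBH is maintained by updating only the
axial slices that enter or leave the sphere.  All randomness flows from R's
RNG, so any run is bit-reproducible given its seed, and replicate seeds are
derived from a master seed by a fixed increment.

Runs stop at `t_end`, at `max_events`, or when no doable reaction or
scheduled event remains (substrate exhausted, or every enzyme bound to
lignin).  Conversions — `100 * free glucose / initial glucose` and the xylose
analogue — are recorded on a uniform grid that extends flat to `t_end` if the
run stops early, so replicates always share a common grid.  The optional DP
histogram records, per grid time, the glucose mass fraction residing in
cellulose polymers of each degree of polymerization (DP 1 = free glucose,
DP 2 = cellobiose); each row sums to one.

## Parameters and defaults

| parameter | default | unit | origin |
|---|---|---|---|
| `n_chains`, `dp_bonds` | 36, 200 | – | microfibril geometry |
| composition | 61.9 / 9.5 / 28.6 % | monomer fractions | medium pre-treatment severity |
| crystallinity fractions | 19% (cel), 23% (hemi) | – | medium severity calibration |
| `r_ca` | 0.03 (cel), 0.043 (hemi) | – | severity calibration |
| `N_steps`, `t_CBH` | 50, 90 s | – | single-molecule CBH measurements |
| `R_CBH` | 4.25 nm | nm | CBH hard-sphere radius |
| counts | 20 / 52 / 15 / 61 | enzymes | literature cocktail ratios at 5 µM |
| `k_EG`, `k_XYL` | 2e-3, 6e-3 | bond⁻¹ enzyme⁻¹ h⁻¹ | free parameter |
| `k_BGL` | 0.1 | cellobiose⁻¹ enzyme⁻¹ h⁻¹ | free parameter |
| `k_CBH_attach` | = `k_EG` | end⁻¹ enzyme⁻¹ h⁻¹ | free parameter |
| `k_bind` | 0.1 | free-enzyme⁻¹ h⁻¹ | free parameter |
| `N_lignols_bound` | 50 ± 5 | monolignols | binding footprint |
| covering μ, σ | 0.5, 0.1 | – | moderately branched lignin |

The per-bond digestion rates, the attachment rate and the adhesion rate are
genuinely free parameters of this class of model — they are exactly what the
fitting module optimizes against data.  The defaults were chosen once so
that the default substrate follows a realistic 72-hour course: glucan
conversion rises smoothly through ~75% at 24 h towards the low nineties at
72 h, xylan conversion somewhat lower, adhesion capacity-limited at the
default lignin content.  Time units are nominally hours, but since only rate
ratios shape the dynamics the axis can be read as arbitrary units; sweep
horizons (`t_end = 30`–`40` for lignin scans) are chosen so that the
adhesion/digestion competition is visible rather than saturated.

## Dosage bookkeeping

The dosage module converts batch conditions into enzyme counts: sub-unit
mass `m_SU = Σ N_k M_k / N_A` (≈ 3.4 × 10⁻¹⁸ g at the default composition),
sub-unit count `N_SU = m_substrate / m_SU`, prism volume `V_SU = d_SU² ·
(N_bonds + 1) · d_glc`, surrounding solvent volume `V_surrounding =
V_solution / N_SU − V_SU`, and `N_enzyme = c · V_surrounding · N_A`.  With a
4 g, 50 mL batch these formulas give `N_SU ≈ 1.16 × 10¹⁸`, `V_surrounding ≈
2.3 × 10⁻²³ m³` (a cube of ≈ 28 nm) and, at 5 µM, less than one enzyme per
sub-unit — an honest consequence of dividing so small a solvent share per
sub-unit.  The default simulated counts (20/52/15/61) are therefore not
derived from this chain; they are adopted directly from the literature
cocktail split of 148 enzymes (cellulase ratios 23/60/17%, cellulase:xylanase
59:41) and exposed as plain configuration.

## The synthetic-data generator

`generate_pseudo_experiment()` stands in for bench time-course data, which
is not machine-readable here: it simulates replicate-averaged conversion
curves for one or more severity presets under a known truth parameter
vector, samples them on a measurement grid and adds i.i.d. Gaussian noise
clipped to [0, 100], storing the truth alongside for recovery scoring.  It
emulates the *shape* and sampling of saccharification assays, not their
error structure: real assays have correlated, heteroscedastic errors,
systematic composition uncertainty and batch effects.  A passing recovery
test therefore shows that the fitting machinery can identify parameters of
the model from data the model itself could have produced — not that the
model is correct for any particular biomass.

## The fitting procedure

`run_fit()` is a generational hybrid of random and directed search.  Each
generation draws `n_subsets` candidate vectors coordinate-wise uniform in
`[p − Δ·p, p + Δ·p]` (clipped to bounds), evaluates each by
replicate-averaged forward simulation against every experimental curve
(per-curve RMSE at the measurement times, combined as an unweighted mean over
all glucose and xylose curves), and accepts the best candidate only if it
beats the incumbent.  After an acceptance the next window is centred one
step ahead along the accepted direction (`λ = 1`); if that directed
generation fails to improve, sampling reverts to undirected.  Candidates
within a generation share replicate seeds (common random numbers), which
removes simulator noise from the comparison — a deliberate implementation
choice.  The accepted-error sequence is non-increasing by construction and
the whole trace is reproducible from the master seed.

## Numerical choices and degenerate inputs

* Truncated normal draws (residence times, covering fractions) use
  redraw-until-in-range, which keeps the mean close to the nominal value for
  interior parameters.
* Monolignol consumption per binding is `min(pool, max(1, round(draw)))`; if
  the draw exceeds the pool, binding still happens and the pool empties.
* A fragment reduced to two monomers is lifted off as one cellobiose; a
  single leftover monomer is released as free glucose (no enzyme acts on
  DP 1 cellulose).
* At most one CBH works a given fragment at a time; both-end digestion
  arises across successive attachments.  The steric zone follows the working
  position and suppresses EG/XYL cuts only (attachment and the enzyme's own
  stepping are unaffected).
* Shell generation spends the hemicellulose/lignin monomer budgets exactly:
  stochastic run-length passes followed by a deterministic fill, so realized
  composition equals the rounded target.
* `replicate_rmse()` is `100·‖a−b‖₂/‖b‖₂` on the common grid.  A pointwise
  relative definition is dominated by the near-zero early grid points of any
  conversion curve (it reads several percent even for curves that agree
  closely everywhere); the global normalization coincides with the pointwise
  one for constant relative offsets and is the quantity reported by
  `scripts/acceptance.R`.
* Degenerate substrates (single chains, two-monomer chains, empty shells,
  zero crystallinity or covering) are first-class and covered by tests.

## Problem sizes used in the tests

The test suite runs the full default geometry (36 × 200) for the
replicate-convergence statistic and the DP-signature checks, and smaller
substrates elsewhere: 12–60-bond toys for the propensity-oracle and
conservation checks, 100-bond fibrils for the fitting recovery experiment
(6 subsets × 4 replicates × 8 generations), and 6–8 replicates per point for
the lignin and crystallinity sweeps.  These sizes are the package's chosen
defaults for its own regression suite; all of them rerun identically from
fixed seeds.

## Known limitations

* Enzymes are well-mixed; there is no spatial diffusion, crowding beyond the
  CBH steric zone, product inhibition or enzyme deactivation other than
  lignin adhesion.
* Lignin branching is abstracted to a covering fraction; monolignol species
  (S/G units) are not distinguished.
* Hemicellulose is a single xylan backbone; side groups and xylanase
  sub-types are out of scope.
* Fragments produced by internal cuts stay in place until their monomers are
  released; solubilization of longer oligomers is not modelled.
* The cross-section is a rectangular lattice approximation of the
  quasi-hexagonal bundle; alternative allomorph shapes are only reachable
  through the configurable chain count.
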