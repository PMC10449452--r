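---
title: "Methods: multiscale modeling of EMT-PD-L1 crosstalk under immunosuppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale modeling of EMT-PD-L1 crosstalk under immunosuppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The regulatory network

The package models a tumor cell's coupled EMT and PD-L1 state with a
deterministic ODE network in three layers.

**EMT core (ternary switch).** miR-200 (`u`), ZEB1 mRNA (`mz`) and ZEB1
protein (`z`) form a mutually inhibitory circuit driven by SNAIL1:
SNAIL1 and ZEB1 repress miR-200 transcription (shifted Hill functions
with fold changes 0.1 at thresholds 1.8e5 and 2.2e5 molecules), while
SNAIL1 and ZEB1 activate ZEB1 transcription (fold changes 10 and 7.5 at
thresholds 1.8e5 and 2.5e4 molecules). miR-200 silences ZEB1 mRNA
post-transcriptionally through up to six binding sites: complexes with
`i` bound miRNAs occur with binomial weights, reduce translation by a
ladder of factors (1, 0.6, 0.3, 0.1, 0.05, 0.05, 0.05), and degrade both
the mRNA and the bound miRNAs. This architecture yields the well-known
tristability between an epithelial state (high miR-200, ZEB1 mRNA below
~150 molecules), a hybrid E/M state (intermediate, ~250-600 molecules)
and a mesenchymal state (low miR-200, ~800-1000 molecules). ZEB1 mRNA is
the phenotype readout throughout: hysteretic transitions use the
thresholds 235 (E to H), 145 (H back to E), 715 (H to M) and 370 (M back
to E) molecules, with no direct M-to-H transition.

**PD-L1 arm.** IFN-gamma (nM) activates a JAK-STAT intermediate `st`
(dimensionless, relaxing at 1/h to a shifted-Hill steady state with
fold change 15, threshold 0.15 nM, coefficient 2), which drives PD-L1
transcription (fold change 25, threshold 5, coefficient 4 - the quartic
coefficient keeps basal PD-L1 low without IFN-gamma). PD-L1 mRNA carries
two miR-200 binding sites with a steeper repression ladder (1, 0.3,
0.05), so mesenchymal (miR-200-low) cells translate PD-L1 several-fold
more efficiently than epithelial cells. Protein passes through a
cytoplasmic pool to the membrane pool `pm` (membrane PD-L1, the
observable). Membrane PD-L1 in turn represses miR-200 production (fold
change 0.7, threshold 4e4 molecules, coefficient 2), closing the mutual
miR-200/PD-L1 inhibition that lets IFN-gamma promote EMT. These
parameters are the package's own calibration of the arm: they were fixed
once against four qualitative/quantitative anchors - tristability with
membrane PD-L1 ordered E < E/M < M at SNAIL1 = 1.95e5 molecules and a
basal IFN-gamma production rate of 0.1 nM/h; a near-saturated PD-L1
response above ~0.3 nM/h; a leftward shift of the EMT folds with
increasing IFN-gamma production; and negligible feedback at zero
IFN-gamma - and are not revisited by any test.

**TGF-beta-SNAIL1 submodel.** TGF-beta (nM) is produced at a constant
rate `gt` (0-0.3 nM/h) and degraded at 1/h, so its steady state equals
`gt` numerically. SNAIL1 mRNA has a basal production of 1500 molecules/h
plus a TGF-beta-activated, SNAIL1-self-inhibited term of up to
600 molecules/h (activation threshold 0.1 nM with coefficient 2;
self-inhibition threshold 3.5e5 molecules with coefficient 2), and decays
at 0.09/h; SNAIL1 protein follows at 17/h production per mRNA and 1.66/h
decay. The two Hill thresholds are package choices calibrated so that
steady-state SNAIL1 sweeps ~1.7e5-2.15e5 molecules as TGF-beta spans its
range, placing the EMT folds inside the studied TGF-beta window.

**Immunosuppression.** The basal IFN-gamma production `gi` is multiplied
by a shifted-Hill inhibition by membrane PD-L1 (fold change 0.1,
coefficient 2, threshold 2e4 molecules), by TGF-beta (fold change 0.1,
coefficient 2, threshold 0.15 nM), by both (their product; `combined`
mode), or by neither. The thresholds follow the half-functional rule:
they sit mid-scale of the regulator's dynamic range so the link is
roughly equally likely to be engaged or not.

Units: molecule counts for all species except the cytokines (nM) and the
STAT intermediate (model units); 1 nM corresponds to ~6020 molecules at
the 10000 um^3 cell volume, and `nm_to_molecules()` /
`molecules_to_nm()` convert at interaction boundaries.

# Steady states and bifurcation structure

`find_equilibria()` locates steady states by stiff integration
(`deSolve::lsoda`, absolute tolerance 1e-8, relative 1e-6 - tristable
systems are tolerance-sensitive near saddle-nodes) from canonical
E/hybrid/M basin starts plus log-uniform random starts, refines endpoints
by damped Newton with a finite-difference Jacobian (step
`1e-6 * (1 + |x|)`), de-duplicates in log1p space at relative tolerance
1e-4 (species span decades), and flags stability by the Jacobian
spectrum. Saddles between adjacent stable states are sought from
log-interpolated midpoints; forward integration alone would never find
them.

`sweep_branches()` uses natural (warm-started) continuation over a
parameter grid with a fresh multi-start every 10th point, matches
branches by nearest neighbors in log1p state space, and reports each
saddle-node fold as the midpoint of the bracketing grid interval with
the half-width as uncertainty. Grid-sweep bracketing was chosen over
pseudo-arclength continuation because every property asserted about the
diagrams (fold counts, fold orderings, within-branch monotonicity) is a
statement at grid resolution; unstable-branch geometry is located for
plotting parity but not exploited quantitatively.

# The cellular Potts layer

Cells live on a 2 um lattice; one Monte Carlo step (MCS) is 0.6 s and
performs one copy attempt per lattice site between randomly chosen
8-neighborhoods. The Hamiltonian is the standard sum of heterotypic
surface energies (Table of `cpm_parameters()`: tumor-tumor 2-14,
tumor-T cell 0.5, E-medium 3, H/M-medium 1, T cell-medium 15 or 2),
quadratic area constraints (weight 1; targets 452 um^2 tumor, 140 um^2
T cell) and quadratic perimeter constraints (weights 0.25/0.2/0.15/0.1
for E/H/M/T). T cells move actively via the Act model: newly gained
sites carry activity MaxAct = 20 that decays by 1 per MCS, and a copy
from site u into v is biased by `-20/20 * (GM(u) - GM(v))` where GM is
the geometric mean activity over the second-order Moore neighborhood
restricted to same-cell sites. A local connectivity test (the T cell's
sites around the lost site must form a single arc) prevents T cell
fragmentation, and no copy may annihilate a cell.

Two geometric conventions deserve note. First, the target perimeter uses
the circle-perimeter-at-target-area reading `2*sqrt(pi*A)`; since the
engine counts perimeter as heterotypic interfaces in the 8-neighborhood,
the um value is converted with a calibration factor of 3.1 interfaces
per site-length of true circumference, measured on rasterized disks at
this resolution. Second, the Metropolis temperature is not a published
quantity; it was calibrated once so that T cells among tumor cells move
at ~7 um/min with the amoeboid Act parameters, giving the default of 15.
Migration speed is measured as centroid displacement per 0.5-min
sampling interval (expressed in um/min): the protrusion persistence time
is only MaxAct x 0.6 s = 12 s, so sampling much coarser than that (e.g.
1 min) measures the diffusive rather than the instantaneous motion and
yields systematically lower values (~5 um/min at the same parameters).

# Cytokine fields

IFN-gamma is a dynamic field in molecules per lattice site, advanced by
forward-time central-space diffusion (D = 5430 um^2/min) with automatic
sub-stepping to a fraction of the stability bound `h^2/(4D)`, no-flux
boundaries, exponential (positivity-preserving) per-site first-order
uptake, and continuous T cell sources (1200 molecules/min spread over
the cell's sites). Uptake rates attach to the occupant type: 2100/min
(tumor) and 420/min (medium) in the short-range spreading scenario,
0.021/min and 0.0042/min in the long-range scenario; T cells consume
nothing. In coupled simulations the field may be coarsened by an integer
factor (default 2) to keep the sub-step count manageable; secretion,
uptake and sensing are conserved under the coarsening.

The short-range parameter set has a continuum decay length
`sqrt(D/k)` = 1.6 um - smaller than one lattice site - so its
steady-state profile around a secreting T cell collapses within a
fraction of a cell layer, and the discrete per-site decay (factor ~3.2
per 2 um) governs the profile; the per-cell-layer fold under this
parameter set is astronomically large rather than moderate. The
long-range set decays over 508 um, which is macroscopic: any closed
lattice domain of feasible size either accumulates a flat background
(no-flux) or is shaped by the artificial outer boundary (absorbing), so
the package provides `radial_continuum_profile()`, a radially symmetric
finite-volume solution with the far boundary placed at four decay
lengths, for decay-profile measurements; the 2-D lattice solver
(`steady_state_ifng()`) remains the reference for simulation-scale
geometries and mass-balance checks. Under the long-range parameters the
layer-averaged concentration falls e-fold across about six cell layers
(geometric spreading plus weak exponential decay), which the acceptance
suite verifies.

TGF-beta is a static field in nM: uniform, or - for invasive-front
scenarios - peaked at the front edge and decreasing linearly into the
tumor (the simplest monotone realization; the shape is replaceable via
`make_tgfb_field()`). Sensing maps molecules/site to nM using a
documented slab thickness of 10 um (site volume 40 um^3, so 1 nM ~ 24.1
molecules/site), chosen so that sensed concentrations fall in the ODE
layer's responsive range.

# Multiscale coupling

Fields and Potts dynamics advance per MCS; each tumor cell's regulatory
state advances per MCS by 1800 x 0.6 s = 18 min of ODE time (fixed-step
RK4 at 0.015 h, comfortably inside the stability region since the
fastest network rate is ~17/h). Sensed IFN-gamma and TGF-beta enter the
per-cell ODEs as clamped inputs - the field layer owns the conserved
cytokine pool, so the cell's own cytokine equations are replaced by the
sensed values and no molecule is double-counted. T cell production is
recomputed every MCS (instant relaxation): under PD-L1-mediated
inhibition it is scaled by the shifted Hill evaluated at the
boundary-length-weighted mean membrane PD-L1 of contacting tumor cells
(a symmetric, stable summary of "neighboring" contact); under
TGF-beta-mediated inhibition, at the T cell's sensed TGF-beta.
Phenotypes are re-classified hysteretically at each output interval, at
most one transition per interval, and a switch immediately swaps the
cell's surface-energy row, perimeter weight and target perimeter.

Scenario initialization rasterizes a circular tumor (spiral seeding,
nearest-seed partition) or an invasive-front slab, stamps T cell disks
at a 1:40 T cell:tumor ratio (12 T cells among 480 tumor cells at full
scale, 5 among 200 for the front), and freezes T cells - motion and
secretion - for the first 10 min so tumor regulatory states settle into
the zero-IFN-gamma attractor (300 ODE hours at the acceleration factor).

# What the scenario generator emulates, and what it does not

The long-range scenario default couples a uniform 0.05 nM TGF-beta field
with the long-range uptake set. At that level the homogeneous epithelial
state remains stable at every IFN-gamma concentration the infiltrated
tumor reaches, while cells whose ZEB1/miR-200 production rates sit in
the upper tail of the heterogeneity distribution lose the epithelial
attractor once IFN-gamma floods the tumor - reproducing the regime in
which only a tumor subpopulation undergoes IFN-gamma-induced partial
EMT, and none of it reaches the mesenchymal state. Intratumoral
heterogeneity is log-normal multiplicative noise on the miR-200 and ZEB1
mRNA production rates; its width (sigma = 0.014) was chosen as a
round value that passes the no-spontaneous-EMT dry run with margin and
places the converting minority at roughly a tenth of the population,
and `apply_heterogeneity()` halves it automatically (with a warning) if
a drawn cohort ever violates the constraint. The constraint check
relaxes each cell's single-cell ODE at zero IFN-gamma rather than
re-running the spatial model: phenotype transitions are a property of
the regulatory layer alone.

Desk-scale experiments (the test suite and the worked examples) shrink
the geometry to 40-60 tumor cells in 200-240 um domains over 200-400
simulated minutes with three seeds per condition; these sizes preserve
the tumor area fraction and approximate T cell density of the full
geometry, which set the flooded IFN-gamma level. Contact-dependent
suppression, bystander shielding under PD-L1-mediated inhibition, the
size of the IFN-gamma-responsive minority, and hybrid escape all
manifest at this scale with the correct signs. One effect is attenuated to its sign alone: without
IFN-gamma inhibition, heterogeneous tumors expose their epithelial
cells slightly *more* because escaping hybrid cells leave them
concentrated near an IFN-gamma-rich tumor center - a spatial gradient
that only becomes substantial when the domain is comparable to the
508 um long-range decay length. In a 200-240 um closed domain the field
equilibrates to within half a percent, so the desk-scale reversal is a
fraction-of-a-percent effect verified for its sign under fixed seeds,
not for its magnitude. Paper-scale effect sizes require the full
480-cell, 2410-min, five-replicate configuration.

The simulations deliberately omit tumor growth and death, T
cell-mediated killing, cytostatic IFN-gamma effects, additional
IFN-gamma sources, dynamic TGF-beta secretion, and three-dimensional
lattices. Real tumors also violate two simplifications knowingly made
here: regulatory dynamics are accelerated 1800-fold relative to
cellular motion (so PD-L1 responds in seconds of simulated time rather
than hours), and T cells neither exhaust durably nor consume IFN-gamma.

# Numerical choices and degenerate inputs

Stiff integration tolerances (1e-8/1e-6) and the Newton residual
tolerance (1e-9 scaled) were set once; equilibrium de-duplication and
branch matching operate in log1p space. Zero regulator levels are valid
inputs everywhere (shifted Hills evaluate to 1); negative levels,
non-positive thresholds or volumes, and unknown inhibition modes raise
errors naming the offending quantity, and a parameter file missing a
symbol fails at validation rather than defaulting silently. The FTCS
sub-step uses a 0.5 safety factor on the stability bound within coupled
runs and 0.2 in the standalone stepper; uptake is applied as an exact
exponential per sub-step, so concentrations cannot go negative. Potts
copies that would annihilate a cell or disconnect a T cell are rejected
before energy evaluation; frozen cells reject all copies touching them.

# Known limitations

The regulatory parameterization of the PD-L1 arm is a calibrated
reconstruction (anchored to the published steady-state structure), not
a transcription of a reference parameter table, so absolute molecule
counts for the PD-L1 species should be read comparatively, not as
measurements. The short-range uptake parameter set is internally
inconsistent with a moderate per-layer decay under any first-order
continuum reading (decay length below one lattice site); the package
reports what the stated rates actually produce. Fold locations inherit
grid resolution as their uncertainty, and the local connectivity test is
conservative (it can reject a copy that a global test would allow).
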