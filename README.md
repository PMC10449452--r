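# emtpdl1

Multiscale modeling of the crosstalk between epithelial–mesenchymal
transition (EMT) and IFNγ-induced PD-L1 expression in tumors, under
tumor-mediated immunosuppression.

Tumor cells evade immune attack along two coupled routes: they undergo
EMT — driven by the miR-200 / ZEB1 double-negative feedback circuit
under SNAIL1/TGFβ input — and they up-regulate the immune checkpoint
ligand PD-L1 in response to T cell-derived IFNγ. The two programs talk
to each other (miR-200 silences PD-L1 mRNA; PD-L1 feeds back on
miR-200), and the tumor suppresses the IFNγ supply itself, either
through PD-L1–PD-1 engagement of T cells or through TGFβ. This package
is for computational biologists who want to dissect that crosstalk
quantitatively: it provides the regulatory ODE network and its
bifurcation analysis, and embeds the network in spatial cellular Potts
simulations of T cell-infiltrated tumors with explicit cytokine fields.

## The model in brief

Every regulation is a shifted Hill function
`H^S(B) = H^-(B) + λ H^+(B)` with `H^-(B) = 1 / (1 + (B/B0)^n)`, so the
production rate of the target is scaled by a factor that moves from 1
(no regulator) to the fold change λ (λ < 1 inhibition, λ > 1
activation). The network couples:

- the miR-200 (`u`) / ZEB1 (`mz`, `z`) ternary switch with SNAIL1
  input, including binomially weighted miRNA–mRNA complex silencing and
  degradation — this yields tristability between epithelial (E), hybrid
  (E/M) and mesenchymal (M) states, read out on ZEB1 mRNA;
- an IFNγ → JAK-STAT → PD-L1 arm with membrane PD-L1 (`pm`) as the
  observable, silenced by miR-200 and feeding back on it;
- a TGFβ → SNAIL1 submodel (`dT/dt = g_T − k_T T`,
  `dm_S/dt = g0_mS + g_mS H^+(T) H^-(S) − k_mS m_S`,
  `dS/dt = g_S m_S − k_S S`);
- immunosuppression of the IFNγ source:
  `dI/dt = g_I · H^S(PM, λ_PM,I) · H^S(T, λ_T,I) − k_I I`, with either,
  both, or neither inhibition factor active (modes `pdl1`, `tgfb`,
  `combined`, `none`).

The spatial layer is a 2-D cellular Potts model (2 µm lattice, 0.6 s
per Monte Carlo step) with adhesion, area and perimeter constraints,
Act-model amoeboid T cell migration with a connectivity constraint, a
reaction–diffusion IFNγ field (D = 5430 µm²/min, cell-type-dependent
uptake, T cell secretion at 1200 molecules/min), a static uniform or
edge-peaked TGFβ field, and per-cell regulatory ODEs accelerated
1800-fold relative to the cellular dynamics. Hysteretic ZEB1-mRNA
thresholds (235/145, 715/370 molecules) switch cell phenotypes and
their Potts parameters on the fly.

## Worked example

Steady states at a fixed SNAIL1 level of 1.95e5 molecules and a basal
IFNγ production rate of 0.1 nM/h, without immunosuppression:

```r
library(emtpdl1)
p  <- regulatory_parameters("none", gi = 0.1)
eq <- find_equilibria(p, snail_fixed = 1.95e5, seed = 1)
eq[eq$stable, c("mz", "pm", "phenotype")]
#>          mz       pm phenotype
#> 1  85.55706 11346.76         E
#> 3 362.14567 16758.06       E/M
#> 5 846.76273 41490.22         M
```

Three stable states coexist — epithelial, hybrid and mesenchymal at
ZEB1 mRNA ≈ 86, 362 and 847 molecules — and membrane PD-L1 is ordered
E < E/M < M (≈ 1.1e4, 1.7e4 and 4.1e4 molecules): mesenchymal cells
carry the most PD-L1 because low miR-200 de-represses its translation.
Re-running with `regulatory_parameters("pdl1", gi = 0.1)` lowers PD-L1
in every phenotype without creating or destroying equilibria.

A bifurcation sweep over TGFβ, and a reduced-scale spatial run:

```r
br <- sweep_branches(regulatory_parameters("tgfb", gi = 0.11),
                     "tgfb", c(0, 0.3), n_points = 25)
fold_locations(br)      # bracketed saddle-node positions

sc  <- scenario("long_range", n_tumor = 40, domain_um = 200,
                duration_min = 250, inhibition = "pdl1",
                heterogeneous = TRUE)
run <- run_simulation(sc, seed = 1)
hybrid_fraction(run, c(150, 250))   # ~0.1: the IFNγ-responsive minority
```

Command-line wrappers for simulation, bifurcation tables and run
summaries live in `inst/cli/`.

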