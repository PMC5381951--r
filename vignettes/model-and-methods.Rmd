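---
title: "A coarse-grained model of Sec-facilitated membrane protein integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of Sec-facilitated membrane protein integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seccg)
```

## The problem

Most integral membrane proteins are inserted into the membrane
co-translationally: the ribosome docks onto the Sec translocon and feeds the
nascent polypeptide chain (NC) into the channel, where each segment either
passes through to the far (lumenal) side or partitions laterally through the
translocon's lateral gate into the lipid bilayer. Whether a given segment
integrates, and with which orientation, depends on its hydrophobicity and
charge, but also on kinetics: translation takes seconds to minutes while
chain conformations relax in nanoseconds. `seccg` implements a
three-dimensional coarse-grained (CG) model that spans this range of
timescales: beads of three residues each, an implicit membrane, a fixed
two-conformation translocon with stochastic lateral-gate switching, explicit
ribosomal elongation, and overdamped Langevin dynamics for the chain.

## Units and bead mapping

The length unit is the bead diameter $\sigma = 0.8$ nm (the Kuhn length of a
polypeptide chain) and the energy unit is $\epsilon = k_BT$ at $T = 310$ K
(0.616 kcal/mol); times are in seconds. Every group of three consecutive
residues maps to one bead (`map_sequence()`). A bead carries

* a water-membrane transfer free energy $g_i$: the sum of its residues'
  water-to-octanol transfer free energies (Wimley-White pentapeptide scale),
  plus 1.78 $\epsilon$ for every residue whose backbone is not
  hydrogen-bonded (coil), the cost of burying a free peptide bond;
* a charge $q_i$: the formal-charge sum (R, K: +1; D, E: −1; histidine
  neutral), with an extra +1/−1 and +6 $\epsilon$ on the N-/C-terminal beads
  for the charged termini;
* two channel-interaction coefficients $\lambda^o(g_i), \lambda^c(g_i) \in
  [0,1]$ interpolated piecewise-linearly between four anchor substrates
  (LLL: $g=-6.1\epsilon$, $\lambda = 1$; QQQ helix: $3.8\epsilon$; QQQ coil:
  $9.1\epsilon$; DDD: $23.1\epsilon$, $\lambda = 0$) and clamped outside
  that range, since the LLL and DDD interactions bound the possible channel
  interactions.

Because the 3:1 grouping admits three frames, every assay is run for all
three frameshifts and reports their mean: no frame is privileged
(`enumerate_frameshifts()`). Partial triplets at a frame-shifted terminus
form a short terminal bead rather than being dropped, so chain length and
total charge are conserved.

The two QQQ anchor $\lambda$ values are only determined up to a fit against
reference translocation free-energy profiles; the defaults (open 0.60/0.35,
closed 0.55/0.30 for helix/coil) were fixed once and are exposed as
configuration in `lambda_anchors()`. `fit_lambda()` re-derives such values
from any reference profile.

## Potential energy

The total potential (`total_energy()`) is a sum of six terms, all in
$\epsilon$:

1. **FENE bonds** between consecutive beads,
   $-\tfrac12 K_0R_0^2\ln(1-r^2/R_0^2)$ with $K_0 = 5.833\,\epsilon/\sigma^2$,
   $R_0 = 2\sigma$.
2. **Excluded volume**: purely repulsive (WCA) Lennard-Jones between all NC
   bead pairs, cut at $2^{1/6}\sigma$.
3. **Debye-Hückel electrostatics** between all charged pairs involving the
   NC, $l_Bq_iq_je^{-r/\kappa}/r$ with $l_B = \kappa = \sigma$
   (physiological screening). A $6\sigma$ cutoff (screened factor
   $e^{-6}$) is applied for speed and is configurable; tests verify
   insensitivity against the uncut sum.
4. **Solvation** $g_iS_{mem}(x_i)$, where
   $S_{mem} = [1-S(x,y)]\,S(z)$ is a smooth product of tanh switches that
   equals 1 inside the membrane slab (half-width $2\sigma$) but outside the
   channel cylinder (radius $1.5\sigma$), with switching width $0.25\sigma$.
5. **Channel interactions**: for each NC bead,
   $[1-S_{mem}]\sum_j[\lambda U_{LLL} + (1-\lambda)U_{DDD}](r_{ij}) +
   S_{mem}\sum_j U_{out}(r_{ij})$, where the sums run over translocon beads,
   $\lambda$ is $\lambda^o$ or $\lambda^c$ according to the gate state, and
   each channel bead's class (`normal` or `confined`) selects its parameter
   row. All rows use a soft-core Lennard-Jones form
   $4\epsilon_{int}[(\alpha + (r/\sigma_j)^6)^{-2} -
   (\alpha + (r/\sigma_j)^6)^{-1}] - \epsilon_{cr}$, finite at contact.
6. **Ribosome terms**: a capped soft-core repulsion from each explicit
   ribosome bead ($\epsilon_{int} = \epsilon$, $\sigma_j = 1.2\sigma$) and a
   repulsive sphere centred at $(-10, -0.5, 1)\sigma$ standing in for the
   ribosome body not represented by beads.

Interactions among fixed beads (channel-channel, ribosome-ribosome,
channel-ribosome) are excluded: their conformation-dependent self-energy is
absorbed into the empty-channel opening penalty, so that with no substrate
the gate statistics reduce exactly to $\Delta G_{empty}$.

The soft-core shape parameter $\alpha$ is not free: it is the root of
$4\epsilon_{int}(1/\alpha^2 - 1/\alpha) = 100\,\epsilon$, capping the
potential at zero separation at 100 $\epsilon$ so that instantaneous gate
switches can never generate infinite energies. This rule reproduces the
published $\alpha$ of all nine interaction rows to ±0.001
(`alpha_from_cap()`), which is why it is implemented as the defining
relation; the closed form is a quadratic in $1/\alpha$. Likewise
$\epsilon_{cr}$ is the unshifted value at the cutoff
(`eps_cr_from_params()`), and the purely repulsive confined rows cut off at
the potential minimum $(2-\alpha)^{1/6}\sigma_j$ — whence their printed
cutoffs 1.075 and 1.110 and shifts equal to $-\epsilon_{int}$. The cutoff
radii are interpreted in units of $\sigma_j$, which is what makes those
relations exact.

## Dynamics

NC beads evolve by overdamped Langevin dynamics with a first-order Euler
integrator: $x \leftarrow x - \beta D\nabla U\,\Delta t +
\sqrt{2D\Delta t}\,R$, with $D = 253$ nm²/s and $\Delta t = 300$ ns.
Each timestep iterates five operations in order: forces, Langevin move,
a lateral-gate attempt, ribosomal translation, and the termination check.

**Gating.** The translocon switches between fixed closed and open bead
configurations with Glauber-form probabilities per attempt (one attempt per
step, scaled by $\Delta t/\tau_{LG}$ with $\tau_{LG} = 500$ ns):
$p_{open} \propto e^{-\beta\Delta G}/(1+e^{-\beta\Delta G})$ and
$p_{close} \propto 1/(1+e^{-\beta\Delta G})$, where
$\Delta G = \Delta G_{empty} + U(\text{open}) - U(\text{closed})$ and
$\Delta G_{empty} = 3\,\epsilon$. The ratio is exactly
$e^{-\beta\Delta G}$, so the gate obeys detailed balance; with frozen
positions its stationary open fraction is $1/(1+e^{\beta\Delta G})$, which
the test suite verifies empirically ($1/(1+e^3) \approx 0.0474$ for the
empty channel). The energy difference is evaluated at the configuration
produced by the Langevin move of the same step.

**Translation.** The C-terminal bead is held fixed and advanced along $+z$
by $\sigma\Delta t/t_{trans}$ per step; after $t_{trans}$ it is released
and the next bead appears at the insertion point. The default
$t_{trans} = 0.6$ s encodes 5 residues/s at 3 residues per bead. The fixed
bead still interacts with all other beads.

## Numerical choices

* **Tabulated channel fields.** For ensemble runs the three channel
  soft-core sums (attractive bound, repulsive bound, exterior) are
  precomputed for both gate conformations on a $0.1\sigma$ Cartesian grid
  and interpolated trilinearly (`build_field_grid()`); electrostatics, the
  ribosome terms and all chain terms stay exact. Exact pairwise evaluation
  remains the default and is what `total_energy()` reports; a test compares
  both routes.
* **Drift cap.** The deterministic displacement per step is capped at
  $0.25\sigma$; the steep excluded-volume wall can otherwise catapult a
  freshly placed bead that transiently overlaps the chain. The cap only
  engages at forces far beyond thermal scales.
* **Bond guard.** If a proposed move would stretch a FENE bond to $R_0$
  (where the potential diverges), the noise for that step is redrawn; the
  event counter is reported and is zero in nominal runs.
* **Random numbers.** Each trajectory uses its own mt19937_64 stream with
  exact Box-Muller normals, drawn in fixed coordinate order, so a seed
  reproduces a trajectory bit-for-bit on any platform.
* **PMF quadrature.** Single-bead translocation potentials of mean force
  integrate $e^{-\beta U_1}$ over a cylinder cross-section of radius
  $1.5\sigma$ (the restraint radius of the reference calculations) on a
  uniform grid, default spacing $0.025\sigma$; halving the spacing twice
  changes the profile by under $10^{-3}\,\epsilon$. Profiles are shifted so
  their mean over $4.0\sigma \le z \le 4.5\sigma$ is zero; only free-energy
  differences are meaningful.
* **Fitting.** $\lambda$ fits are bounded one-dimensional least squares
  over $z \ge -2\sigma$ with the vertical offset profiled out; soft-core
  parameter fits are bounded quasi-Newton searches over
  $(\epsilon_{int}, r_{cr}, \sigma_j)$ from multiple starts, with $\alpha$
  and $\epsilon_{cr}$ tied to their defining relations throughout.

## The synthetic scaffold

`synthetic_channel_fixture()` builds a self-contained stand-in geometry so
that nothing external is required: an hourglass of channel-bead rings
spanning the membrane slab with a four-bead constriction ring (class
`confined`) whose +y-facing seam pair swings aside in the open
conformation; lateral-gate columns in the outer rings that open toward +y;
and a ribosome represented by an exit-tunnel collar, a tunnel plug, a
partial shield and a bead roof that together funnel the emerging chain into
the vestibule between ribosome and channel while leaving a window for
cytosolic loops. A handful of charged beads exercise the electrostics.

What the scaffold reproduces: the membrane/channel partitioning geometry,
graded translocation barriers that increase from LLL to DDD in both gate
states, a lateral path from pore to membrane that exists only on the gate
side, and co-translational arrival of beads at the channel mouth. What it
does not reproduce: the real translocon's size (about 150 beads versus 36
here), its asymmetric charge distribution, and the full gating
thermodynamics — with so few confined beads the hydrophobicity dependence
of gate opening is weak, and the selectivity of the scaled-down assays is
carried mainly by the implicit-membrane solvation term rather than by
gate-state energetics. Trend-level results on this scaffold therefore
demonstrate that the machinery works end to end, not that the scaffold is a
quantitative surrogate for the experimentally derived geometry, which can
be supplied as a TSV (`read_geometry()`) or built from coordinates
(`map_protein_to_beads()`, `map_rna_to_beads()`, `align_and_center()`).

## Assays

The integration assay (`integration_probability()`) reconstructs the
stop-transfer intermediate: an upstream TMD pre-inserted in the membrane
with its C-terminal end lumenal, the downstream linker threaded through the
channel, and the 19-residue H-segment (0-7 leucines, remainder alanine)
translated during the run. A trajectory terminates as *integration* when
every H-segment bead is at least $2\sigma$ from every channel bead, lies
within the membrane slab, and the flanking beads sit on opposite sides of
the midplane; as *translocation* when the whole H-segment has crossed to
the lumenal side. The integration probability is the fraction of
trajectories ending in integration, averaged over the three frames, and
converts to an apparent free energy via
$\Delta G_{app} = -kT\ln[p/(1-p)]$ (`dg_app()`), with the alanine/leucine
decomposition via the linear fit in leucine count (`fit_ala_leu()`) and
single-residue values via reference substitution (`dg_app_residue()`).

The topogenesis assay (`topology_curve()`) translates a signal-anchor
construct from an initial state with four beads outside the channel and
classifies the final orientation when the TMD spans the membrane at least
$10\sigma$ from the channel: Type 2 if the C-terminal bead is lumenal,
Type 1 if cytosolic.

Because a single trajectory at the physiological translation rate spans
tens of seconds of simulated time, the packaged tests run both assays at a
hundredfold reduced per-bead translation time (6 ms), with ensembles of
20 (integration) or 12 (topology) trajectories per frame and simulated-time
guards of 0.25 s and 0.5 s; trajectories that outlive the guard are counted
separately as undecided. These sizes are the package's choice for a
single-CPU run and are stated in the tests; larger ensembles simply shrink
the binomial errors. Under these conditions the hydrophobicity trend of
H-segment integration is reproducible, while the topology trends sit at
the edge of statistical resolution — the vignette section above explains
why the scaffold's gating thermodynamics make orientation kinetics weakly
resolved at this scale.

## Limitations

* The bead mapping fixes three residues per bead; per-residue resolution
  of, e.g., charge placement within a triplet is lost.
* Secondary structure is an input (H/C per residue), not predicted, and
  enters only through the peptide-bond transfer penalty.
* Translation is uniform; heterogeneous codon-dependent rates are not
  modelled.
* The membrane is implicit and laterally homogeneous; there are no lipid
  particles, no bilayer deformation, and membrane insertion from the
  aqueous phase has no kinetic barrier beyond the solvation ramp.
* The gate has exactly two conformations with instantaneous switching.
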