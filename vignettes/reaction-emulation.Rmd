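---
title: "Emulating biomolecular reaction cascades with kinetic Monte Carlo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating biomolecular reaction cascades with kinetic Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmcreact)
```

## The model

Classical molecular mechanics force fields cannot break or form bonds, yet
many biochemical processes of interest -- radical migration cascades,
force-driven backbone scission, photodimerization -- are exactly such bond
rewiring events, often on timescales of seconds that no reactive
simulation method can reach directly. `kmcreact` emulates these reactions
instead of simulating them. The system lives in a discrete chemical state
(a molecular topology: atoms, bonds, angles, dihedrals, 1-4 pairs).
Each cycle:

1. **Sample** a conformational ensemble of the current state with a
   stochastic-dynamics sampler.
2. **Predict** a rate for every candidate reaction, using a pluggable
   model (table-driven surrogate, physical law, or heuristic) evaluated
   over the ensemble.
3. **Choose** one reaction by rejection-free kinetic Monte Carlo (rf-kMC):
   event $i$ is selected with probability $p_i = k_i / R$,
   $R = \sum_j k_j$, via a uniform draw $u_1 \in (0, 1]$ and the
   cumulative rule $F(p_{i-1}) < u_1 \le F(p_i)$; simulated time advances
   by $\Delta t = -\ln(u_2) / R$.
4. **Effect** the reaction by applying its recipe -- an ordered list of
   elementary `Break`, `Bind`, `Place` and `Relax` steps -- to the
   topology and coordinates, then equilibrate the product briefly before
   the next cycle.

The cycle is Markovian: each transition depends only on the current
(topology, coordinates) state and the random stream. The event list of a
state is built only when the state is actually visited (the adaptive
variant of rf-kMC), which is what makes cascades through a combinatorially
vast chemical state space tractable.

### Rates from barriers: ensemble averaging

For hydrogen atom transfer (HAT) the rate of a candidate reaction is
obtained per frame from a barrier $\Delta G^{\ddagger}$ through the Eyring
equation

$$k = \frac{k_B T}{h} \exp\!\left(-\frac{\Delta G^{\ddagger}}{k_B T}\right),$$

and the event rate is the **arithmetic mean of the per-frame rates**, not
the rate of the mean barrier. The distinction matters: by Jensen's
inequality the mean rate is dominated by the rare, low-barrier
conformations, so ensemble averaging is what lets the emulator account
for how often reactive geometries are actually visited. Units are fixed
package-wide: kcal/mol for energies, Angstrom for lengths, seconds for
inverse rates, with $k_B = 0.0019872$ kcal mol$^{-1}$ K$^{-1}$ and
$h = 9.5306 \times 10^{-14}$ kcal s mol$^{-1}$, so $k_B T / h \approx
6.26 \times 10^{12}$ s$^{-1}$ at 300 K. Temperature is always a parameter
(`constants(T = )`), never hard-coded.

### The surrogate barrier predictor

A production-scale emulator would predict HAT barriers from reactant
structures with a learned model (for example a graph neural network
trained on quantum-chemical barriers). Training and weights of such a
model are out of scope here; what the package provides is the
*interface*: any pure function `(topology, h, acceptor, frame, table) ->
barrier` can be plugged into the HAT plugin. The shipped default is a
table keyed by the hydrogen shift class with a linear distance penalty:

$$\Delta G^{\ddagger} = B[\text{shift}] + s \cdot \max(0, d_{HA} - 1.1\,\text{Å}),$$

where $d_{HA}$ is the hydrogen-acceptor distance in the frame. The
default table encodes the ring-strain ordering known for intramolecular
hydrogen shifts: 1-2 and 1-3 transfers (three- and four-membered cyclic
transition states) are the most strained and slowest, the 1-5 transfer
(six-membered transition ring) is the most favourable:

```{r}
barrier_table()$barriers
```

The absolute values are surrogate choices on the scale of computed HAT
barriers (tens of kcal/mol); what the package's checks rely on is the
*ordering*, which reproduces the experimentally observed dominance of the
1-5 shift in n-alkyl radicals. The distance penalty slope (2 kcal/mol/Å)
makes closer acceptors faster without letting geometry override the
shift-class ordering.

A shift between atoms $k$ bonds apart is labelled `1-(k+1)` -- both
endpoint heavy atoms are counted, so the 1-5 label corresponds to a
six-membered cyclic transition state. Separations beyond 6 bonds are
`"long-range"`, different molecules give `"intermolecular"`.

### Competing closed-shell chemistry: Bell and hydrolysis models

Homolysis under mechanical force follows the Bell model,
$k(F) = k_0 \exp(F \Delta x / k_B T)$, with $k_B T$ converted to
pN·Å (1 kcal/mol = 69.48 pN·Å). Hydrolysis uses a heuristic with a
*saturating* force response, one rate decade per pH unit, and linear
scaling in solvent-accessible surface area:

$$k = k_\mathrm{ref}\,
  \exp\!\left(\frac{\alpha (F - F_\mathrm{ref})}{1 + F/F_\mathrm{sat}}\right)
  10^{\,\mathrm{pH} - \mathrm{pH}_\mathrm{ref}}
  \frac{\mathrm{SASA}}{\mathrm{SASA}_\mathrm{ref}}.$$

The defaults ($k_\mathrm{ref} = 10^{-9}$ s$^{-1}$, $\alpha = 0.01$
pN$^{-1}$, $F_\mathrm{sat} = 2000$ pN against $k_0 = 10^{-15}$ s$^{-1}$,
$\Delta x = 0.3$ Å) are chosen so the qualitative competition is
reproducible as a property: both channels are negligible at zero force,
hydrolysis wins around 1 nN, and because its force response saturates
while the Bell exponential does not, homolysis overtakes it at a few nN.
The exact fitted constants of force-clamp experiments are not reproduced;
the functional form and the crossover are the contract.

### Photodimerization and quantum yields

Stacked pyrimidine double bonds dimerize when close and well aligned. The
heuristic rate is

$$k(d, \theta) = A\, e^{-d/d_0} \max(0, \cos\theta)\,
  \mathbf{1}(|\theta| \le \theta_\mathrm{max}),$$

with $d$ the distance between the two reactive double bonds and $\theta$
the dihedral between them. Frames with $k$ above a threshold count as
dimerisable, and the quantum yield $\phi$ is the dimerisable fraction of
the ensemble. Defaults ($A = 10^9$ s$^{-1}$, $d_0 = 1$ Å,
$\theta_\mathrm{max} = 60^\circ$, threshold $A e^{-4}$) put the reactive
window at roughly $d \lesssim 4$ Å for aligned stacks, the geometric
regime in which dimerization is considered feasible; in applications the
parameters are configuration, to be tuned against measured quantum
yields.

## The sampler and its toy force field

The ensemble generator is an overdamped (position) Langevin integrator,

$$x \leftarrow x + \mu\, \Delta t\, F(x) +
  \sqrt{2 k_B T \mu\, \Delta t}\, \xi, \qquad \mu = \frac{1}{\gamma m},$$

on a deliberately small energy function: harmonic bonds
$k_b (r - r_0)^2$, harmonic angles $k_\theta (\theta - \theta_0)^2$, and
a soft repulsion $10\,(r - 2.5)^2$ kcal/mol for $r < 2.5$ Å between atoms
at bond-graph distance $\ge 4$ or in different molecules (preventing
collapse without any Lennard-Jones parameterization). There are no
torsional energies, no electrostatics, no solvent and no periodic
boundaries. The contract is **thermostat correctness** -- the stationary
distribution is the Boltzmann distribution of this toy energy -- not
dynamical realism. An overdamped update was chosen over velocity Verlet
because only the sampled ensemble matters here and a first-order scheme
keeps the integrator (and its checkpointable state) minimal.

Numerical choices: the default timestep of $5 \times 10^{-4}$ ps with
friction 5 ps$^{-1}$ keeps the stiffest update factor
$\theta = 2 k_b \mu \Delta t \approx 0.07$ for C-H bonds, giving a
stationary-variance bias of $\theta/2 \approx 4\%$ -- inside the 10%
equipartition tolerance the tests enforce (mean harmonic bond energy
$\approx k_B T / 2$ per bond). Degenerate geometries are guarded: zero
interatomic distances fall back to a fixed direction, angle forces clamp
$\sin\theta$ away from zero, and non-finite forces abort with the step
index rather than propagating NaNs.

`Relax` steps use 200 steepest-descent iterations with per-atom
displacements capped at 0.02 Å -- a stand-in, with the same contract
(relax the product coordinates), for the gradual reactant-to-product
parameter interpolation a production MD engine would perform. The
interpolation schedule of such an engine is deliberately not reproduced.

## Synthetic fixtures: what they emulate and what they do not

All test systems are generated in code:

* `build_alkane(n)` / `build_alkyl_radical(n, i)` -- all-trans alkanes
  (C-C 1.526 Å, 111° backbone) and their radicals, the classic validation
  systems for 1-n hydrogen shifts.
* `build_dipeptide_water()` -- a glycylglycine-like fixture with explicit
  hydrogens, order-2 carbonyl bonds and one water, for hydrolysis vs.
  homolysis of the same peptide bond.
* `build_pyrimidine_pair()` -- a *synthetic* minimal stand-in for two
  stacked pyrimidine C5=C6 bonds: two ethylene-like units. It has the
  right reactive degrees of freedom (stack distance, inter-bond dihedral,
  ring closure) but none of the base, sugar or backbone chemistry.
* `synth_dimer_geometry_ensemble()` -- (distance, dihedral) samples from
  a zero-truncated normal and a wrapped normal, emulating the joint
  geometry distributions seen in nucleic-acid stacking ensembles.

Radical bookkeeping is by **valence deficit**: an atom is a radical iff
the sum of its bond orders falls short of its element's nominal valence
(H 1, C 4, N 3, O 2, S 2, P 3; configurable). This keeps the radical set
recomputable after arbitrary recipe edits, at the price of requiring
formal bond orders in fixtures (a carbonyl carbon with three order-1
bonds would otherwise be misread as a radical -- hence the `order`
column).

Passing tests on these fixtures show that the machinery -- topology
editing, rate laws, kMC selection, provenance, replay -- is correct.
They do *not* show that a real protein or DNA system would give
quantitatively correct cascades: that would require a trained barrier
predictor, a real force field and much longer sampling than the
desk-scale ensembles used here.

## Design decisions

* **Indices.** Atom indices are 1-based on disk and in memory. The file
  dialect mirrors the section names of GROMACS topology files
  (`[atoms]`, `[bonds]`, `[angles]`, `[dihedrals]`, `[pairs]`, `;`
  comments) without its macro system; one indexing convention end to end
  removes a whole class of off-by-one errors in recipe code.
* **Regeneration, not patching.** After a recipe's bond edits, angles,
  proper dihedrals and 1-4 pairs are rebuilt wholesale from the bond
  graph (length-2 paths, length-3 paths, distance-3 pairs), preserving
  parameters of surviving terms and assigning generic parameters
  (covalent-radius bond lengths, tetrahedral angles) to new ones.
  Improper dihedrals are carried through but never auto-generated --
  they encode chemistry a generic rule should not invent.
* **HAT search radius.** Candidate (hydrogen, radical) pairs must
  approach within a cutoff in at least one frame; the default is 7 Å.
  In an extended alkyl chain the 1-2 through 1-6 donors all lie within
  about 6.6 Å of a terminal radical, so the default makes the full
  competition visible to the selector even from modest per-cycle
  ensembles, while the per-frame distance penalty in the barrier model
  keeps distant acceptors appropriately slow. Systems with a trained,
  geometry-sensitive predictor may prefer a tighter radius; it is
  configuration.
* **Selection boundary.** $u_1, u_2$ are drawn on $(0, 1]$ so
  $-\ln u_2$ is finite; the cumulative search implements the
  $\le$ boundary exactly (a draw landing on $F(p_i)$ selects event $i$),
  and zero-rate events can never be selected. The first-reaction kMC
  variant is a registry slot left unimplemented; only rf-kMC with
  adaptive event lists is used.
* **Empty event lists.** If no plugin proposes any reaction, the cycle
  resamples a fresh ensemble up to a configurable retry count and then
  halts gracefully, returning the records so far -- an emulation that
  runs out of chemistry is a result, not an error.
* **Determinism.** Every random draw flows from one seeded
  Mersenne-Twister stream per run; sampler and equilibration seeds are
  derived from it, the algorithm name is logged in every record, and
  checkpoints serialize the exact generator state (floats as `%.17g`
  text, because JSON number printing is lossy). Replaying a seed, or
  restoring a checkpoint, reproduces records bitwise.
* **Equilibration length.** How long the product must be equilibrated to
  sample from its Boltzmann distribution has no general criterion; it is
  exposed as configuration (default 200 sampler steps) rather than
  auto-detected.

## Problem sizes used in the checks

The shipped verification suite uses: $10^5$ selection draws and $10^6$
waiting-time draws for the kMC laws; 20 random molecules of 6-12 atoms
against an exhaustive path-enumeration oracle; a $10^5$-step octane run
for equipartition; $10^5$ geometry samples for quantum-yield recovery
against numerical integration; and 20 independent seeds of 30-step
octyl-radical emulations (400 sampling plus 200 equilibration integrator
steps per cycle) for the 1-5 shift dominance check. These sizes give
three-standard-error resolution on every stochastic comparison while
keeping a full run on a single CPU in the minutes range.

## Known limitations

* Barriers come from a static table plus a distance term; no electronic
  structure, no transition-state search, and no quantum tunnelling
  corrections (which can accelerate real HAT by orders of magnitude at
  300 K -- selection probabilities are much more trustworthy than
  absolute waiting times, and the same caveat applies to any barrier
  emulator without tunnelling).
* The toy force field cannot describe conformational preferences that
  depend on torsions, sterics beyond soft repulsion, or electrostatics;
  ensembles are qualitatively floppy.
* Hydrolysis conserves atoms via an explicit water but ignores
  protonation states beyond that; dimerization covers only the single
  syn ring closure, not alternative photoproducts or isomers.
* Nonbonded parameters after a reaction are assigned by the generic
  rule; no claim of equivalence to any production force field's
  heuristics is made.
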