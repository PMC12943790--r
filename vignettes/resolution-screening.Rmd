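---
title: "Screening diastereomeric-salt resolutions with ideal melting phase diagrams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening diastereomeric-salt resolutions with ideal melting phase diagrams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiralmelt)
```

## The screening problem

Classical optical resolution dissolves a racemate together with a chiral
resolving agent and lets the two diastereomeric salts compete during
fractional crystallization. Whether that competition is worth running depends
on solubility relations that are tedious to measure. The premise of this
package is the well-established shortcut: under ideal eutectic behavior the
*eutonic* composition of the salt pair in solution is estimated by the
*eutectic* composition of their binary solid--melt phase diagram, and that
diagram is fixed by two DSC observables per phase — the melting temperature
$T^f_i$ and the molar enthalpy of fusion $\Delta H_i$.

## The model

Each crystalline phase in equilibrium with an ideal melt follows the
Schröder–van Laar liquidus

$$\ln x_i = \frac{\Delta H_i}{R}\left(\frac{1}{T^f_i} - \frac{1}{T}\right),$$

and a 1:1 crystalline addition compound (a racemic compound, or a double salt
of the diastereomeric salt pair treated formally the same way) follows the
Prigogine–Defay branch

$$\ln\left[4 x_S (1 - x_S)\right] =
  \frac{\Delta H_{RS}}{R}\left(\frac{1}{T^f_{RS}} - \frac{1}{T}\right),$$

valid between its two flanking eutectics and peaking at $x_S = 0.5$ at the
compound's own melting point. Both are closed-form in each direction, so the
package keeps exact inverses (`svl_fraction_at_T()` / `svl_T_at_fraction()`,
`pd_T_at_fraction()`).

A binary eutectic is the unique temperature where the saturation fractions
close to one, $x_A(T) + x_B(T) = 1$; a sub-ternary eutectic extends the sum to
three phases. Because every fraction is strictly increasing in $T$ and the sum
exceeds 1 at the lowest melting point involved, each closure is a bracketed
scalar root on $T \in (1\,\mathrm{K}, \min T^f - 10^{-6}\,\mathrm{K})$, solved
with `uniroot()` at a $10^{-10}$ K tolerance and verified to close the fraction
sum to $10^{-8}$. An independent brute-force check (a 0.001 K temperature
scan) backs every solver in the test suite.

Assumptions inherited from the model, and deliberately not relaxed:

* ideal melts — no activity coefficients, no NRTL/UNIQUAC;
* no heat-capacity ($\Delta C_p$) corrections to the liquidus;
* addition compounds are single pseudo-components (no melt dissociation);
* DSC peak temperatures and decomposition-corrected enthalpies are taken as
  given — correcting them is the calorimetrist's job, upstream of this
  package;
* solid solutions (pseudo-racemates) are out of scope.

## Coordinates and conventions

Compositions are barycentric triples over (enantiomer-1, enantiomer-2,
resolving agent), counted in mole fractions of *molecules*: a 1:1 salt sits at
$(0.5, 0, 0.5)$, the racemic compound at $(0.5, 0.5, 0)$, and a
2 agent : 1 racemate double salt at $(0.25, 0.25, 0.5)$ — exactly the 1:1
racemate : agent test composition, which is why such a double salt captures
the conventional starting mixture. On a salt/double-salt/salt binary section
the double salt is booked as $0.5 A + 0.5 B$; this is the accounting the
Prigogine–Defay form presupposes and the natural reading of treating the
double salt "formally" as a racemic compound of the two salts.

Temperatures are kelvin everywhere inside the package; Celsius appears only at
ingest (`t_fus_unit = "C"`) and in human-readable output. The gas constant is
fixed at $R = 8.314$ J mol⁻¹ K⁻¹ and atomic weights at the conventional
two-decimal values, so derived numbers are stable to the printed digit.

## Assembling the triangle

The full diagram is a patchwork of sub-ternary eutectic systems. Practitioners
pick the triplets by hand; `triangulate()` accepts such `explicit_triplets`
and validates them (three known phases, non-degenerate, no other phase
enclosed). Without them it triangulates the phase coordinates by the
empty-circumcircle rule, which automatically enforces the no-enclosed-phase
requirement. The canonical layouts (corners plus edge midpoints) are full of
cocircular quadruples, but in every such quadruple the ambiguous triangles
also carry a phase point on an interior edge and are rejected, leaving a
unique tiling; should a genuinely ambiguous configuration arise, a greedy
smallest-circumradius tiling resolves it deterministically. Point sets here
are tiny (≤ 10 phases), so exhaustive enumeration is the entire algorithm.

Within a sub-ternary, the liquidus surface at composition $c$ is evaluated by
expressing $c$ in barycentric coordinates $y_i$ of the triplet's
stoichiometries and taking the highest Schröder–van Laar branch
$T_i = T^{SvL}_i(y_i)$; the arg-max phase is the dominating solid — highest
melting, least soluble — whose domain $c$ belongs to. Restricted to an edge
between two phases this reproduces the binary envelope exactly. Near compound
phases the binary sections additionally use the Prigogine–Defay branch; the
2-D surface does not, which is an acknowledged approximation — the binary
sections remain the quantitative record, and the surface is used for domain
topology, test-point dominance and domain areas. Ternary eutectic
temperatures from the three-phase closure are exact within the ideal model
and always lie at or below the three edge eutectics of their triplet.

`domain_map()` rasterizes the dominating phase on a barycentric lattice
(default 201 points per edge; cells outside the phase convex hull are marked
invalid) and reports per-phase domain areas as fractions of the valid region.

## Verdict rules

`resolution_verdict()` encodes the empirical screening rules:

* **blocked_by_double_salt** — a double-salt phase dominates at the
  $(0.25, 0.25, 0.5)$ test point: the 1:1 starting mixture yields only the
  addition compound, and no racemate : agent mixing ratio favors either salt;
* **promising** — otherwise, when the salt pair's melting points differ by at
  least 20 K (the rule is applied as $\geq 20.0$ K on the as-ingested
  temperatures, with no uncertainty propagation);
* **inefficient** — a crystalline pair closer than 20 K;
* **indeterminate** — a required salt lacks melting data (an amorphous salt,
  noted as expected to remain in the mother liquor).

Quantitatively, `salt_pair_metrics()` reports the eutectic fraction $x_{eu}$
of the *higher-melting* (favored) salt and the Fogassy resolubility parameter
$F_{max} = 2 - 1/(1 - x_{eu})$, the theoretical maximum efficiency: 1 when the
favored salt crystallizes alone, 0 at the symmetric eutectic. For promising
systems the report also samples the racemate–agent mixing line and records the
segment where the favored salt dominates — the recommended initial mixing
ratios.

Degenerate inputs are handled explicitly rather than extrapolated: two
distinct phases with identical melting data return the symmetric $x = 0.5$
eutectic with a degeneracy flag; a compound whose branch never rises above an
end member's raises a "metastable" error; a triplet without data yields a
sub-ternary without a eutectic and, downstream, an indeterminate verdict.

## The synthetic generator

`generate_synthetic_system()` emulates the *shape* of real resolution
systems: an enantiomer pair with identical data (physically required), a
racemic compound melting near the enantiomers (drawn within $-30/+5$ K of
them, with a 1.2–2.2× enthalpy, as racemic compounds typically behave), an
independent salt pair, optionally a crystalline agent, a double salt at the
test point, and 2:1 salts on the agent-rich edges. Melting points default to
330–480 K and enthalpies to 15–65 kJ/mol, the span of the packaged case
tables. What it does **not** emulate: correlated measurement error, melting
with decomposition, solvates, polymorphism, or non-ideal melts. Passing
property tests on these systems therefore demonstrates solver correctness
under the model's own assumptions, not predictive accuracy for any real
laboratory system.

One limit worth recording: for a compound melting at the enantiomers'
temperature, growing $\Delta H_{RS}$ flattens the Prigogine–Defay branch
toward $T \approx T^f_{RS}$, so the flanking eutectics drift monotonically
*outward* (toward the pure ends), not toward the branch's center; the
property tests assert this verified direction.

## Problem sizes and numerical checks in the shipped tests

The test suite checks every eutectic against an independent two-stage
brute-force scan (0.1 K coarse, 0.001 K fine) — 1000 seeded systems for the
pairwise solver, with mirror-symmetry of domain maps checked exactly on
41-point lattices and domain-area statements on 101-point lattices; these
sizes keep the default run inside a few seconds while the sampling error
$2/\mathrm{grid}$ stays below the asserted tolerances. The acceptance script
re-runs the three case studies end to end and a 200-system sweep.

## Worked example

```{r example, eval = FALSE}
cs <- load_case("case3_2ClMA_pregabalin")
m <- salt_pair_metrics(get_phase(cs$phase_set, "4''"),
                       get_phase(cs$phase_set, "5''"))
m$x_eu      # 0.0857: eutectic fraction of the favored salt
m$F_max     # 0.906:  theoretical maximum resolution efficiency
td <- ternary_diagram(cs$phase_set)
resolution_verdict(td)   # promising; salt 4'' dominates the test point
plot(td)
```

## Known limitations

The melt diagram is a proxy: real resolutions happen in a solvent, which is
not a component here, and kinetics (seeding, entrainment) are outside the
model. The case-study enthalpies include two literature values an order of
magnitude below their neighbors and decomposition-corrected specific
enthalpies whose phase assignment follows the parallel order of the published
melting-point and enthalpy lists; both are carried as printed, with
provenance notes in the fixtures. Ternary eutectic temperatures shown in
published figures are used only for ordering checks, never as reference
numbers.
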