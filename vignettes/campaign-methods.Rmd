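---
title: "Methods: dictionary-driven analog design and assay analysis for a dCK campaign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dictionary-driven analog design and assay analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dckdesign)
```

## The problem this package addresses

Deoxycytidine kinase (dCK) is the rate-limiting enzyme of the nucleoside
salvage pathway. Because cancer cells can compensate for de novo pathway
inhibition by upregulating salvage, a potent dCK inhibitor combined with a
ribonucleotide-reductase inhibitor is a synthetic-lethality strategy, of
particular interest in T-cell acute lymphoblastic leukemia. The tyrosine
kinase inhibitor masitinib binds dCK as an off-target and *activates* it;
increasing the ligand's complementarity for the binding site switches the
series from activators to inhibitors. `dckdesign` implements the
computational half of such a hit-to-lead campaign: systematic analog
enumeration around the seed scaffold, filtering, template-constrained 3D
evaluation, the campaign's assay computations, and the bookkeeping that
turns per-compound measurements into the decision tree of the
optimization.

## Analog enumeration from a generic dictionary

The design space is a *generic modification dictionary*: functional
groups, 3- to 6-membered rings (carbocyclic and N/O heterocycles,
decorated or not), and short C/O/N spacers, each fragment carrying exactly
one attachment dummy `[*]`. The dictionary is the cross-product

    (ring core x decoration x spacer)  +  (functional group x spacer)

deduplicated by canonical SMILES. Because published descriptions of such
dictionaries state the categories but not the membership, the shipped spec
(`default_dictionary_spec()`) is an explicit, editable reconstruction: 32
functional groups from a standard medicinal-chemistry repertoire, 27 ring
cores, decorations `none`/`ortho`/`meta`/`para` on 6-membered rings
(adjacent/non-adjacent mapped to `ortho`/`meta` on smaller rings; methyl
as the decoration substituent), and spacers of length 0-2 over {C, O, N}.
That yields 1403 unique fragments - deliberately sized so that a single
attachment site on a masitinib-like seed produces more than 1000 unique
analogs, the scale of the campaign being emulated.

```{r dictionary, eval = FALSE}
dict <- build_generic_dictionary(default_dictionary_spec())
nrow(dict$entries)   # 1403
```

Two choices are worth making explicit. First, chemically unattractive
combinations (e.g. an O-O spacer contact forming a peroxide) are *not*
suppressed at generation time: generation is a pure cross-product with
only valence validity enforced, and liabilities are handled downstream by
the alert filter. This keeps the generator auditable - the entry count
equals what a nested-loop enumeration of the spec predicts. Second, there
is deliberately no diversity reduction: the campaign keeps close analogs,
so the library is exactly one product per (site, fragment) pair that
attaches, deduplicated by canonical text.

Attachment replaces one hydrogen of the chosen seed atom with a single
bond to the fragment (or swaps a terminal group), then re-canonicalises;
every product must pass the same valence validator as every input. One
canonicalisation authority (OpenBabel canonical SMILES) is the identity
notion everywhere - deduplication, ledger keys and tests all compare that
string. Ring fusions and spiro attachments are out of scope: the
enumeration models substituent replacement, which is what a predefined
attachment point expresses.

## Standardisation and filtering

`standardize()` first neutralises charges where chemically safe
(OpenBabel's neutralise operation, which protonates carboxylates and
deprotonates ammonium ions but leaves balanced zwitterions like nitro
groups and permanent quaternary ammonium charges untouched), then selects
one tautomer deterministically via an InChI round-trip: InChI pools mobile
hydrogens, so 2-hydroxypyridine and 2-pyridone inputs both map to one
output. The composition is idempotent, which the test suite checks as a
property. Full microspecies distributions (pKa models) are intentionally
out of scope; this is a single-species pH-neutral approximation.

Physicochemical profiles pin one published estimator per quantity:
molecular weight from standard atomic masses with implicit hydrogens,
logP from the Wildman-Crippen atomic-contribution scheme (OpenBabel's
implementation; the value for n-propylbenzene is frozen in the tests
against an independent computation of the same published table), TPSA,
donor/acceptor counts, and rotatable bonds from the usual
non-terminal/non-ring single-bond SMARTS definition.

The default property windows (MW <= 650, logP <= 6, <= 12 rotatable
bonds) are campaign-tunable defaults, *not* values reported by any
experiment - the campaign literature says only that compounds with
unreasonable properties were discarded. The same applies to the alert
list: a compact curated set of reactive/unstable substructures (nitro,
peroxide, hydrazine, acyl and sulfonyl halides, Michael acceptors, ...)
in a plain-text SMARTS file. Filtering applies alerts first, then each
window in a fixed order, recording the first triggered rule per compound,
so the report satisfies the accounting identity
`retained + sum(per-rule rejections) = input` exactly, and tightening any
window can only shrink the retained set (tested on 500 random window
draws).

## Template-constrained 3D evaluation

The campaign evaluated designs against the crystallographic (bioactive)
conformation of the first hit inside the dCK pocket using commercial
software. That stage is replaced here by transparent components; no
proprietary scoring function is reimplemented.

**Embedding.** The requirement is bit-reproducibility: the same molecule
and seed must give identical coordinates. General-purpose stochastic 3D
builders do not offer seed control, so the package embeds deterministically:
a 2D structure layout with explicit hydrogens is lifted to 3D by a seeded
Gaussian perturbation (sigma 0.35 A out of plane) and relaxed by
steepest-descent MMFF94 minimisation, which is deterministic given its
input. The geometry audit (bond lengths within 15% of covalent-radii
sums, no atom pair closer than 0.5 A) triggers a seeded restart on
failure. The resulting conformers are suitable for mapped-atom
superposition and clash/torsion screening - they are not a conformer
*search*, and the method does not claim to find the global minimum.

**Mapping.** The correspondence between a design and the template is the
maximum common connected substructure under element and bond-class
compatibility, with aromatic bonds forming one class so that kekulisation
cannot split a ring match. The common case - the template is an exact
substructure of the design, because the design is seed + fragment - is
solved by colored VF2 subgraph isomorphism; the general case falls back
to maximum cliques of the modular product graph, restricted to connected
mappings. The fallback is exponential and therefore limited to small
molecules (about 50x50 atoms); ties are broken by the lexicographically
smallest mapped index sequence so the mapping is deterministic. Mappings
below 5 atoms (configurable) are rejected as having no usable template
overlap.

**Superposition.** Closed-form least-squares rigid superposition (Kabsch:
SVD of the mapped-atom cross-covariance with the determinant correction
that excludes reflections), applied to the whole conformer. The tests
compare the minimised RMSD against an independent rotation-grid +
Nelder-Mead oracle to 1e-4 A and check invariance under rigid motions.

**Clashes.** An inter-molecular clash is a ligand/pocket heavy-atom pair
closer than `scale x (r_vdw_i + r_vdw_j)`, with Bondi-type radii pinned
in `inst/extdata/vdw_radii.csv` and `scale = 0.7` by default; the
intra-molecular rule is identical but excludes pairs within three bonds
(1-2, 1-3, 1-4). Counts are monotone in the scale by construction.

**Torsion strain.** Rotatable bonds (acyclic single bonds between
non-terminal heavy atoms) are classified from the molecular graph into
three rule classes - sp3-sp3, biaryl, aryl-amide - and the dihedral over
the lowest-index heavy substituents is checked against per-class allowed
windows shipped in `inst/extdata/torsion_rules.csv` (staggered rotamers
for sp3-sp3, twisted for biaryl, near-planar for anilides). Classifying
from the graph rather than by SMARTS keys keeps the matched atoms
available for the dihedral computation with no extra machinery; the rule
file remains the editable definition of the windows. Unclassified
torsions are unscored rather than guessed. This is a minimal curated rule
set, not a full published torsion library.

**Prioritisation.** The priority score is minus the weighted sum of
normalised penalties - clash counts, strained torsions, mapped-atom RMSD,
physicochemical window violations - i.e. exactly the non-proprietary
criteria the campaign used, made explicit. Each term is scaled by its
maximum over the evaluation set so weights compare like with like;
weights are non-negative, the sort is stable and ties break on canonical
SMILES. Because the affinity estimator used in the original workflow is
closed software, its contribution is *not* emulated; the score reproduces
the shape of the decision procedure, not its numbers.

## Assay computations

Units are normalised package-wide: degrees Celsius, seconds, nanomolar,
kcal/mol.

**Thermal shift.** The melting temperature is the inflection of a
Boltzmann sigmoid fitted by Levenberg-Marquardt least squares, with the
argmax of the smoothed derivative as fallback when the sigmoid does not
converge; a flat curve raises `NoTransitionError` instead of returning a
number. The vendor software used for such assays does not document its
estimator, so the Boltzmann midpoint is this package's pinned definition.
Delta Tm is the signed holo-minus-apo difference; destabilisation is
negative.

**Enzymatic velocity.** The coupled assay reads kinase activity as NADH
fluorescence decay, and the velocity is the slope of the linear range.
"Linear range" is made precise as: among all contiguous windows covering
at least 30% of the points whose linear fit reaches R^2 >= 0.99
(configurable), take the window maximising R^2, break ties by length then
by earliest start. On a noiseless piecewise trace this provably returns
the generating slope of the linear segment. A constant trace is the
accepted degenerate case (velocity 0, flagged); a trace with no
qualifying window raises `NonLinearTraceError`.

**Dose-response.** A four-parameter logistic with free Hill slope, top
and bottom constrained to [0, 120]% unless overridden, fitted in
log-concentration by Levenberg-Marquardt from a half-maximum-based start
(with a median-based restart). The *technical floor* models the fact that
an enzymatic IC50 cannot be resolved below the enzyme concentration in
the assay (100 nM, or 50 nM in the low-concentration variant): when the
fitted IC50 falls below the floor, the result is censored and reported as
`"< floor"`; censored values are flagged, and the ledger refuses to use
them in ratios.

**ITC.** Integrated heats are fitted to the independent-sites isotherm.
The titrations being emulated are *reverse* (protein in the syringe,
compound in the cell, to avoid compound solubility limits), so the model
places the binding sites on the cell analyte, dilutes it per injection,
accumulates the titrant, solves the free-titrant mass balance per
injection by root finding, and applies the standard displaced-volume
correction. The two-site model serves biphasic thermograms (the second,
weaker site seen crystallographically); fitting it to monophasic data
converges but is flagged when the two dissociation constants are
statistically indistinguishable (overlapping 95% intervals). Fits use a
deterministic multi-start grid over stoichiometries and Kd decades to
avoid local minima. Zero heats raise `NoBindingSignalError`.

## What the synthetic generators emulate - and what they do not

Every estimator is validated against `simulate_*` generators that store
their ground truth. The noise model is additive Gaussian throughout:
on fluorescence for melt curves and kinetic traces, in percent points for
dose-response, and scaled to the largest injection heat for ITC.
Concentration grids are log-spaced over the campaign's cellular range
(10 pM to 40 uM). The generators do **not** simulate dye photochemistry,
baseline drift or aggregation artifacts in melt curves, substrate
depletion curvature in kinetics, or ITC power-trace integration and
baseline correction - inputs are assumed to be already-integrated heats.
Passing recovery tests therefore demonstrates estimator correctness under
the stated error model, not robustness to every real-world artifact.

Two generator defaults deserve justification:

* *Dose-response*: 8 log-spaced concentrations in triplicate at 3 percent
  points of noise - a typical plate layout; at this design the IC50 is
  recovered with a mean relative error under 10% across 200 Monte-Carlo
  seeds, which is what the acceptance suite asserts.
* *ITC two-site*: 25 x 2.5 ul injections of 400 uM titrant into 20 uM
  analyte (molar ratio reaching ~5.7, so the weak 10 uM site is actually
  titrated) at 0.1% peak-heat noise. The weak site of a biphasic isotherm
  is intrinsically ill-conditioned: at 2% noise its fitted Kd can be off
  by half an order of magnitude regardless of optimiser. The defaults
  were chosen so that the recovery demonstration tests the estimator, not
  the titration design; with real instrument noise a wider uncertainty
  must be expected, which is why the fit reports a residual norm and an
  indistinguishability flag rather than bare point estimates.

## The SAR ledger

The shipped ledger fixture contains only values printed in the campaign's
main text - thermal shifts, dissociation constants, enzymatic and
cellular IC50s and c-KIT selectivity ratios for masitinib, dCKi1, dCKi2,
the nine milestone compounds and the negative control - each row carrying
a provenance note and a comparator (`<`, `>`) where the value is
censored. Supplementary per-compound tables are user-loadable CSVs, not
shipped. Fold-change and difference operations are exact arithmetic on
the stored values; censored operands raise `CensoredValueError` rather
than silently producing a bound.

Parent links form a single-parent forest. The hybrid compound OR0634
merges two branches chemically; its ledger parent is OR0602 (the branch
whose potency sequence it continues), a forest constraint made explicit
here. OR0602's thermal shift is described in the text only as "affinity
maintained" and is deliberately left blank rather than guessed. The tree
export validates acyclicity, orders nodes topologically and annotates
each node with its headline values and the sign of change versus its
parent (lower is better for IC50, higher for delta Tm).

```{r ledger, eval = FALSE}
led <- default_sar_ledger()
fold_change(led, "dCKi1", "OR0642", "cellular_ic50")   # ~3136
delta_field(led, "OR0642", "dCKi1", "delta_tm")        # 7.9
```

## Numerical choices and degenerate inputs

* Canonical SMILES (OpenBabel) is the single identity function; all
  orderings that must be deterministic sort on it with radix order.
* 0-based atom indexing in every API and file, regardless of the 1-based
  indexing of interchange formats.
* Nitrogen valence admits 5 because the canonicalisation authority writes
  nitro/N-oxide groups in the neutral hypervalent form.
* The mol-block reader is a compact internal fixed-width V2000 parser:
  the package round-trips thousands of single-molecule blocks during
  enumeration and must accept bond-less records such as water.
* Flat melt curves, all-zero isotherms, non-linear traces and sub-40%
  dose-response spans raise classed errors rather than returning numbers.
* Problem sizes in the test suite - the 1403-entry dictionary at one
  site, 200 Monte-Carlo dose-response seeds, 500 random filter windows,
  100 random clash fixtures, rotation-grid superposition oracles on
  6-atom toys - were chosen to exercise each property at the scale of the
  campaign while keeping the default test run to about a minute.

## Known limitations

* The dictionary is a reconstruction: category-faithful, membership by
  curation. Different curation changes absolute library counts (the
  >1000-analog scale is preserved by construction).
* Binding-affinity estimation is absent by design; the priority score
  ranks by geometry and physicochemistry only.
* The embedding is a deterministic single-conformer procedure, not a
  conformational search, and aromatic ring planarity is only as good as
  the MMFF94 relaxation from a jittered 2D layout.
* The ITC model covers independent sites in a single titration;
  displacement/competition formats are out of scope.
* Attachment chemistry is limited to single-bond substitution; no
  retrosynthetic feasibility, reaction encoding, ring fusion or
  stereoisomer enumeration.
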