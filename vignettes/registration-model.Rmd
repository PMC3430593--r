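---
title: "The registration model: uniqueness, standardization, and the audit trail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The registration model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucdreg)
```

## Why a registration system

A compound collection is only useful if each chemical entity appears in it
exactly once, under a code that survives redrawing, re-salting, and late
corrections. `ucdreg` implements that guarantee for desk-scale registries:
molecules are stored as standardized neutral structures, salts and
hydrates live one level down as *substances*, and every physical or
literature occurrence is a *batch*. Nothing is ever deleted; corrections
move batches and archive emptied parents, and every transition appends an
audit event.

This vignette explains the chemistry model, the rule set, the tunable
parameters, and the design decisions taken where more than one reasonable
choice existed.

## The uniqueness key

The registration key of a structure is built from three independent
parts, computed on the standardized neutral form:

1. **Skeleton.** The standard InChI of the structure with its tetrahedral
   stereo layers (`/t`, `/m`, `/s`) removed. Standard InChI's mobile-H
   canonicalization is a published, rule-based tautomer canonicalization:
   2-pyridone and 2-hydroxypyridine produce one identical string, which is
   exactly the collision we want. Double-bond geometry (`/b`) stays in the
   skeleton — *cis*/*trans* isomers are different molecules, tautomers are
   not. Carbon-centred (keto–enol) tautomerism is *not* merged by standard
   InChI; the shipped tautomer fixtures are heteroatom-H pairs, and the
   key's contract is defined by those pairs.
2. **Stereo serialization.** SMILES and InChI cannot express enhanced
   stereochemistry — AND/OR stereo collections or a wavy "either" bond —
   so the key carries its own serialization. Each tetrahedral center's
   parity is computed geometrically (the sign of the signed volume spanned
   by its substituents, using wedge direction as the out-of-plane
   component, substituents ordered by InChI canonical atom number; an
   implicit hydrogen ranks last). Centers are bucketed `ABS`, `AND-n`,
   `OR-n`, or `EITH`; relative buckets are renumbered by their smallest
   canonical member, and mirror-canonicalized (a racemate serializes
   identically whichever enantiomer was drawn, because an AND group *is*
   both). An "either" center is an explicit `?` token — deliberately
   distinct from an unannotated center, which contributes nothing: a
   drawing that asserts "unknown configuration" and a drawing that asserts
   nothing are two different registrations.
3. **Mixture ratio.** An ordered integer ratio normalized by its GCD
   (50:50 ≡ 1:1 ≢ 30:70). Mixtures of one enantiomer pair in different
   ratios have different physico-chemical properties and therefore get
   different codes; exact structure search strips this part so that all
   ratio variants of a mixture are retrieved together.

Atom-order invariance comes from the InChI canonical numbering (taken from
the InChI AuxInfo); if AuxInfo is unavailable the serialization falls back
to the package's own symmetry-class refinement order, which is still
deterministic for a fixed drawing. "No Structure" entries — registrable
placeholders for unidentified peaks — have no key at all and *never*
merge: every approval mints a fresh code.

## Standardization and validation

Standardization applies, in order: neutralization; wedge re-pointing (the
narrow end must sit on the stereocenter); redundant-wedge removal (at most
one up and one down wedge per center); and geometry straightening through
triple bonds (substituents on a nitrile are forced to 180°, tolerance 2°).
Each applied rule is recorded, and the whole pipeline is idempotent: a
second pass applies nothing.

Neutralization adds one hydrogen per unit negative charge and removes one
per unit positive charge, implemented by zeroing the formal charge and
letting the charge-adjusted valence model recompute implicit hydrogens —
which guarantees the heavy-atom graph is untouched. A quaternary ammonium
nitrogen (four non-hydrogen substituents) is permanently charged
independent of pH, is left alone, and flags the molecule
`permanent_cation`. Both centers of a zwitterion are neutralized. A
charge that cannot be resolved by hydrogen transfer (a bare metal cation,
for instance) is an error: counter-ions belong in the salt dictionary,
not in the drawing.

Validation catches what cannot be auto-fixed: valence violations against
a standard organic valence table (B, C, N, O, Si, P, S, Se, halogens,
with charge-shifted variants; exotic elements pass with a warning);
stereo bonds on bridging/ring-fusion atoms (ring-degree ≥ 3 — draw the
explicit hydrogen instead); wedges anchored at no stereocenter; and
wedge layouts whose parity determinant is numerically degenerate (below
1e-6), i.e. drawings whose configuration cannot be determined. A
potential stereocenter left unannotated is a warning, not an error.
Stereocenter perception uses Morgan symmetry-class refinement (an sp3
atom whose four substituents, implicit H included, fall in pairwise
distinct classes); this excludes symmetric false positives by
construction but can miss exotic cases (e.g. stereocenters distinguished
only by remote parity), a known and documented limitation.

## Substance mass arithmetic

A substance's theoretical mass is

$$M = M_{mol} + \sum_i c_i M_{salt,i} + n_{hyd} M_{H_2O} - n_H M_H,
\qquad n_H = \sum_i c_i z_i$$

The signed proton-displacement term generalizes the worked
carboxylate-sodium case (85.062 + 22.990 − 1.008 = 107.044 g/mol): a
cationic counter-ion displaces an acidic proton, an anionic counter-ion
arrives as the hydro-acid and contributes one. For permanently cationic
molecules $n_H = 0$ — the quaternary salt pairs without proton transfer —
and pairing such a molecule with another cation is rejected. Fractional
stoichiometry (hemisalts) is supported. Atomic weights are the IUPAC
standard (abridged) values pinned in the package source; the shipped salt
dictionary's stated masses are cross-checked against their formulas at
load time (tolerance 1e-3 g/mol) so a corrupted dictionary fails loudly.

## Workflow, roles, and the audit trail

Registration is two-staged. `submit()` runs parse → standardize →
validate, requires the submitter's sign-off on the normalized form, checks
mandatory metadata (and that numeric fields such as the experimental MW
actually hold numbers), and files the entry in the submission area under
an incremental id. `decide_submission()` is registrar-only: approval
resolves uniqueness — reuse an existing molecule code on key match,
reactivate an archived one, or mint the next code — then reuses or mints
the substance letter (A…Z, AA, AB, …; letters are never reused after
archiving) and registers the batch under the submission id. Rejection
keeps the submission forever with its reason; resubmission gets a fresh
id.

Roles are exactly `viewer` (read), `submitter` (read + submit), and
`registrar` (everything); team-restricted batch fields are readable only
by the owning team. Batch reassignment and archiving cascade: a substance
left with no registered batches is archived, a molecule left with no
active substance likewise, and no row is ever removed. Every status
change appends exactly one audit event, and `replay_audit()` reconstructs
every entity's current status from the event stream alone — the invariant
the randomized workflow suite checks after a thousand mixed operations.

Approving chemistry identical to an archived molecule *reactivates* it
rather than minting a duplicate code; hydrate count and salt stoichiometry
both participate in substance identity. Both choices were genuinely open;
the first avoids two codes for one chemistry, the second follows the
observation that a monohydrate and an anhydrate are different materials.

## Search

Exact search compares structure-only keys (ratio stripped, tautomer- and
stereo-aware). Substructure search is subgraph *monomorphism* on element
and bond order — charge is constrained only where the query states one —
implemented as a backtracking matcher behind a hashed-path fingerprint
prescreen (2048 bits, linear paths up to 7 atoms, element labels only).
Because every path of a subgraph is a path of its parent and charges are
excluded from the labels, the prescreen can only discard guaranteed
non-matches. Similarity search is the Tanimoto coefficient over the same
fingerprint, thresholded and sorted, ties broken by molecule code. A
linear scan is deliberate: at desk scale the contract (no false
negatives) matters more than indexing.

## Bulk import and the fixture generator

`import_sdf()` pushes every record through the *same* submit/approve path
as manual entry, so bulk and manual registration cannot diverge: records
whose drawings needed auto-fixes register "with warnings", invalid
records are rejected individually, and re-importing a structure-bearing
file never creates a molecule. Composition directives (salt, coefficient,
hydrate, mixture ratio, no-structure flag) travel as SDF data fields
under a configurable field map; unmapped fields are preserved verbatim.
Name-to-structure conversion is intentionally out of scope — the importer
requires structures.

`generate_fixtures()` is first-class, tested code: it emits SDF files
realizing requested categories (clean scaffolds, fixable drawings,
valence and bridge-stereo errors, atom-permuted duplicates, tautomer
pairs, salt variants, no-structure records) with a manifest of expected
dispositions and collapse groups, byte-identical for a given seed. The
scaffold list includes the worked figure compounds (2-cyanoacetic acid,
the 4-chloropentan-2-ol stereo family, a glucopyranose). What it emulates
is *registration* diversity — drawing errors, duplicates, tautomer and
salt variants; what it does not emulate is realistic chemical-space or
property distributions, so passing suites demonstrate the bookkeeping and
identity semantics, not chemical coverage.

## Numerical choices and problem sizes

* Salt-dictionary mass check: 1e-3 g/mol; mass-oracle agreement asserted
  to 1e-6 g/mol over 120 randomized compositions.
* Triple-bond collinearity tolerance 2°; parity degeneracy cutoff 1e-6 on
  the determinant; coordinates written to molfiles at 4 decimals.
* Similarity ties broken by molecule code; substance letters bijective
  base-26; molecule-code width 8 digits, configurable.
* The test suites run a 1000-operation randomized workflow, a
  50-molecule × 20-query substructure cross-check, and ~120-composition
  mass checks — sizes chosen to exercise every code path and cascade
  combination while keeping the whole suite comfortably interactive.

## Known limitations

Aromatic input is kekulized by Open Babel on entry, so bond-order-exact
substructure semantics see one kekulization (symmetric rings still match
by symmetry). Stereo perception is 2D-wedge-based; 3D coordinates,
polymers, Markush structures and reaction records are out of scope.
Perspective drawings are not auto-detected — coordinate normalization
subsumes them. The permission model is a local user table, the store an
in-memory set of tables with JSON persistence: both deliberate
simplifications of the deployment-scale architecture this package
distils.
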