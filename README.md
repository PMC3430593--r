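# ucdreg — unique-structure chemical compound registration

`ucdreg` is an R implementation of a corporate-style chemical registration
system for desk-scale use: the kind of system an R&D organisation uses to
guarantee that every small molecule in its collection is registered exactly
once, drawn in a standard way, and traceable through every correction ever
made to it.

It is aimed at chemoinformaticians and data stewards who need registration
*semantics* — uniqueness keys, salt/hydrate bookkeeping, two-stage review,
audit trails — without an Oracle cartridge stack.

## The model

Identity is organised in three levels:

* **Molecule** — the neutral form of a structure, without counter-ions or
  hydrate. Charged drawings are neutralized on entry (one hydrogen added
  per unit negative charge, removed per unit positive charge); quaternary
  ammonium nitrogens, being permanently charged, are exempt and flagged.
  Each molecule gets a code `UCD` + 8 digits.
* **Substance** — a molecule plus counter-ion(s) from a salt dictionary at
  fixed stoichiometry, and/or waters of hydration. Coded by a letter
  suffix: `UCD01234567-A`, `-B`, ...
* **Batch** — one occurrence of a substance (sample, MS identification,
  literature reference) with its metadata. Batch codes are incremental
  integers that double as submission IDs.

Uniqueness is enforced through a registration key computed on the
standardized neutral structure:

```
ucd_key = InChI-skeleton ⊕ stereo-serialization ⊕ mixture-ratio
```

* the skeleton part is the standard InChI with its tetrahedral layers
  stripped — InChI's mobile-H canonicalization makes tautomeric drawings
  collide on purpose;
* the stereo part serializes per-center wedge-derived parities on InChI
  canonical atom numbers, bucketed by enhanced stereo group (absolute /
  AND / OR, plus wavy-bond "either" centers) — configurations that SMILES
  and InChI cannot express;
* the ratio part is the GCD-normalized stereoisomer mixture ratio, so a
  50:50 and a 30:70 mixture of the same enantiomers are different
  molecules, while 50:50 and 1:1 are the same.

Substance masses follow the registration-system rule

```
M(substance) = M(molecule) + Σ cᵢ·M(saltᵢ) + n·M(H₂O) − n_H·M(H)
```

with `n_H = Σ cᵢ·zᵢ` (one proton displaced per unit of balanced
counter-ion charge, signed), and `n_H = 0` for permanently cationic
molecules.

Everything else follows from those invariants: a two-stage
submission/registration workflow with viewer/submitter/registrar roles,
exact / substructure / similarity search over the registration area,
archive-never-delete semantics with cascade archiving and a replayable
audit log, and bulk SDF import that shares the exact uniqueness path with
manual entry.

## Worked example

```r
library(ucdreg)

reg <- ucd_registry()
add_user(reg, "alice", "submitter", team = "chemistry")
add_user(reg, "carol", "registrar", team = "informatics")

# a chemist submits 2-cyanoacetic acid, drawn as the sodium carboxylate
id <- submit(reg, "alice", "N#CCC(=O)[O-]",
             composition = substance_composition(
               data.frame(id = "sodium", coeff = 1)),
             metadata = list(project = "P1", scientist = "alice",
                             notebook_ref = "NB-1"))
decide_submission(reg, "carol", id, "approve")
#> $molecule_code
#> [1] "UCD00000001"
#> $substance_code
#> [1] "UCD00000001-A"
#> $batch_code
#> [1] 1
```

The drawing was stored neutralized; the substance mass is the acid plus
sodium minus one hydrogen:

```r
substances(reg)$mass
#> [1] 107.044      # 85.062 + 22.990 - 1.008
```

Submitting the same acid again — in a different atom order, as a different
salt, or as a tautomeric drawing — reuses molecule `UCD00000001` and only
adds substances and batches. Registered molecules are searchable:

```r
exact_search(reg, "N#CCC(=O)O")[[1]]
#> <hit UCD00000001 score 1.000: 1 substance(s), 1 batch(es)>

compute_properties(parse_structure("N#CCC(=O)O"))
#> <C3H3NO2: MW 85.062, logP -0.02, HBD 1, HBA 3, rot 1, Lipinski pass, lead-like pass>
```

A thin command-line front end with the same operations ships in
`inst/cli/ucd.R` (`submit`, `review`, `search`, `import`, `export`,
`fixtures`, `audit`, ...).

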