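---
title: "Systematic fatty acyl identifiers: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Systematic fatty acyl identifiers: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acylid)
```

## 1. The species model

A fatty acyl metabolite is represented as an `acyl_species`:

* `acyl_class` — the carrier: `fa` (free acid), `coa` (CoA thioester),
  `acp` (acyl carrier protein thioester), `carn` (carnitine ester),
  `nae` (N-acyl ethanolamine).
* `carbons` — total acyl chain carbons, Δ-numbered from the carboxyl
  carbon (C1).
* `n_double_bonds` — the declared count; `double_bonds` — a (possibly
  shorter) list of `double_bond(position, geometry)` with geometry `Z`, `E`,
  or `NA`. A species whose positions are not all known is *incomplete*:
  identifiers can still be written for it, but structures cannot.
* `groups` — `functional_group(kind, position, stereo)` with kinds `OH`,
  `OOH`, `O` (keto), `NH2`, `Me`; `OH`/`NH2` may carry `R`/`S` stereo.
* `base_stereo` — for classes whose head group has its own stereocenter
  (carnitine), `L`/`D`.

Descriptors are kept in canonical order (position, then kind) by
`canonical_order()`, so equal structures always serialize identically.

Iso-branched chains are modelled as the longest chain plus a methyl branch on
the penultimate carbon: the C13 iso acid is `FA(12:0(11Me))`, id
`fa12_0_11me`.

## 2. The two surface forms

**Shorthand** (human-facing): `Class(C:D(descriptors))`, e.g.
`CoA(18:1(9Z))`, `CoA(18:1(9Z,3OH[S]))`, `FA(14:1)` (count-only,
incomplete). `parse_shorthand()` reports the byte offset of any syntax error.

**Model id** (machine-facing, lowercase, model-file safe):
`class` + `carbons` + `_` + `dbcount` + `_` + concatenated descriptors, e.g.
`coa18_1_9z`, `fa18_2_9z12z`. Descriptor tokens are
`ooh, nh2, oh, me, o, z, e`; parsing uses longest-first maximal munch so
`5ooh` is one peroxy group, never a keto plus stray letters.

Stereo can be encoded two ways:

* **inline** — the letter follows the token: `coa18_0_3ohS`;
* **suffix** — double-underscore suffixes after the descriptor block:
  `coa18_1_9z3oh__S`. This matches the widespread model convention of
  `__L`/`__D` suffixes (`crn__L`, `glc__D`).

In the suffix style, for classes with a base stereocenter the *final* suffix
is the base stereo (`carn18_1_9z__L`); remaining suffixes are assigned, in
order, to stereo-capable groups that lack a stereo label. This keeps real
carnitine ids unambiguous while still allowing suffix stereo on chain groups.

The `legacy_tolerant` dialect additionally accepts historical spellings such
as the `crn` prefix and an underscore after the class (`nae_18_1_9z`).

## 3. Chemistry

The free acid of a completely specified chain with $n$ carbons and $d$ double
bonds has formula $C_nH_{2n-2d}O_2$, adjusted per group:
OH $+O$; OOH $+O_2$; keto $+O-H_2$; NH$_2$ $+N+H$; Me $+C+H_2$.

A conjugate is the free acid plus the carrier base minus water
(condensation). Base moieties: CoA $C_{21}H_{36}N_7O_{16}P_3S$, carnitine
$C_7H_{15}NO_3$, ethanolamine $C_2H_7NO$, and a phosphopantetheine-serine ACP
stub $C_{11}H_{21}N_2O_7PRS$ where `R` is a zero-mass pseudo-element standing
for the protein. Protonation conventions then shift H/charge: the `bigg`
convention deprotonates carboxylates ($-1$) and CoA thioesters ($-4$);
`neutral` leaves everything protonated, which is the form compared against
external SMILES/formula oracles.

`to_smiles()` writes neutral SMILES (carnitine as its natural zwitterion)
with explicit `/`…`\` double-bond geometry and `[C@H]`/`[C@@H]` centers for
`S`/`R` hydroxy and amino groups. ACP species and incomplete species are
rejected. The test suite cross-checks formulas and canonicalized SMILES
against ChemmineR/Open Babel when available.

`monoisotopic_mass()` uses CODATA monoisotopic masses; a formula containing
`R` yields a mass flagged `symbolic`.

## 4. Pathway templates

All generators produce elementally balanced `acyl_reaction` objects whose
intermediates are themselves systematic ids, so every step can be re-parsed
and re-balanced.

* **Synthesis** (`generate_fas`): per C2 cycle — malonyl loading onto ACP,
  condensation (decarboxylating; cycle 1 condenses the acyl-CoA primer
  directly, FabH-style), NADPH reduction, dehydration, NADPH reduction —
  then thioesterase release of the free acid. Five reactions per cycle plus
  one release.
* **Elongation** (`generate_elongation`): the same four-step chemistry on
  CoA esters in the ER, 2 NADPH per C2.
* **Desaturation** (`generate_desaturation`): O$_2$/NADH-dependent insertion
  of a cis double bond at a stated position.
* **β-oxidation** (`generate_beta_oxidation`): per cycle — dehydrogenation
  (FAD in mitochondria; O$_2$ → H$_2$O$_2$ in peroxisomes) to the 2E-enoyl,
  hydration to the (S)-3-hydroxy, NAD$^+$ oxidation to the 3-keto, thiolysis
  releasing acetyl-CoA. Pre-existing double bonds arriving at Δ3 insert an
  isomerase step; those arriving at Δ4 (after dehydrogenation forms a 2E,4Z
  diene) insert an NADPH dienoyl reductase plus isomerase. Termination:
  even chains end at acetyl-CoA, odd at propionyl-CoA, iso-branched at
  isovaleryl-CoA. When run over a roster, oxidation of a species stops as
  soon as it reaches a chain already produced by another roster member, so
  shared tails are generated once.
* **Carnitine shuttle** (`generate_carnitine_shuttle`): CPT1, translocase
  (reversible), CPT2.
* **Activation / diffusion** (`generate_activation`, `generate_diffusion`):
  ATP → AMP + PP$_i$ acyl-CoA synthetase; passive membrane transport of
  short free acids.

`lump()` sums a reaction list, cancelling every species not in the `keep`
set, and verifies nothing else remains — the standard way to express a whole
pathway as one net reaction for curation review.

`generate_pathways()` runs the roster configuration shipped in
`inst/extdata/*.tsv` (synthesis primers and compartments, elongation and
desaturation substrates, β-oxidation substrates split by saturation,
shuttle and diffusion species) and `pathway_counts()` tabulates the result by
category.

## 5. Annotation grading and propagation

`grade_record()` assigns one of three levels to a metabolite record:

* **full** — an InChIKey, a single ChEBI or LipidMaps accession, or an id
  that parses to a complete structure;
* **partial** — structure complete except for minor stereo (a hydroxy/amino
  stereo letter, or the carnitine base center);
* **none** — double bond positions/geometry unknown, or nothing parseable.

`extract_pairs()` lists substrate–product acyl pairs across reactions after
removing hub cofactors (CoA, acetyl-CoA, carnitine, ACP) per compartment;
`count_pairings()` cross-tabulates the six grade combinations, showing where
well-annotated chemistry meets poorly annotated chemistry.

`propagate_grades()` runs a breadth-first search from fully annotated,
structurally complete species along two edge types — carrier transfer (same
chain, different class) and ±C2 (elongation/shortening with double-bond
positions shifted) — proposing a systematic shorthand and id for each
reachable unannotated species, with the path recorded for curator review.

## 6. Legacy model migration

`read_metabolite_table()` ingests SBtab-style or BiGG-dump tables;
`alias_table()` declares legacy → systematic renames (an alias may map to
exactly one systematic id; several aliases may collapse onto one id, in which
case `migrate_ids()` merges the records and unions their cross-references and
reports the collision). `write_metabolite_table()` round-trips byte-stably,
so diffs against a curated model stay minimal.

## 7. Verification

The test suite covers golden identifier conversions, randomized codec
round-trips (10,000+ species), elemental-balance checks over hundreds of
generated reactions, mass-conservation identities, closed-form β-oxidation
yields (palmitoyl-CoA: 7 FADH$_2$, 7 NADH, 7 H$^+$, 7 CoA → 8 acetyl-CoA),
brute-force validation of the pairing counter, and byte-stable I/O
round-trips. `scripts/acceptance.R` recomputes the headline pathway
stoichiometries and roster counts at runtime from the installed package.
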