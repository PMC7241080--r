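# acylid

Systematic, machine-readable identifiers and template-generated reactions for
fatty acyl metabolites in genome-scale metabolic models.

## Why

Genome-scale metabolic models accumulate fatty acyl metabolites under ad hoc
names (`ttdca`, `tdcoa`, `c13iso`, …) that encode neither chain length, double
bond positions, functional groups, nor the carrier (free acid, CoA or ACP
thioester, carnitine ester, N-acyl ethanolamine). That makes it impossible to
tell whether two entries are the same molecule, to check elemental balance, or
to extend lipid pathways programmatically. `acylid` implements a systematic
naming scheme in which the identifier *is* the structure:

```
coa18_1_9z        CoA(18:1(9Z))          oleoyl-CoA
fa12_0_11me       FA(12:0(11Me))         C13 iso-branched fatty acid
carn18_1_9z__L    Carn(18:1(9Z))         L-oleoylcarnitine
coa18_1_9z3oh__S  CoA(18:1(9Z,3OH[S]))   (S)-3-hydroxyoleoyl-CoA
```

Chain positions are Δ-numbered from the carboxyl carbon (C1). Because the id
is a lossless encoding of the structure, the package can derive elemental
formulas, monoisotopic masses, and SMILES directly from it, generate entire
β-oxidation / synthesis / elongation pathways by template, and grade + migrate
legacy model annotations onto the systematic scheme.

## What's in the package

- **Species model** — `acyl_species()`, `double_bond()`, `functional_group()`,
  validation and canonical ordering of descriptors.
- **Codec** — `parse_shorthand()` / `format_shorthand()` for the
  lipid-shorthand surface form, `parse_model_id()` / `to_model_id()` for the
  model-id surface form, with inline (`3ohS`) and suffix (`3oh__S`) stereo
  styles and a `legacy_tolerant` dialect (`crn…`, `nae_…`).
- **Chemistry** — `free_acid_formula()`, `conjugate_formula()` under
  configurable protonation conventions, `monoisotopic_mass()` (with a
  pseudo-element `R` for the ACP carrier), and `to_smiles()` for full
  structures including double-bond geometry and R/S stereo.
- **Annotation grading** — `grade_record()` classifies metabolite annotations
  as `full` / `partial` / `none`; `extract_pairs()` + `count_pairings()`
  summarize how annotation quality meets across reactions;
  `propagate_grades()` walks class-transfer and ±2-carbon edges to propose
  systematic ids for unannotated neighbours of fully annotated species.
- **Pathway generation** — `generate_fas()`, `generate_elongation()`,
  `generate_desaturation()`, `generate_beta_oxidation()`,
  `generate_carnitine_shuttle()`, `generate_activation()`,
  `generate_diffusion()`, plus `lump()` to collapse a pathway into one net,
  elementally balanced reaction. `generate_pathways()` runs a full roster
  (shipped in `inst/extdata/`) covering cytosolic and mitochondrial synthesis,
  ER elongation/desaturation, and mitochondrial + peroxisomal β-oxidation.
- **Model I/O** — reaction-formula strings, SBtab-style and BiGG-dump
  metabolite tables, `alias_table()` + `migrate_ids()` for renaming legacy
  models with cross-reference merging.
- **CLI** — `inst/cli/acylid.R` exposes convert / migrate / balance /
  generate / grade / pairs / propagate as a command-line tool.

## Worked example

```r
library(acylid)

s <- parse_shorthand("CoA(18:1(9Z))")
to_model_id(s)
#> [1] "coa18_1_9z"

format_shorthand(parse_model_id("fa12_0_11me"))
#> [1] "FA(12:0(11Me))"

format_formula(conjugate_formula(s, protonation_convention("bigg")))
#> [1] "C39H64N7O17P3S-4"

to_smiles(parse_shorthand("FA(18:1(9Z))"))
#> [1] "O=C(O)CCCCCCC/C=C\\CCCCCCCC"
```

Generate mitochondrial β-oxidation of oleoyl-CoA — the generator inserts the
auxiliary isomerase/reductase steps where the pre-existing Δ9 double bond
meets the β-oxidation machinery:

```r
rxns <- generate_beta_oxidation(parse_model_id("coa18_1_9z"), compartment = "m")
for (r in rxns[1:4]) cat(r$id, ": ", write_reaction_formula(r), "\n", sep = "")
#> BOX_coa18_1_9z_m_c1_dehydrogenate: coa18_1_9z_m + fad_m -> coa18_2_2e9z_m + fadh2_m
#> BOX_coa18_1_9z_m_c1_hydrate: coa18_2_2e9z_m + h2o_m -> coa18_1_9z3oh__S_m
#> BOX_coa18_1_9z_m_c1_oxidize3oh: coa18_1_9z3oh__S_m + nad_m -> coa18_1_9z3o_m + nadh_m + h_m
#> BOX_coa18_1_9z_m_c1_thiolyze: coa18_1_9z3o_m + coa_m -> coa16_1_7z_m + accoa_m
```

Lump the 21-reaction cytosolic synthesis of the C13 iso-branched fatty acid
(primed by isovaleryl-CoA, `coa4_0_3me`) into a single net reaction:

```r
fas <- generate_fas(parse_model_id("coa4_0_3me"), 13, compartment = "c")
net <- lump(fas, c("coa4_0_3me_c", "malcoa_c", "nadph_c", "nadp_c", "co2_c",
                   "coa_c", "h2o_c", "h_c", "fa12_0_11me_c"), id = "fas_net")
write_reaction_formula(net)
#> [1] "4.0 malcoa_c + coa4_0_3me_c + 11.0 h_c + 8.0 nadph_c -> 5.0 coa_c + 4.0 co2_c + 8.0 nadp_c + 3.0 h2o_c + fa12_0_11me_c"
is_balanced(net)
#> [1] TRUE
```

Grade annotations:

```r
g <- grade_record(metabolite_record("coa18_1_9z_c", name = "Oleoyl-CoA",
                                    xrefs = list(ChEBI = "CHEBI:57387")))
cat(g$level, "|", g$rationale)
#> full | unique ChEBI accession CHEBI:57387

g2 <- grade_record(metabolite_record("x_c", name = "Octadecenoyl-CoA (n-C18:1)"))
cat(g2$level, "|", g2$rationale)
#> none | no structure derivable from id or name
```

## Reproducing results

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "acylid", load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

The acceptance script recomputes, from the installed package, the net cofactor
stoichiometry of the lumped iso-branched fatty acid synthesis and elongation
pathways and the reaction counts of the default pathway roster, and writes
them as JSON.

See `vignettes/acylid-methods.Rmd` for the naming grammar, chemistry
conventions, pathway templates, and the annotation-grading procedure in
detail.
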