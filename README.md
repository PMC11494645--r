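# nitrosaminer

Reaction mining for N-nitrosamine chemistry. N-nitrosamines (NSAs,
R2N–N=O) are potentially carcinogenic impurities in pharmaceuticals;
assessing whether they survive a synthesis requires knowing which reagents
and conditions consume the N-nitroso group. `nitrosaminer` is an R package
for building that evidence base from raw reaction records: it curates
reaction tables, validates or generates atom–atom mappings, extracts
reaction centers, decides whether the N–N=O substructure was consumed,
deduplicates, and classifies the surviving reactions into a substrate ×
reagent × transformation reactivity matrix. A seeded synthetic dataset
generator with ground-truth labels stands in for proprietary database
exports, so the whole pipeline is testable offline.

## The method in brief

Each record carries a reaction SMILES `reactants>agents>products`. After
parsing and canonicalisation, a valid atom–atom mapping (a bijection on
heavy atoms joining equal elements) lets the package compute the set of
changed atoms and bonds — the reaction center — and expand it to a
depth-*d* environment (depth 1 by default). The N-nitrosamine query
`[#7;X3]([!#1])([!#1])[#7]=[#8]` is matched against the reactants; the
group counts as **consumed** when a match is altered: a match bond broken
or changed, a match atom lost, or a charge/hydrogen change on a match
atom. Consumed, deduplicated reactions are classified by
precedence-ordered structural rules (denitrosation, hydrazine reduction,
diazonium formation, Fischer–Hepp rearrangement, transnitrosation,
N-nitramine oxidation, …) and tabulated. Stage-wise record losses are
reported as an attrition funnel.

## Worked example

Apply the denitrosation template to N-methyl-N-nitrosoaniline and push the
result through the analysis:

```r
library(nitrosaminer)

m <- apply_template("denitrosation", "O=NN(C)c1ccccc1")
mapped_reaction_smiles(m)
#> [O:1]=[N:2][N:3]([CH3:4])[c:5]1[cH:6][cH:7][cH:8][cH:9][cH:10]1>>
#>   [O:1]=[NH:2].[NH:3]([CH3:4])[c:5]1[cH:6][cH:7][cH:8][cH:9][cH:10]1

v <- fg_consumed(m)
v$consumed
#> [1] TRUE
classify_transformation(m, v)
#> [1] "reduction to amine/denitrosation"
classify_substrate(m$reactants[[1]])$fine_label
#> [1] "alkyl-aryl"
encode_center(expand_center(m, detect_changes(m), depth = 1))
#> [1] "[CH3][N]([c])[N]=[O]>>[CH3][NH][c].[NH]=[O]"
```

The N–N bond breaks (the nitroso nitrogen leaves as HN=O, the parent
amine is regenerated), so the verdict is "consumed" and the rule engine
labels it a reduction to amine/denitrosation. The depth-1 encoding shows
the changed bond's environment on both sides with canonical, map-free
fragments.

A full synthetic study and pipeline run:

```r
ds <- generate_dataset(synthetic_dataset_spec(
  n_per_pair = 8, n_multistep = 20, n_unparseable = 20,
  n_unbalanced = 20, n_spectator = 30, n_duplicates = 25, seed = 42))
res <- run_pipeline(pipeline_config(out_dir = "out"), records = ds$records)
res
#> <pipeline_result>
#>         name input_count kept_count removed_count
#>       curate         355        335            20
#>  single_step         335        315            20
#>      mapping         315        295            20
#>  consumption         295        265            30
#>        dedup         265        240            25
#>     classify         240        240             0
#> mapping success rate: 0.937; classified reactions: 240
```

Each noise type falls at exactly its intended stage, and the 240 clean
records' classification matrix equals the generator's expectation cell for
cell (`res$matrix` vs `ds$truth$expected_matrix`). Artifacts (attrition
JSON/CSV, classified table, matrix in CSV/JSON/text) are written to
`out/`. A thin CLI over the same functions lives at
`inst/scripts/run_pipeline.R` (`generate` and `run` subcommands).

## Configuration

Everything rule-like is an editable YAML file under `inst/extdata/`:
functional-group queries (`fg_queries.yaml`), the 21-class reagent
taxonomy with synonyms (`reagent_classes.yaml`, `reagent_synonyms.yaml`),
the fine-to-coarse substrate mapping (`substrate_coarse.yaml`), and the
generator's template metadata (`templates.yaml`). See the methods
vignette (`vignettes/nitrosamine-reaction-mining.Rmd`) for the model,
its assumptions, and known limitations.
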