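# breedbox

Modern breeding programs run on a central database that tracks germplasm,
trials, crosses and genotypes, and turns those records into decisions —
adjusted means, heritabilities, genomic estimated breeding values, selection
indices. Web platforms that do this well are heavy: a relational server, an
application stack, a deployment. **breedbox** implements the same data model
and analyses as an embedded R package operating on a single portable store
file, for breeders, students and methodologists who want the workflow — and
the quality-control guarantees — at desk scale.

What it covers:

* **Germplasm registry** — accessions with species, passport (MCPD-style)
  properties, synonyms; global name uniqueness on normalized keys; renames
  preserve identity and every link; three-level authorization (`user` /
  `submitter` / `curator` plus per-program roles).
* **Name resolution** — normalization (uppercase, strip ` . - _ /`),
  Levenshtein fuzzy matching, the four-bucket list-validation workflow
  (exact / by synonym / fuzzy / absent) and atomic synonym consolidation.
* **Lists, datasets, wizard** — typed lists, shareable and validated;
  faceted dimension-intersection queries (union within a dimension,
  intersection across, four panels); saved datasets resolved late-bound.
* **Trials** — native generation of alpha lattice, lattice, augmented,
  split-plot, p-rep and Westcott designs with a generic contract checker;
  serpentine/zigzag field coordinates; plot/plant/tissue observation units;
  crop-ontology trait dictionaries; phenotype collection-file
  round-tripping with per-cell scale validation.
* **Crossing** — experiments, the eleven cross types with per-type parent
  rules, configurable cross properties, families, progeny with automatic
  `female/male` pedigrees.
* **Genotyping** — 96/384-well plates, VCF ingestion into per-sample dosage
  documents (biallelic SNPs, ALT-allele counts at any ploidy), dosage
  matrices with mean imputation, VCF/TSV export.
* **Analysis** — trait summaries, robust (MAD) outlier flagging, range
  filters, pairwise-complete correlations, sum-to-zero adjusted means,
  ANOVA heritability, GBLUP with REML-estimated h², standardized selection
  indices; every result storable and reusable as input.
* **Simulator** — a deterministic synthetic breeding program (founders
  under HWE, Mendelian progeny, alpha trials, phenotypes with configured
  plot-basis h²) with known breeding values for end-to-end testing.

The quantitative core in the field's notation: the genomic relationship
matrix is VanRaden method 1, `G = ZZ' / (2 Σⱼ pⱼ(1−pⱼ))` with `Z = X − 2p`;
GBLUP solves `y = 1μ + g + ε`, `g ~ N(0, G σ²g)`, via
`ĝ = G(G + λI)⁻¹(y − μ̂)` with `λ = (1−h²)/h²`; heritability is
`H² = σ²g/(σ²g + σ²e)` from one-way ANOVA mean squares,
`σ²g = (MS_G − MS_E)/r`.

## Worked example

```r
library(breedbox)
st <- create_store()
add_breeding_program(st, "IITA")
add_location(st, "Mokwa", "Nigeria")

# name hygiene: "Tx 303" collides with "TX303" after normalization
rep <- add_accessions(st, data.frame(
  name    = c("TX303", "TMS30572", "Tx 303"),
  species = c("Zea mays", "Manihot esculenta", "Zea mays")))
rep$rejected
#>     name         reason
#> 1 Tx 303 duplicate_name

add_synonym(st, "TX303", "Tx 303")
v <- validate_names(c("TX303", "Tx 303", "TMS3057", "BRANDNEW"), st)
str(v[c("exact", "by_synonym", "absent")])
#> List of 3
#>  $ exact     : chr "TX303"
#>  $ by_synonym: chr "Tx 303"
#>  $ absent    : chr "BRANDNEW"
v$fuzzy[[1]]$candidates          # "TMS3057" is one edit from a known name
#>       name matched_via distance score
#> 1 TMS30572        name        1 0.875
```

A complete simulated program, analysed end to end:

```r
sim <- simulate_program(n_founders = 100, n_crosses = 10,
                        progeny_per_cross = 5, n_markers = 300,
                        reps = 3, seed = 42)
st2 <- sim$store
st2
#> <breedbox store>
#>   organisms: 106 | programs: 1 | locations: 1 | users: 1
#>   accessions: 150 (synonyms: 0) | lists: 0 | datasets: 0
#>   trials: 1 | units: 450 | observations: 450 | traits: 1
#>   crossing experiments: 1 | crosses: 10
#>   genotyping protocols: 1 | plates: 0 | analysis results: 0

h <- heritability(st2, "SIM-T1", "yield")    # simulated at true H2 = 0.5
sprintf("H2 = %.3f (sigma2_g = %.3f, sigma2_e = %.3f)",
        h$H2, h$sigma2_g, h$sigma2_e)
#> "H2 = 0.520 (sigma2_g = 1.171, sigma2_e = 1.079)"

adjusted_means(st2, "SIM-T1", "yield", save_as = "yield-means")
g <- gblup_gebv(st2, "SIM-GBS", result = "yield-means", save_as = "yield-gebv")
sprintf("REML h2 = %.3f; accuracy vs simulated truth = %.3f", attr(g, "h2"),
        cor(g$values, sim$truth$true_breeding_values[names(g$values)]))
#> "REML h2 = 0.934; accuracy vs simulated truth = 0.920"

idx <- selection_index(st2, c(`yield-gebv` = 1))
head(attr(idx, "ranking"), 3)
#>   accession    index rank
#> 1  SIM-F038 2.672835    1
#> 2  SIM-F040 2.109295    2
#> 3  SIM-F032 1.838086    3
```

The heritability estimate sits near the simulated 0.5; the REML h² is
higher because it is fitted on three-replicate adjusted means (entry-mean
scale), and the GEBV ranking feeds straight into a selection index.

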