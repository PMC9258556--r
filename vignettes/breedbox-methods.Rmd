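---
title: "breedbox: models, procedures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{breedbox: models, procedures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedbox)
```

breedbox is a desk-scale re-implementation of the data model and analyses
that web-based breeding database platforms expose: a germplasm registry
with synonym resolution, faceted querying, trial design generation with
phenotype round-tripping, crossing with automatic pedigrees, VCF-backed
genotype storage, and the quantitative-genetics layer (GRM, GBLUP,
heritability, adjusted means, selection indices). This vignette documents
the models and the design choices behind each module, including the
places where the behaviour of the large platforms is under-specified and
we had to pick a rule.

## The store

A store is one in-memory instance of the whole database, serialised to a
single portable JSON file (`save_store()`/`load_store()`). All identity is
by surrogate integer key, so renaming an accession changes only its
display name; every trial plot, cross and genotype record keeps pointing
at the same key. Deletion follows a *restrict* policy: an accession that
is referenced anywhere refuses to die, rather than cascading. Every
created object records the creating username so that the submitter
ownership rule (below) can be enforced.

The organism table ships with a bundled list of roughly one hundred crop
species rather than a full taxonomy download; `add_organism()` and the
`extra_organisms` argument extend it.

### Authorization

Three role levels exist: `user` (read-only), `submitter` (may create
data, and may update or delete only data they themselves own) and
`curator` (unrestricted). Additionally a `program:<name>` role scopes
create/update by a submitter to that breeding program, applied to trials,
crossing experiments and other program-owned objects. `authorize()` is a
pure function of roles and ownership, which makes the allow/deny matrix
enumerable in tests; a useful property that follows from its form is
monotonicity — granting a role never converts an allow into a deny.
Authentication (passwords, sessions) is deliberately out of scope; the
caller asserts a username.

## Name normalization and approximate matching

Most germplasm naming problems are capitalization differences and
separator characters. `normalize_name()` uppercases and strips exactly
the five troublemakers — space, dot, dash, underscore, slash — and leaves
everything else alone; it is idempotent. Global uniqueness of accession
names *and* synonyms is enforced on these normalized keys, so `"Tx 303"`
cannot be created while `"TX303"` exists.

One subtlety: a synonym may legitimately normalize to the same key as its
own accession's name (that is precisely the `"Tx 303"` ~ `"TX303"`
situation). Such a synonym is an alias of the same record, so it does not
violate uniqueness, and we store it verbatim; list validation then
classifies a query that equals a stored synonym string as `by_synonym`
and everything else that is normalization-equal to an accession name as
`exact`.

Approximate matching uses plain Levenshtein distance on normalized keys
(computed with `utils::adist`), with a default cutoff of 2 edits.
Candidates are ranked by ascending distance with lexicographic
tie-breaks; synonym hits rank equally with name hits and are
distinguished by a `matched_via` flag. The similarity score is
`1 - d / max(len(query), len(candidate))`, which is 1 exactly when the
normalized strings are equal. The test-suite checks the distances against
an independently written dynamic-programming implementation. Phonetic or
token-reordering similarity is out of scope.

## Lists, datasets and the wizard

Typed lists are ordered collections of text element names with a type
drawn from a small vocabulary (`accessions`, `trials`, `traits`, `years`,
`locations`, `breeding_programs`, `plots`); they are private to their
owner unless shared. Validation of an accession list runs the full
four-bucket name-resolution partition; other types use exact existence.

The wizard treats the store's plot-level data as a cube: within a
dimension, selected elements combine by union; across dimensions, by
intersection. The engine is generic but the default configuration
exposes at most four selection steps, mirroring the four panels such
interfaces present. Two modelling decisions: *years* are trial years as
integer-valued text, and the *traits* dimension means "has at least one
observation of the trait" (not "trait planned in the design") — the
has-data reading is what makes wizard selections useful as analysis
inputs. A saved selection is a *dataset*; resolution is late-bound, i.e.
re-executed against the current store, so a dataset grows as qualifying
data arrives.

## Trials and phenotypes

Six design types are generated natively rather than delegating to an
external design package, so the constructions are explicit and their
contracts testable (`check_design()` is exported):

* **alpha** — a resolvable incomplete-block design built from a cyclic
  generating array: entry (i, j) of a k × s array falls, in replicate
  l, into block (j − i·l) mod s. Entry labels, block order and
  within-block order are then randomized. Requires k | v and r ≥ 2.
* **lattice** — the square special case v = k².
* **augmented** — checks form a randomized complete block in each of b
  blocks; unreplicated test entries are split as evenly as possible
  across blocks and shuffled within block.
* **split plot** — whole-plot treatments randomized within each
  replicate block, entries randomized within each whole plot; the
  treatment travels in a `treatment` column.
* **p-rep** — ceiling(p·v) randomly chosen entries appear twice, the
  rest once; with more than one block the two copies of an entry land in
  different blocks.
* **Westcott** — the literature leaves this construction loose, so our
  rule is explicit and configurable: unreplicated entries on a grid,
  check columns every `check_interval`-th column (default 3, i.e.
  columns 1, 4, 7, ...), the two checks alternating by row (check 1 on
  odd rows, check 2 on even rows).

All randomization flows through a user-supplied seed with the global RNG
state saved and restored, so the same seed reproduces a layout exactly.
`assign_coordinates()` lays plot numbers onto a grid serpentine-style
(row 2 reversed) or zigzag (every row left-to-right); Westcott layouts
carry their coordinates from the construction.

Plot units are named `<trial>-PLOT_<n>` (the platform convention here is
under-specified; the rule is ours and documented), with plant units
`<plot>_plant_<i>` and tissue samples `<unit>_tissue_<i>` chaining to
their plot — stable, unique, barcode-ready identifiers.

Phenotype *round-tripping* uses a Field-Book style flat CSV: seven
identifier columns then one column per trait variable. Import matches
rows by unit name, validates every cell against the variable's scale
(numeric bounds, ordered categories, ISO-8601 dates), stores valid cells
and reports everything else. The round-trip identity — export, fill,
import, re-export reproduces the file on valid cells — is what makes
offline collection safe, and is asserted byte-for-byte in the tests.
Trait variables follow the crop-ontology structure (trait + method +
scale with a stable identifier) loaded from a TSV dictionary.

## Crossing

Crosses live under a crossing experiment and carry one of eleven types.
The platform literature states parent requirements only for biparental
("both required") and open-pollinated ("female only; the male may be a
population name"); our full table is an explicit interpretation:
biparental, reciprocal and sib require both parents; self, doubled
haploid and bulk-selfed record the female as the male; the bulk,
open-pollinated, polycross and multicross family require the female and
accept an optional male that may be a population name stored as text.
Cross properties (pollination date, tag number, four seed/fruit counts
by default) come from the instance configuration, with counts validated
as non-negative integers.

Progeny creation writes new accessions with the cross's parents as
pedigree links and the cross type recorded, after validating the whole
name batch (a single collision aborts everything). Pedigrees render as
`female/male` with `?` for unknowns and parenthesized recursion at
depth > 1 (`(C/D)/B`); the separator is configurable since the platforms
print "AxB" without committing to a grammar.

## Genotyping

A genotyping protocol is an ordered marker set (sorted by chromosome and
1-based position, VCF convention) plus metadata; per-sample dosages are
stored as named vectors keyed by marker — the document-store analogue of
the JSON-column storage large platforms use. Only biallelic SNPs are
stored; multi-allelic and non-SNP records are skipped and counted at VCF
load. The dosage is the ALT-allele count across arbitrary ploidy (so
0/1/1 → 2 for a triploid banana sample) and any missing allele makes the
whole score missing. Plates are a thin tracking layer: 96 (8 × 12) or
384 (16 × 24) wells, row-major assignment, zero-padded well ids.

The genomic relationship matrix is VanRaden's method 1 with observed
allele frequencies: columns centered at 2p, `G = ZZ' / (2 Σ p(1−p))`,
monomorphic markers excluded from both numerator and denominator. The
platforms name the matrix without fixing a formula; method 1 is the
field's default. GRM computation is restricted to diploid dosages; VCF
export likewise refuses ploidy > 2 (dosage 0/1/2 maps to 0/0, 0/1, 1/1
and missing to ./.), pointing the caller at the dosage TSV export
instead.

## Analyses

All estimators here are declared choices, since the platforms name their
tools without formulas:

* **Summaries** use the sample (n−1) standard deviation and report
  units lacking a value as missing.
* **Outlier flagging** uses the robust z-score |x − median| / (1.4826 ·
  MAD) with a default threshold of 3.5, falling back to the ordinary
  z-score when the MAD is zero; flags are a review list and never mutate
  data.
* **Range filters** return unit-name vectors, so they compose: chaining
  two filters equals intersecting them.
* **Correlations** are pairwise-complete Pearson, with cells backed by
  fewer than 3 complete pairs reported missing.
* **Adjusted means** come from the two-way additive fixed-effects model
  value = μ + genotype + block fitted by least squares with sum-to-zero
  constraints; the adjusted mean of genotype i is μ̂ + ĝᵢ, which on
  balanced complete data collapses to the genotype's arithmetic mean.
  Blocking uses the replicate, which is a complete block in every
  resolvable design we generate.
* **Heritability** is the one-way random-effects ANOVA estimator on
  complete cases: σ²g = (MS_G − MS_E)/r truncated at zero, σ²e = MS_E,
  plot-basis H² = σ²g/(σ²g + σ²e). For unbalanced complete cases r is
  the standard ANOVA coefficient (N − Σnᵢ²/N)/(G − 1), which reduces to
  the replicate count when balanced. The platforms do not say whether
  their tool reports plot-basis or entry-mean-basis H²; we default to
  plot basis and expose entry-mean H² = σ²g/(σ²g + σ²e/r) as an option.
  Phenotypes are never mean-imputed.
* **GBLUP** solves y = 1μ + g + ε with g ~ N(0, G σ²g). Given h², the
  shrinkage is λ = (1 − h²)/h² and ĝ = G·,ₒ (Gₒₒ + λI)⁻¹ (yₒ − μ̂) with
  the GLS intercept, which also yields predictions for genotyped but
  unphenotyped individuals through the off-diagonal G blocks. When h² is
  not supplied it is chosen to maximize the restricted likelihood,
  profiled through one eigendecomposition of Gₒₒ and searched on
  (0.01, 0.99) by `stats::optimize` (golden-section based). A singular
  (G + λI) receives one 1e−8 jitter before erroring.
* **The selection index** standardizes each input to zero mean and unit
  variance over the accessions carrying all inputs, then combines them
  as Σ wₖ zₖ, ranking descending with name tie-breaks. Standardization
  makes the ranking invariant to affine rescaling of any input.
  Inputs may be stored analysis results, so adjusted means and GEBVs
  feed in exactly like primary data.

## The simulator

`simulate_program()` populates a fresh store end to end with known
truth, consuming the same public interfaces as a user (accession upload,
cross and progeny creation, design generation, trial creation, the
observation pathway; genotypes enter through the programmatic
`add_genotypes()` route that `load_vcf()` also uses). The generative
model:

* founder ALT frequencies pⱼ ~ Uniform(0.05, 0.95), dosages
  Binomial(2, pⱼ) (Hardy–Weinberg);
* marker effects uⱼ ~ N(0, σ²g / Σⱼ 2pⱼqⱼ), so that the expected
  realized variance of g = (X − 2p)u across founders equals σ²g — the
  per-marker variance is normalized by the total heterozygosity rather
  than the marker count, which is what makes the σ²g calibration exact
  in expectation;
* progeny by independent Mendelian transmission per marker: each parent
  contributes a Bernoulli(dosage/2) gamete. No linkage map, hence no LD
  beyond pedigree — sufficient for GRM/GBLUP testing, not for
  haplotype-based methods;
* trials are alpha designs (block size 5) over a random entry subset;
  phenotype = μ + g + block + e with block effects N(0, 0.25σ²e) and
  residuals N(0, 0.75σ²e), where σ²e = σ²g(1 − h²)/h², so the total
  non-genetic plot variance matches the configured plot-basis h²;
* one seed drives everything, and the global RNG state is restored
  afterwards; the same seed reproduces a byte-identical store export.

What the simulator does *not* emulate: genotype-by-environment
interaction, spatial field trend, selection across cycles, linkage
disequilibrium, measurement-scale artefacts (all phenotypes are clean
numerics). Passing recovery tests therefore demonstrates correctness of
the estimators under the stated model, not robustness to the messiness
of real field data.

## Problem sizes and numerical choices

The test-suite exercises recovery at the sizes a small program would
recognise: heritability at 200 entries × 3 replicates across 20
simulation seeds (the mean estimate is required to land in [0.4, 0.6]
around a true plot-basis 0.5), and GBLUP at 200 phenotyped founders ×
500 markers with REML-estimated h², required to correlate at least 0.6
with the simulated breeding values. GRM correctness is asserted against
a naive double-loop oracle at 1e−10 and against the hand-computable
2 × 2 example. Edit distances are checked against a dynamic-programming
oracle on hundreds of random short strings. Degenerate inputs are
handled explicitly: zero polymorphic markers, all-missing marker
columns (dropped and reported under mean imputation), MAD = 0 in
outlier flagging, n = 1 standard deviations (reported missing), and
negative variance components (truncated at zero).

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` re-runs all of the
above from scratch against the installed package — the authorization
matrix, wizard-vs-scan agreement on a ~400-plot store, plate capacities,
the GRM examples, both round-trip identities, the design contracts over
ten seeds per type, the heritability and GBLUP recovery, and the
name-resolution checks — and writes each quantity with the problem size
it was computed at.
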