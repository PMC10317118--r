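---
title: "Models and methods behind strpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind strpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

strpanel analyses short tandem repeat (STR) mutation accumulation in
two-founder recombinant inbred (RI) panels such as the BXD mouse family.
Each RI strain descends from an F1 cross of two inbred founders (labelled
B and D) followed by decades of sib-mating, so its genome is a homozygous
mosaic of founder haplotype blocks.  An STR genotype that is homozygous for
an allele matching neither founder is a germline mutation that arose during
inbreeding and drifted to fixation.  The package discovers such mutations,
summarises them into per-strain mutator phenotypes, and maps the loci that
modulate them.  This vignette records the models, the tunable parameters
and the design decisions; the README shows a worked example.

## The synthetic panel generator

Because a real panel requires hundreds of whole genomes, the package ships
a generator that emulates one end to end, at a scale every test can run.

**Breeding.**  Each strain is bred on an explicit two-line pedigree:
generation 1 is the F1 of the two founder stocks, and each subsequent
generation mates the previous generation's two siblings.  Gametes place
crossovers as a Poisson process on the genetic map (Haldane model: no
interference, no sex-specific maps), which is the simplest model that
produces realistic founder block structure.  Sib-mating is simulated
explicitly rather than approximated by instant fixation because mutations
must occur on transmissions and must then drift to homozygosity — the
observable is the *fixed* mutation, and the simulator reproduces exactly
that filtering by drift.  Residual heterozygosity after $t$ sib-mating
generations follows the classical recursion
$H_{t+1} = H_t/2 + H_{t-1}/4$, which the test suite uses as an independent
oracle; 30 generations leave well under 1% of loci unfixed.

**Mutation model.**  At every parent-to-gamete transmission each STR
mutates with probability
$\min(\text{rateCap},\ \text{baseRate}\cdot e^{\text{lengthSlope}\cdot L})$
where $L$ is the transmitting parent's current allele length in bp
(repeat-unit count times motif length).  Step sizes are
$1 + \mathrm{Geometric}(p)$ repeat units — most mutations are a single
unit — and the step is an expansion with probability $\pi_B$ or $\pi_D$
according to the transmitting parent's diploid genotype at a designated
mutator locus (heterozygous parents use the mean, the neutral choice).
Because the rate depends on the *current* (possibly already mutated)
length, alleles can drift over many generations through successive
expansions and contractions.  Defaults
(`baseRate = 1e-4`, `lengthSlope = 0.04` per bp, `rateCap = 0.01`,
`stepGeometricP = 0.8`, $\pi_B = 0.6$, $\pi_D = 0.4$) were chosen once to
give each strain tens to a few hundred fixed mutations at the default
panel scale (5,000 loci, 20–100 generations) — enough statistical power for
every downstream stage.  The per-locus mutation-rate scale of real panels
is not well determined, and these defaults are explicitly for test power,
not rate realism; the *shape* of the model (length dependence, ±1-unit
dominance, expansion bias under genetic control) mirrors what is observed
in rodent STR data.

**Founder panels.**  SNP founder alleles are informative (distinct between
founders) at a configurable fraction of markers (default 0.9, emulating an
LD-pruned informative marker set).  STR founder alleles are 6–20 repeat
units; a configurable fraction (default 0.3) differ between founders by
3–5 units.  The offset is kept at ≥3 units deliberately: polymorphic loci
whose founders differ by a single unit make a ±1 mutation
indistinguishable from the other founder allele, a case the calling rule
must discard, and a realistic panel is dominated by clearly separated
founder alleles.  A fraction of loci (default 0.05) has one founder allele
masked, exercising the modal-allele inference path.  The genetic map is
linear in physical position (default 60 cM per 100 Mb chromosome).  The
generator is autosomal: the chromosome-class stratification in the pattern
module applies to real data carrying X/Y calls, but the breeding simulator
does not model hemizygous transmission.

**Epoch sharing.**  Real panels are bred in epochs, and strains within an
epoch share mutations that arose in the parental stocks ancestral to it.
The generator models this as optional cumulative founder-stock drift:
before each epoch, `stockTransmissionsPerEpoch` rounds of the mutation
process are applied to each founder stock haplotype, so later epochs
inherit all earlier stock mutations and add their own.  The default is 0
(all epochs transmit the reference founder alleles), because the
mutation-calling benchmark is cleanest when "the" founder allele is
unambiguous; analyses of mutation sharing (the PCA) switch it on.

**Rendering.**  Genotype files receive missing calls (default 2%) and
spurious heterozygous STR calls (default 0.5%), the two error channels the
calling rules must tolerate.  Read-level noise and stutter modelling are
out of scope.  What passing tests on these panels do *not* show: robustness
to systematic genotyping bias, reference-alignment artifacts, segmental
duplications, or mutation processes outside the stepwise model.

## Founder inference

SNP calls coded against the founders give per-marker labels: homozygous
matches become B or D; heterozygous calls, calls matching neither founder
and uninformative markers are missing.  Missing labels are imputed with a
two-state hidden Markov model per chromosome: transition probability
between adjacent markers is the Haldane recombination fraction of their cM
distance expanded for RI-by-sibling panels, $R = 4r/(1+6r)$ (the standard
map expansion for an RI family built by sib-mating); emissions match the
state with probability $1-\epsilon$.  The emission error rate
$\epsilon = 0.002$ is a free parameter — the conventional genotype-
probability machinery this replaces does not print its internal value — so
it is surfaced as an argument and logged.  Marginal posteriors come from
forward–backward; a missing label is imputed only when its posterior
exceeds `minProb = 0.5`, and exact ties stay missing.  Observed labels are
never overwritten.

Blocks are maximal runs of identical consecutive non-missing labels
(connected components of the adjacent-identical-label graph).  Unresolved
markers between runs leave gaps; gap loci are attached to the nearest
block edge only at mutation-calling time, and a locus exactly midway
between two blocks is dropped for that strain, because an ambiguous
haplotype of origin would corrupt phase-dependent phenotypes.

Missing founder STR alleles are inferred by the modal rule: among strains
whose local haplotype carries the missing founder, count the distinct
homozygous allele values; if at most one non-modal value is present and
the modal allele is carried by a strict majority, the founder takes the
modal allele, otherwise the locus is dropped.  "Strict majority" resolves
the rule's boundary conservatively; ties drop.

## Mutation calling and filters

A candidate mutation is a homozygous, non-missing strain genotype matching
*neither* founder allele, assigned to the local haplotype block to
determine the founder allele it mutated from.  Genotypes equal to the
other founder's allele are not candidates — they are indistinguishable
from a block misassignment near a recombination breakpoint — which is what
keeps calling precision high at marker-limited block resolution.  The
package also exposes a literal local-founder rule
(`rule = "local-founder"`) for sensitivity analyses.  Heterozygous strain
calls are excluded (enriched for genotyping error and incomplete
inbreeding), as are loci with unresolved founders.

Three filters follow, in order: (1) recurrence — drop every call at a
locus where the identical new allele is carried by more than 10 strains
(such alleles segregate on many backgrounds or reflect founder genotyping
error); the count is per (locus, allele) rather than per locus because
sharing is allele-specific, and the alternative reading is a configuration
switch; (2) outlier strains — a strain whose call count exceeds twice the
median of the other strains in its epoch is excluded entirely; (3) strain
support — strains with fewer than 10 remaining calls are excluded from
phenotypes, since ratios over a handful of mutations are noise.  Their
calls stay in the raw output, flagged.

## Phenotypes and PCA

Per strain: *mutation count* (calls / non-missing genotyped loci),
*mutation size* (mean signed repeat-unit change, separately for expansions
and contractions), *expansion propensity* (fraction of calls with positive
change; undefined at zero calls; contraction propensity is its
complement).  The mutation-sharing PCA builds a strain × (locus, new
allele) indicator matrix — allele-keyed so that distinct new alleles at
one locus are distinct events — centres columns without scaling, and takes
the SVD; component signs are fixed so the largest-magnitude loading is
positive, making score signs reproducible across platforms.

## QTL mapping

The scan is a linear mixed model per marker:
$y = X\beta + u + e$, $\mathrm{var}(u) = \sigma_g^2 \cdot 2K$,
$\mathrm{var}(e) = \sigma_e^2 I$, with $K$ the founder-probability kinship
and the conventional additive multiplier 2 (a flag exposes raw $K$).
Kinship uses leave-one-chromosome-out (LOCO) so the tested marker never
contaminates the covariance.  Under the null (intercept + covariates; the
number of inbreeding generations is always a covariate, since burden
scales with breeding depth), $2K$ is eigendecomposed once per chromosome
and the profiled ML likelihood is maximised over
$h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$ by scalar search on
$[0, 0.99]$ (tolerance $10^{-6}$); a likelihood flat in $h^2$ (identity
kinship) resolves to 0, and residual variances are floored at $10^{-12}$.
$h^2$ is re-estimated per chromosome under the null only, keeping the scan
linear in markers.  LOD is $(n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$
in the rotated, weighted space; markers monomorphic within the analysed
strains are removed first, and a marker collinear with the covariates
scores 0.

Significance thresholds permute the rows of (phenotype, covariates)
jointly against the genotypes and kinship — the generations covariate is a
property of the strain's mutation history and cannot be detached from the
phenotype — re-estimate $h^2$ per permutation, record each permutation's
genome-wide maximum LOD, and take the empirical $(1-\alpha)$ quantile with
linear interpolation (quantile type 7, fixed for cross-implementation
reproducibility).  100 permutations resolve $\alpha = 0.05$ adequately;
fewer than 20 trigger a warning.  Support intervals span the contiguous
run of markers within `drop = 1.5` LOD of the peak, extended by one
flanking marker on each side.

## Mutation-spectrum analyses

Binned rates assign every non-missing genotyped call a parent length — the
founder allele of the strain's local haplotype, in bp (repeat units × motif
length; bp is the primary scale because length thresholds in the
literature are quoted in bp, with repeat-unit binning behind a flag;
default bin width 4 bp) — and compute mutations / calls and expansions /
mutations per bin.  Group contrasts (B vs D haplotype at a focal marker,
overall and per motif-length class, canonical motif, or chromosome class)
pool counts across strains and use the two-sided z-proportion test with
pooled variance; pooling rather than strain-averaging matches how such
tests are applied to mutation sets.  The normal approximation is retained
even at small counts for fidelity to the stated method, with a warning
when an expected cell is below 5.  Motifs are canonicalised to the
lexicographically smallest rotation of the motif or its reverse
complement.  Length trends are Pearson correlations of bin midpoint
against rate with the t-distribution p-value; bins with undefined values
are skipped and fewer than three bins give a missing result.

## Orchestration, formats and reproducibility

`runPipeline()` wires the stages, writes every artifact as plain text
(founder-coded SNP TSV with founder rows, a GangSTR-style VCF 4.2 with
`REPCN` diploid copy numbers and founder alleles in INFO, BED-style block
TSVs, phenotype/scan TSVs with JSON sidecars), and emits a manifest whose
per-stage record counts must reconcile (input = retained + dropped per
reason).  Containers are Bioconductor-native (GRanges,
SummarizedExperiment), so genomic coordinates are 1-based closed
internally; conversion to 0-based half-open happens only at the BED
boundary, preserving the single-convention rule that motivated the
original all-0-based design.  Every stochastic stage takes an explicit
seed; identical config + seed give identical outputs, and the pipeline can
resume from serialized intermediates when the config hash matches.
Filter-sensitivity sweeps (vectors of recurrence / strain-support
thresholds), per-motif-length scans and epoch-subset scans are config
options, since each is a strain or call filter rather than new machinery.

## Problem sizes used in validation

The test-suite and acceptance analyses run at the design scale of 150
strains (five epochs, 20–100 generations), 5 × 200 markers and 5,000 STR
loci for end-to-end checks (single-replicate pipelines take seconds to a
few tens of seconds), with 10 replicate seeds for power, 40 for null
calibration, and small hand-built fixtures for every exact oracle
(enumeration HMM posteriors, brute-force GLS scans, chi-square identities).
Known limitations: two founders only; autosomal breeding; no read-level or
stutter noise; permutation calibration assumes exchangeable strains under
the null, which epoch structure makes only approximately true.
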