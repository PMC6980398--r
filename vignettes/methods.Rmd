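---
title: "Methods: models, parameters and design choices in ageomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in ageomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ageomics` re-implements, as a tested and reusable pipeline, the analysis
pattern of a 2×2 (young/aged × wild-type/heterozygous-mutant) bulk brain
study with three biological replicates per condition: differential
expression with unwanted-variation correction, a multi-contrast pattern
taxonomy centred on age-dependent "inversion" of the mutant effect,
rotation gene-set testing, signed weighted co-expression networks with
cross-network module preservation, promoter motif over-representation, and
peptide-level proteomics. This vignette records the models, the parameters
that matter, and the choices made where the design was genuinely open.

## 1. Differential expression

Counts are filtered at >1.5 CPM (computed on raw library sizes, strict
inequality) in at least 6 of the 12 libraries. TMM normalisation factors are
computed by hand following the published trimmed-mean-of-M-values recipe
(30% trim on M-values, 5% on A-values, inverse asymptotic binomial-variance
weights, factors normalised to zero log-sum; the reference sample is the one
whose 75th-percentile CPM is closest to the mean of those percentiles); the
implementation is cross-checked against edgeR in the test suite.

Log-CPM uses a 0.5-count offset so zeros stay finite, with TMM-scaled
effective library sizes. Unwanted variation is estimated RUVs-style: the
expression matrix is centred within replicate groups (the four condition
groups — centring removes biology by construction), and the first *k* right
singular vectors of the centred matrix become sample-level covariates `W`
(unit-norm, orthogonal, sign fixed by the first element). The default
*k* = 1. `W` enters the linear model as covariates rather than transforming
the counts.

The moderated fit is delegated to limma (cell-means design over the four
conditions plus `W`; four pairwise contrasts): per-gene least squares,
method-of-moments estimation of the variance prior (d₀, s₀²) on log
residual variances, posterior variances
s̃²_g = (d₀ s₀² + d_g s²_g)/(d₀ + d_g), moderated t on d₀ + d_g df, and
Benjamini–Hochberg FDR within each contrast (matching per-comparison DE
counts). The test suite verifies the prior against an independent
root-finding solution of the digamma/trigamma moment equations. A prior df
estimate above 10⁶ is reported as infinite. The fit is ordinary least
squares on log-CPM with eBayes moderation — whether the original analysis
used a mean–variance trend or precision weights is not reconstructable, and
this is the main reconstruction uncertainty of the DE stage. Under a
Gaussian null the moderated p-values are uniform (asserted by
Kolmogorov–Smirnov in the acceptance tests); with negative-binomial counts
at n = 3 per group, small deviations from uniformity are expected and the
null-calibration test instead bounds the count of FDR < 0.05 calls.

## 2. Pattern classification

The four rules operate on the per-contrast tables:

* **inverted** — sign(log₂FC) differs between the two het-vs-wt comparisons,
  with FDR < 0.05 in one and unadjusted p < 0.05 in the other (either
  orientation). Fold-changes of exactly zero carry no sign.
* **inappropriately down-regulated** — FDR < 0.05 with negative log₂FC in
  both het aging and aged het-vs-wt.
* **failure to up-/down-regulate** — FDR < 0.05 in the expected direction in
  normal aging, and *failing* the (FDR < 0.05 and sign) criterion in aged
  het-vs-wt. "Not up-regulated" does not require significance in the
  opposite direction.

Because the published group sizes do not state exclusivity, labels are
assigned by the precedence order inverted > inappropriately down >
failure-up > failure-down (yielding a partition), and the raw, possibly
overlapping sets are attached as an attribute. Two consequences are worth
recording. First, a gene that satisfies the inversion rule usually also
satisfies the inappropriate-down rule (its het-aging fold-change is strongly
negative); precedence resolves this. Second, under the literal failure
rules, a gene that ages identically in both genotypes is "not up-regulated
in aged het vs aged wt" and is therefore classified as a failure gene; this
is a property of the rule, not of the implementation, so classifier
*precision* is only a meaningful recovery metric in simulations that plant
the patterns under test (inverted/failure/inappropriate/null), which is how
the recovery tests are configured.

Sensitivity at the default world (effect 2.0 log₂ units, dispersion 0.1,
n = 3 per group) is bounded by per-contrast FDR detection (~0.93 per
contrast); rules that require two significant contrasts (inappropriate-down,
the aging signature) compound to ~0.86, and the corresponding tests assert
agreement with that product rather than an unattainable higher bound.

Display clustering uses Euclidean distance on the four-contrast log₂FC
vector, complete linkage, deterministic leaf order, and the |log₂FC| > 0.5
display filter (applied as "in at least one comparison").

## 3. Rotation gene-set testing

`roast_test()` and `fry_test()` wrap limma's ROAST (9,999 rotations,
set statistic "mean") and FRY. Up/down proportions use the ±√2 threshold on
moderated z-scores — the convention attached to the "mean" statistic — and
are emitted from the same run as the p-values. The Mixed FDR is BH across
sets. By default all sets share one seeded rotation stream (the seed is
reset before each set) so their p-values are comparable and the FDR is not
inflated by between-set Monte-Carlo noise; this makes set p-values
positively correlated, so calibration experiments that assume independent
sets should pass `share_rotations = FALSE`. Genes missing from the data are
dropped from a set before testing; sets losing all genes are reported
untestable rather than failing. FRY's directional p-value is the analytic
infinite-rotation limit of ROAST's directional (UpOrDown) p-value, which is
the pair asserted to converge in the acceptance tests; the mixed statistics
of the two methods are related but not the same functional.

## 4. Co-expression networks

The signed adjacency is a_ij = ((1 + cor_ij)/2)^β with Pearson correlation
and β = 14; connectivity k_i = Σ_{j≠i} a_ij; genes are kept when k is
strictly above the 10th percentile (type-7 midpoint interpolation; with
several datasets a gene must pass in each). The topological overlap is
TOM_ij = (ℓ_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij) with
ℓ_ij = Σ_{u≠i,j} a_iu a_uj.

Module detection is a **documented variant** of the dynamic-hybrid tree
cut — exact parity with the reference implementation is not promised; the
variant is validated by planted-structure recovery. The average-linkage
dendrogram of 1 − TOM is walked top-down: a node is split while its two
children are separated by more than the PAM assignment distance (mean
cross-child dissimilarity > 0.90, so the children cannot belong to one
module); a cohesive branch is accepted as a module when (i) it has at least
`min_module_size` (40) genes, (ii) its core scatter (mean dissimilarity
among the most-connected half) is below both a deepSplit-dependent fraction
of the dissimilarity range (0.64/0.73/0.82/0.91/0.95 for deepSplit 0–4;
default deepSplit 1) and the absolute PAM distance 0.90, (iii) its mean
intra-branch dissimilarity is ≤ 0.90, and (iv) it is separated from the
rest of the network by a minimum gap. Accepted modules are pruned of members
whose average dissimilarity to the module exceeds 0.90, and the PAM-like
stage attaches unassigned genes to the nearest module when their mean
dissimilarity is ≤ 0.90 (label 0, "grey", otherwise). Modules are numbered
by decreasing size. At 12 samples the 0.90 PAM rule deliberately admits
background genes whose chance correlation with a module factor makes them
co-expressed *in the data*; this is a property of the published constants,
quantified in the design notes of the recovery tests.

Module eigengenes are the first principal components of the standardised
module expression (unit norm, sign aligned with the module mean profile;
variance explained recorded). Module–trait correlations use the hybrid
biweight midcorrelation: median/MAD weights (1 − u²)² with u = (x −
median)/(9 MAD) on continuous sides, Pearson-style mean/sd on sides with
zero MAD or ≤2 distinct values (binary condition indicators), with
unadjusted Student t p-values on n − 2 df. Cross-network module overlap is a
contingency table over ortholog-linked genes with one-sided Fisher exact
p-values and a Sankey-ready node/link export whose weights sum to the
shared-ortholog count.

## 5. Module preservation

Preservation of reference-defined modules in a test network uses a fixed,
documented battery of three density statistics (mean intra-module
correlation, mean intra-module signed adjacency, eigengene variance
explained — computed in the test network on the reference module) and three
connectivity statistics (cross-network correlations of intramodular
connectivity, of eigengene-based connectivity kME, and of the intra-module
correlation entries). The reference method uses a larger, unenumerated
battery, so numerical parity with published tables is not expected; the
subset is validated by planted-structure behaviour. The null permutes which
test-network genes play each module's role (drawn from the whole aligned
universe, module sizes preserved, reference side fixed; 200 permutations);
Z = (obs − mean)/sd per statistic, Z_density and Z_connectivity are medians
of their groups, Z_summary their mean, and the conventional thresholds
apply (<2 none, 2–10 weak-to-moderate, >10 strong). The random baseline
evaluates a 1000-gene uniform pseudo-module exactly like a real module;
between independently simulated networks its expectation is below 2, which
is the quantity the acceptance script recomputes.

## 6. Promoter motifs and over-representation

Promoters are 1500 bp upstream plus 200 bp downstream of the TSS (BED
0-based half-open in, mirrored and reverse-complemented on the minus
strand, truncation at contig edges flagged). Scanning scores every position
on both strands with log₂-odds against a uniform 0.25 background
(probabilities floored at 10⁻⁴; N bases contribute zero); a hit requires a
score of at least 90% of the motif's maximum by default, following the
"90% match" convention — the reference scanner's internal probability
thresholds are not reproduced. Enrichment counts genes with ≥1 hit (not hit
multiplicity) in a one-sided hypergeometric test over the declared
background universe, with Bonferroni adjustment across tested terms;
whether the original analysis used hypergeometric or binomial enrichment is
unstated, and hypergeometric is fixed here. The same function serves flat
GO/KEGG-style annotations consumed as GMT sets.

## 7. Proteomics

Peptide intensities are log₂-transformed and quantile normalised (limma's
implementation; censored entries are excluded from the reference
distribution and interpolated). Censored entries are treated as
left-censored at the per-sample minimum observed intensity and imputed with
a Gaussian accelerated-failure-time regression (survival::survreg) on
sample-level condition covariates where estimable, falling back to an
intercept-only fit; the imputed value is the conditional expectation below
the censor point, μ − σφ(z)/Φ(z), which cannot exceed it. The AFT's
covariates and error family are not stated in the source analysis; the
Gaussian sample-level form is a documented reconstruction. Summarisation is
Tukey median polish (eps 10⁻⁴, 10 iterations, fixed for determinism; the
protein profile is the overall plus column effects, so constant peptide
offsets land in row effects). The two age batches are processed separately
and then combined, quantile-normalised and filtered to complete proteins,
mirroring the two-batch flow forced by an unresolvable batch effect in the
source data. Differential abundance reuses the moderated fit. The
mRNA–protein Spearman correlation is computed over matched pairs of
group-mean log-CPM and group-mean abundance per age group (ties
mid-ranked); a fold-change-based mode is available by passing fold-changes
as the "expression" matrix.

## 8. The synthetic-study generator

The generator's defaults are the stated world of the pipeline: 4000 genes,
3 replicates per condition, planted pattern groups mirroring the published
sizes (63/65/94/26/57 plus a 200-gene aging signature), effect size 2 log₂
units, common NB dispersion 0.1 (var = μ + φμ²; typical bulk brain
RNA-seq), library sizes 1–2 million, one batch level per replicate index
with N(0, 0.3 log₂) per-gene offsets — balanced across conditions so the
RUV stage has signal to remove; the real batch effect's origin is
undescribed, so this is a stand-in, not a reconstruction. Baseline log₂
abundances are N(5, 2), giving a realistic low-count tail; q is
column-normalised so counts are NB(lib·q, 1/φ).

Pattern offset geometry (log₂, e = effect): inverted +e young-het / −e
aged-het; accel_aging +e everywhere except young-wt (the aging offset
arrives early in the mutant); fail_up/down ±e in aged-wt only; inapprop_down
−e in aged-het only; aging_only +e in both aged groups.

Module expression is latent-factor structured: gene g in module m is
λ_g f_m + √(1−λ_g²) ε with loadings uniform around √(module_cor), so the
mean pairwise within-module correlation equals `module_cor` (calibration
asserted at large n). Factors are drawn **orthogonal across samples**: at
n = 12, raw Gaussian factors routinely correlate above 0.5 by chance, which
genuinely merges planted modules in the data and would make recovery
ill-defined. A `preserved_fraction` of modules keep membership, loadings
and factor values in species B (fresh noise); the remaining modules'genes
are scattered over the whole non-preserved + background pool and new
modules of the same sizes are formed there, so (i) species B retains global
module structure and (ii) a dispersed reference module is a uniform random
set with respect to species B — exactly the permutation null, hence
|Z_summary| < 2. Recovery tests use module-dominated compositions (75–90%
of genes in modules), matching networks where detected modules cover most
filtered genes.

Promoters are i.i.d. draws from the stated base composition with one
consensus (or PWM-sampled) occurrence inserted at a uniform position and
strand for the designated fraction of target genes; insertions are recorded.
The shipped `synthetic_motifs.jaspar` (GRE-like palindrome, ETS-like,
homeobox-like) is a synthetic stand-in library, not curated biology; note
the GRE-like motif is its own reverse complement, so its hits appear on
both strands at the same position.

Proteins couple to mRNA through a Gaussian copula: the latent Pearson
correlation is 2·sin(π·ρ_s/6) for a Spearman target ρ_s (default 0.4), the
independent component (gene-level noise plus per-sample wiggle, sd 0.15) is
standardised as a whole and orthogonalised against the mRNA component so
the latent correlation is exact by construction; the observed Spearman is
that target attenuated by count noise and summarisation (a few hundredths)
plus rank-sampling error (sd ≈ 0.06 at 300 pairs). Each protein yields
1 + Poisson(4.3) peptides (≈5.3 on average, the published peptide/protein
ratio), constant peptide offsets, 0.2 sd measurement error, and global
left-censoring at the `censor_quantile`.

What the generator does **not** emulate: read-level sequencing artefacts,
GC/length biases, correlated gene-gene structure inside the count simulator
(counts and the module simulator are separate worlds), spectra-level
proteomics, missingness that is not left-censoring, and sequence evolution
between species. A green recovery test therefore establishes that the
algorithms recover the planted statistical structure — not that they are
robust to every artefact of real data.

## 9. Numerical choices and degenerate inputs

Sub-seeds are derived from the master seed by fixed offsets (kept below
2³¹), so each component is independently reproducible. Strict inequalities
are used for the CPM filter and connectivity percentile (with all-equal
connectivities nothing is removed). Correlations are clipped to [−1, 1]
after BLAS products; adjacency/TOM symmetry is enforced by averaging.
Constant genes are an error in adjacency construction and are dropped with
a warning by the connectivity filter. Zero fold-changes are non-concordant
with any sign. Rotation p-values have granularity 1/(B+1). Median polish
convergence constants (10⁻⁴, 10 iterations) are fixed for determinism; with
an even number of samples the polish can settle in a two-cycle whose
residual medians stay at the 10⁻³ scale. survreg failures fall back to
intercept-only fits and then to censor-point substitution. Fewer genes than
the minimum module size yields an all-grey labelling with a warning; a
module with fewer than three mapped orthologs is flagged untestable rather
than scored.

## 10. Known limitations

* The tree-cut variant and the preservation statistic battery are
  documented re-implementations, not ports; their outputs will not
  numerically match the reference packages on real data.
* At three replicates per condition, rules requiring two significant
  contrasts have compounded sensitivity (~product of the marginals), and a
  moderated t-test at an effect of twice the residual sd has two-sided
  power ≈ 0.70 — both are properties of the design, not of the code.
* The PAM distance 0.90 admits chance-correlated background genes at small
  sample sizes; module assignments at n = 12 should be read accordingly.
* The pipeline assumes the 2×2 design throughout; other designs can reuse
  the component functions but not `run_pipeline()`.
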