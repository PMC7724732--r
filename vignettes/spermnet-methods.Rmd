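---
title: "Methods: integrating multi-trait GWAS and sperm RNA-seq networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating multi-trait GWAS and sperm RNA-seq networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`spermnet` implements a systems-biology pipeline for dissecting semen-quality
traits in breeding boars: single-SNP mixed-model GWAS across 25 correlated
sperm phenotypes, GREML genomic heritability, sperm RNA abundance screens and
trait correlations, an expression GWAS with a phenotype-anchored double
filter, an associated weight matrix (AWM) built around a key phenotype, PCIT
partial-correlation network inference on both SNP effects and RNA
abundances, network intersection and augmentation, and two prediction
layers (an RNA regression model and a SNP panel). This vignette explains the
models, the tunable parameters, the synthetic cohort generator that the
tests run against, and the numerical choices made where the design was open.

## The phenotype panel and its preparation

The panel has 19 measured traits — concentration (CON), viability (VIAB),
osmotic resistance (ORT), head/neck/tail abnormalities (HABN/NABN/TABN),
cytoplasmic droplets (PDROP/DDROP), abnormal acrosomes (ACRO), and the CASA
motility and velocity measures (MT, VAP, VCL, VSL), most recorded after 5
and 90 minutes of incubation — plus six 90 min/5 min ratios (R_MT, R_VAP,
R_VCL, R_VSL, R_VIAB, R_ACRO), 25 traits in all. Ratios are computed from
the raw values before any adjustment. For correlation analyses the traits
are adjusted by ordinary least squares for farm (3 levels), season-year
(9 levels) and boar age (3 levels); `adjust_phenotypes()` returns raw
residuals (Pearson correlations are invariant to the dropped grand mean). A
covariate observed at a single level is dropped, reducing the adjustment to
centering; an aliased design is an error that names the aliased columns.

Ratio traits are heavy-tailed by construction whenever the denominator
trait can approach zero; occasional spurious associations on ratio traits
are expected and are visible in synthetic runs too. The measured traits are
simulated as unbounded Gaussians on the published mean/SD scales, so
percentage traits are not truncated at 0/100 — a deliberate choice that
keeps the QTL effects exactly linear.

## Genotype QC

`apply_qc()` reproduces the standard array filters: samples with call rate
below 96% are excluded; SNPs with minor allele frequency below 0.05, exact
Hardy–Weinberg P ≤ 0.001, more than 5% missing genotypes, or a non-autosomal
(sex chromosome or unplaced scaffold) position are excluded. Boundary
conventions follow the wording of the rules: call rate and MAF exactly at
the threshold are kept, HWE P exactly at the threshold is removed,
missingness exactly at the threshold is kept. The HWE test is the exact
conditional test on the heterozygote count (the test form behind PLINK's
default), verified in the tests against full enumeration for every
genotype table with up to 50 individuals. Because removing SNPs changes
sample call rates (and vice versa), the filter sequence is iterated to a
fixed point, which makes QC idempotent. Linkage disequilibrium is the
squared Pearson correlation of dosages (composite LD, no phasing), with
mean imputation of missing genotypes for that computation only.

## GRM, GREML and the mixed-model scan

The genomic relationship matrix uses the standardized-dosage form
`G_jk = (1/N) Σ_i (x_ij − 2p_i)(x_ik − 2p_i) / (2p_i(1−p_i))` over the
polymorphic SNPs. `greml()` fits `y = Xb + u + e`, `u ~ N(0, G σ_u²)` by
average-information REML in the eigenbasis of G (one symmetric
eigendecomposition per sample set, O(n) per iteration afterwards). AI steps
that leave the parameter space or decrease the restricted likelihood fall
back to an EM step; variance components are floored at `1e-8 · var(y)`;
convergence requires a relative log-likelihood change below 1e-8 (or a
parameter change below 1e-8) within 100 iterations. Standard errors come
from the inverse AI matrix, with the delta method for h². With `G = I` the
two components are confounded; the fit returns a finite boundary solution
and is documented as degenerate rather than an error.

`mlm_assoc()` uses the P3D/EMMAX approximation: variance components are
estimated once under the no-SNP null and reused for every SNP, which makes
the per-SNP test a generalized-least-squares Wald test (exact per-SNP REML
is available behind `exact_reml = TRUE`). The Wald statistic rescales the
null-model covariance by the per-SNP weighted residual variance, so when
`σ_u² = 0` the test is exactly the OLS t-test with `n − p − 1` degrees of
freedom; under a correctly specified V it is t-distributed, which keeps the
empirical type-I error at nominal level (checked at α = 0.05 over 10⁴ null
SNPs). Dosages are centered (the −1/0/1 coding) and mean-imputed. FDR is
Benjamini–Hochberg within trait by default (`pool` option available).
Significant SNPs are chained into QTL intervals per trait and chromosome
while consecutive gaps are shorter than 5 Mbp; a gap of exactly 5 Mbp
starts a new interval (the two natural readings of the rule conflict only
at this boundary; the strict "< 5 Mbp merges" reading was chosen).
Single-SNP intervals are kept but flagged, and excluded from candidate
lists downstream.

## Expression screens

mRNA features are kept when mean FPKM ≥ 10 (boundary kept); miRNAs when
mean CPM > 1 (boundary dropped; a strict per-sample variant is available
since the published rule "higher than 1 CPM in all the samples" admits both
readings). Values are stabilized as `log2(x + 1)`; the pseudo-count is
configurable and defaults to 1 so that zero abundances remain
representable. `expr_variance_components()` fits the crossed random-effects
model (library fixed; gene, gene×farm, gene×year-season, gene×age,
gene×run random) on the long-format library×gene response via `lme4` REML
and reports variance shares. The result is a report only: by default
abundances are not batch-corrected downstream, consistent with the
observation that the gene main effect dominates. Trait–abundance screening
uses Pearson correlation with the exact t-test P-value; pairs with
P ≤ 0.05 are flagged, and per-feature significant-trait counts feed the
network augmentation and panel rules.

## eGWAS and the double filter

`egwas_scan()` regresses each gene's log2 abundance on each SNP's dosage
(no covariates, matching the published model) over the genotyped RNA-seq
samples. FDR is computed within each gene's genome scan by default — each
gene is its own testing family — with a pooled option; the choice is an
open question in the source method and is therefore configurable. Records
are labeled cis when SNP and gene are on the same chromosome within 1 Mbp
(the window only affects labeling). `filter_egwas()` keeps a record only
when the SNP is itself a genome-wide significant GWAS hit (FDR ≤ 0.05) for
some trait and the gene's abundance correlates significantly with that same
trait; the matching trait is annotated.

## AWM and PCIT

`select_awm_snps()` anchors the AWM on the key phenotype VIAB_5 (cell
viability being a prerequisite of fertilization): SNPs with key-trait
P ≤ 0.01 form stage 1; Ap, the mean number of non-key traits associated at
P ≤ 0.01 among stage-1 SNPs, defines stage 2 as SNPs associated with at
least `max(2, ceiling(Ap))` non-key traits. The two stages are united by
default (`sequential` intersects them; the source text underdetermines the
interplay). SNPs closer than 2500 bp to, or farther than 1 Mbp from, the
nearest annotated gene are kept and assigned to that nearest gene
(strict inequalities at both bounds); one SNP per gene survives — the one
with the smallest key-trait P. The AWM cell is the SNP's signed additive
effect for each trait, z-scored within trait columns.

`pcit_filter()` implements the partial-correlation-with-information-theory
edge filter: for every feature trio the three first-order partial
correlations are formed, the trio tolerance ε is the mean of the absolute
partial/direct ratios (ratios with |direct| < 1e-12 are skipped), and an
edge is eliminated when its correlation is, within some trio, at or below ε
times both other correlations (ties eliminate; absolute values throughout,
since signed ratios can produce negative tolerances). Surviving edges with
correlation-test P ≤ 0.05 are significant; the significance filter is
applied after elimination (switchable). The O(n³) core is compiled C++;
the tests hold it to exact agreement with an independent triple-loop R
oracle on hundreds of random instances. The same filter builds the SNP
network (AWM rows over 25 trait observations), the RNA network (genes over
samples), and the miRNA–gene edges, of which only significant negative
correlations are kept.

## Networks

The shared network is the edge-wise intersection of the SNP and RNA
networks — gene pairs supported by both co-association and co-abundance —
with incident nodes. The final network adds genes absent from the shared
network that correlate with more than three phenotypes (the companion
abstract says "more than four"; the Methods wording "more than three" is
implemented and the threshold is configurable), together with their RNA
network edges ("their co-associated genes" is read as RNA-network
neighbors, since the SNP network lacks most of them), and the negative
miRNA–gene edges touching final-network genes. Node attributes carry the
number of significantly correlated traits, the top trait (maximum |r|,
ties broken lexicographically), the TF/TF-cofactor class, and shared-network
membership; exports are SIF and GraphML (byte-stable).

## Prediction layers

`candidate_gene_pool()` applies the reproducible filters — correlated with
at least four phenotypes, mutually non-adjacent in the final network,
abundance above 0 in every RNA sample — with the literature-driven ranking
supplied by the caller as `manual_list`. `all_subsets_r2()` evaluates the
OLS R² of every nonempty subset (refusing pools above 20 predictors);
`select_common_genes()` takes, per trait and model size, the best-R² subset
(ties: lexicographically smallest) and tallies gene occurrences across all
traits' best models; `stepwise_fit()` runs forward–backward stepwise OLS
with entry/stay P thresholds of 0.15 (the SAS PROC REG STEPWISE defaults,
since the source names the procedure without settings) on the raw,
unadjusted abundances — "unadjusted" is taken literally, so raw FPKM feeds
the RNA model. The SNP panel unions the GWAS interval lead SNPs, the
per-gene lead SNPs of the filtered eGWAS records, and, for each shared
network gene correlated with ≥ 4 phenotypes, its most significant GWAS SNP
within 1 Mbp; duplicates carry all source tags; only autosomal SNPs enter.
`panel_variance_explained()` estimates each trait's variance captured by
the panel via GREML on the panel-restricted GRM, with the same fixed
covariates as the GWAS.

## The synthetic cohort generator

Real genotypes, phenotypes and sperm RNA-seq for this design are not
redistributable, so the package ships a generator whose defaults emulate
the study conditions at desk scale: 300 boars, 5000 autosomal SNPs in
10-SNP LD blocks (latent gamete AR(1) correlation 0.8, allele frequencies
uniform on [0.05, 0.5], 1% missingness), the fixed 25-trait panel with the
published means, SDs and heritabilities, farm/season-year/age at 3/9/3
levels, 500 genes and 40 miRNAs with RNA-seq in 40 samples. LD is a
block-wise Gaussian copula on haplotypes — simple and controllable, since
the source describes none. The polygenic term is drawn from
`N(0, G σ_u²)` with the realized GRM, which makes GREML recovery
well-posed. Planted structure comprises: six single-trait QTL
(0.50–0.60 SD per SD of dosage) for clean effect-recovery checks; four
pleiotropic QTL touching the key phenotype VIAB_5 arranged in two pairs
with matching trait profiles, each anchored inside a co-expressed gene, so
that the pipeline's shared network has true positives; expression–trait
correlations at r = ±0.45–0.5 via a Gaussian copula against the trait's
non-environmental component (the log2 abundance is linear in the latent, so
the planted r is exact in expectation); two strong eQTL (latent r = 0.85)
on single-loading genes whose trait matches the QTL's, giving the eGWAS
double filter true positives; and negative miRNA–target loadings
(r = −0.6). A configurable fraction (default 20%) of features is simulated
below the abundance screens.

What the generator does **not** emulate: realistic allele-frequency
spectra and LD decay, pedigree/population structure, count-based
sequencing noise (abundances are exactly log-normal), bounded percentage
traits, and trait–trait residual correlations beyond those induced by
shared QTL (the source never states the full trait covariance). Passing
tests therefore demonstrate correctness of the algorithms under the
generative model's assumptions, not robustness to everything real sperm
RNA-seq data can do.

## Problem sizes and numerical choices

The test-suite and acceptance-script problem sizes are the package's
choices for a reproducible desk-scale study: the end-to-end run uses the
default 300 × 5000 cohort; GREML recovery uses n = 500 with 2000 SNPs and
h² ∈ {0, 0.2, 0.4, 0.8}; calibration uses 10⁴ null SNP tests at n = 300;
the all-subsets pool in the end-to-end run is capped at 12 genes (4095
subsets per trait; the operation itself allows 20). Sub-seeds for
independent stages are derived by fixed offsets from the user seed, and
every generator call is reproducible from `SimConfig$seed` alone — two
pipeline runs with the same configuration produce byte-identical output
files.

Known limitations: GREML standard errors come from the AI matrix and are
slightly optimistic near the h² boundary; the P3D approximation
understates per-SNP variance-component uncertainty (the standard trade-off
of EMMAX-class methods); PCIT is O(n³) in features and the package applies
it to AWM- and screen-reduced gene sets, not to hundreds of thousands of
SNPs; and with 25 trait observations per AWM row, SNP-network edges carry
substantial sampling noise, so shared-network membership — by design an
intersection — is the robust signal, not individual SNP-network edges.
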