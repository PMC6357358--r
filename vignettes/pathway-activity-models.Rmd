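---
title: "Pathway activity scoring and drug-sensitivity models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway activity scoring and drug-sensitivity models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathdrive)
```

## The problem

Predicting how a cancer cell line responds to a drug from its transcriptome
is usually attempted gene by gene: a penalized regression of log-IC50 on
thousands of individual expression values. Such models are hard to interpret
and fragile, because drug response is modulated by the coordinated behaviour
of many genes. pathdrive implements the alternative: compress each
pre-defined pathway (gene set) into a single per-sample *activity score*,
and regress drug response on the pathway activities instead. The package
covers the whole workflow — scoring, collection diagnostics, model fitting,
and mechanistic evaluation of the selected pathways — plus a synthetic-data
generator that makes every stage testable without proprietary cell-line
data.

## The four scorers

All four scorers are unsupervised and single-sample: they need only the
expression matrix and the gene sets, never phenotype labels. Input is a
genes x samples matrix of *log-scale* expression (the loaders never
transform values; normalization and log-transformation are the caller's
job).

**DiffRank** (competitive, rank-based). Within each sample, genes are
ranked in descending expression order (rank 1 = highest); ties get average
ranks so the per-sample rank sum is exactly $G(G+1)/2$. For a pathway with
$n_1$ members and $n_2 = G - n_1$ non-members,

$$\mathrm{DiffRank} = \frac{1}{n_1}\sum_{i \in \text{members}} r_i \;-\;
\frac{1}{n_2}\sum_{j \notin \text{members}} r_j .$$

Scores lie in $[-G/2, +G/2]$ and are invariant under any strictly monotone
transformation of a sample's expression values. Note the orientation of the
literal formula: because rank 1 is the *highest* expression, a highly
expressed pathway scores *negative*. We implement the formula literally and
expose `orient = "high_positive"` to negate scores when a
"higher score = higher activity" reading is wanted; nothing downstream
depends on the choice, since the elastic net is sign-agnostic. Average
ranks (rather than competition ranks) were chosen because the statistic
averages ranks, and average ties keep the rank-sum identity
$n_1\bar r_1 + n_2\bar r_2 = G(G+1)/2$ exact.

**Combined Z-score** (self-contained). Each gene is standardized across
samples and a pathway's activity is $\sum_i z_i / \sqrt{n_1}$ over its
members — the classic Stouffer-style combination, which has unit variance
under independent members. We use $\sqrt{n_1}$ scaling (not the mean)
because that is the convention of the combined-Z pathway literature.
Zero-variance genes contribute $z = 0$.

**PLAGE** (self-contained). The member-gene submatrix is standardized per
gene and the activity vector across samples is the dominant right singular
vector — the "meta-gene" of the pathway. The vector has unit Euclidean
norm; since an SVD sign is arbitrary, we fix it so the activity correlates
non-negatively with the mean standardized member profile (tie: first
non-zero entry positive). This makes results deterministic across LAPACK
implementations.

**GSVA** (competitive, rank-based). Four stages: (1) a per-gene Gaussian
kernel CDF estimate $\hat z_{gj} = \frac1n\sum_k \Phi\!\big((x_{gj} -
x_{gk})/h_g\big)$ with bandwidth $h_g = s_g/4$ by default; (2) per sample,
kernel scores become descending ranks, symmetrized to weights
$w_{gj} = |G/2 - \mathrm{rank}_{gj}|$ raised to the exponent $\tau$
(default 1); (3) a Kolmogorov–Smirnov-like random walk down the ranked
list, adding normalized member weights and subtracting $1/(G-n_1)$ at
non-members; (4) the enrichment score, either maximum positive plus minimum
negative deviation (default) or the single largest-magnitude deviation.
Scores are bounded in $[-1, 1]$. Zero-variance genes get a bandwidth floor
of $10^{-8}$ times the global sd so the kernel stays defined. Walk ties in
the kernel ranks are broken by gene order, which keeps the scorer fully
deterministic.

Member genes absent from the expression matrix are dropped per set (counts
reported); sets left without usable members — or, for the competitive
scorers, sets covering the entire universe — are omitted with a warning.
The gene universe is always the rownames of the supplied expression matrix:
the competitive scorers need a well-defined non-member set, and the
expression matrix is the only principled universe available.

## Collection diagnostics

`jaccard_matrix()` quantifies pairwise overlap of the collection;
`filter_genesets()` applies the conventional `[5, 200]` size window
(inclusive). The filter defaults to database sizes (pre-intersection)
because size filters are conventionally stated against the curated
collection; `restrict_to_universe = TRUE` switches to effective
(expression-measured) sizes. Filtering is idempotent.

**MACC** — the median of absolute pairwise Pearson correlations among a
pathway's members — measures co-expression coherence.
`macc_permutation_test()` asks whether a pathway is more coherent than
chance. Two null schemes are offered because "shuffling" is genuinely
ambiguous:

* `gene_resample` (default): random same-size gene sets from the universe.
  This preserves the background correlation structure of the data, so a
  pathway must beat *typical* gene-gene correlation, not just independence.
* `within_gene_shuffle`: permute each member gene's values across samples,
  destroying all inter-gene correlation — the literal reading of shuffling
  expression across samples. Under this null virtually any co-regulated set
  is significant, which is why it is not the default.

p-values are `#(permuted >= observed) / n_perm` with no pseudocount (so 0
is attainable), ties counting toward the numerator (conservative). Results
are bit-reproducible given `(seed, n_perm, scheme)`.

## The response model

`fit_elastic_net_cv()` regresses a drug's log-IC50 on the pathway
activities with the elastic net, delegating the coordinate-descent solver
to glmnet and owning everything around it. The penalty is

$$\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i\beta)^2 +
\lambda\Big(\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\Big),$$

searched over the default grid of 10 α values equally spaced on
$[0.2, 1]$ times 250 λ values log-equally spaced on $[e^{-6}, e^{5}]$
(2500 settings) with 10-fold cross-validation. Log-equal spacing is the
only sensible reading of an exponential-endpoint range. Design choices that
matter for reproducibility:

* **Folds** are a deterministic hash of sample id and `fold_seed`, dealt
  round-robin after sorting by hash — so the fit is invariant to input row
  order, and folds are assigned once and reused across all 2500 grid
  points.
* **Tie-breaking** on the CV surface (minima within 1e-12): prefer larger
  λ (sparser), then larger α — parsimony.
* **Standardization** of features is on by default (the solver's
  convention); coefficients are reported on the original feature scale.
* Samples with missing response are dropped per drug; missing feature
  values are an error (the scorers never produce them for retained
  pathways).

The fit returns a classed object (`pd_enet`) with `print`, `summary`,
`coef`, `predict`, `plot` (CV surface) and `residuals` methods;
`nonzero_features()` lists the selected pathways, signed-descending for
waterfall-style ranking. `write_model()`/`read_model()` serialize fits to a
key-value text format.

## Evaluation against drug-gene annotations

`categorize_pathway()` maps each selected pathway to one of five mutually
exclusive categories given a drug's annotated targets, transporters and
metabolic enzymes: `target_plus` (target plus at least one transporter or
enzyme), `target_only`, `enzyme_only`, `transporter_only`, `none`. Target
presence dominates. A non-target pathway containing both an enzyme and a
transporter is not covered by the four published color rules; we assign
`enzyme_only` with a warning rather than invent a fifth category.
`count_drug_related_pathways()` counts all nonzero-coefficient pathways
(no top-N cut: the selection is already sparse).

`sensitivity_group_ttest()` contrasts a pathway's activity between the k
most sensitive (lowest IC50) and k most resistant samples (default
k = 20), Welch's t-test by default since equal group variances are not
guaranteed; Student's variant is available. IC50 ties at the boundary break
by stable sample-id order, keeping groups deterministic.

`compare_methods()` ranks scorers per drug by CV MSE; MSEs tied to within
1e-12 share the better rank (logged), and rank-1/rank-2 counts are
aggregated per method.

## The synthetic-data generator

`simulate_dataset()` emulates the latent-factor structure the workflow
assumes. Per pathway, a latent activity $a_{ps} \sim N(0,1)$; a member gene
follows $x_{gs} = \mu_g + w_g a_{ps} + \varepsilon$ with
$w_g \sim N(1, 0.25^2)$, $\varepsilon \sim N(0, 0.3^2)$ and baseline
$\mu_g \sim N(6, 1)$ (a realistic log2 microarray scale); genes in several
pathways sum their loading terms. A synthetic drug's response is a sparse
linear function of 5 latent activities with coefficient magnitude 1, random
signs, plus $N(0, 0.5^2)$ noise. Defaults are 2000 genes, 300 samples and
100 pathways with sizes uniform on [5, 25], built disjointly (sizes are
capped so the disjoint construction fits the universe); a positive
`overlap_fraction` draws part of each set from a small shared pool, which
raises expected Jaccard overlap monotonically without attempting exact
overlap control. Everything is deterministic given the seed.

What the generator does *not* emulate: heavy-tailed and platform-specific
noise, correlated non-member background, nested or topology-structured
pathways, batch effects, and realistic multi-drug pharmacology. Passing the
end-to-end recovery tests therefore shows the pipeline is *correct* under
its own model assumptions, not that it attains any particular accuracy on
real cell-line panels.

## Numerical choices and degenerate inputs

* Ranks: average ties everywhere (exactness of the rank-sum identity).
* Zero-variance genes: z = 0 (Z-score), standardized row of zeros (PLAGE),
  bandwidth floor (GSVA), dropped with a warning (MACC, where a
  correlation is undefined).
* A pathway whose member submatrix is entirely zero after standardization
  scores 0 (PLAGE) with a warning.
* glmnet is run with a log-densified, warm-start-extended λ path and
  convergence threshold 1e-10 so that single-λ requests (e.g. the
  vanishing-penalty limit) are accurate; requested λ values are extracted
  exactly from the fitted path, never interpolated.
* All scorers and fits are deterministic: two runs on identical input are
  bit-identical.

## Problem sizes used in the validation suite

The test suite verifies the scorers against independently coded
step-by-step oracles (1000 random DiffRank instances at up to 50 genes;
100 instances each for Z-score, PLAGE and GSVA at up to 20 genes x 10
samples), calibrates the permutation p-values on i.i.d. noise (200
repetitions at 200 permutations), and runs the full recovery pipeline at
the generator's default scale (2000 genes x 300 samples, 100 pathways, 5
causal). `scripts/acceptance.R` re-runs that pipeline from scratch — four
scorers, per-drug elastic nets over the full 2500-point grid for four
synthetic drugs, MACC tests at 1000 permutations — and reports the
recovery, coherence and comparison quantities it computes.

On this Gaussian latent-factor data the self-contained scorers (PLAGE in
particular) typically achieve the lowest CV MSE: the latent activity *is* a
linear factor of the member genes, which is exactly PLAGE's model. The
relative advantage of competitive, rank-based scorers on real expression
data — robustness to normalization and background shifts — is precisely
what the simplified generator does not simulate, so method rankings on
synthetic data should not be read as statements about real panels.

## Known limitations

* GSVA's kernel stage is $O(G n^2)$; at very large sample counts a
  subsampled or binned kernel CDF would be needed.
* The permutation test reports raw p-values only; multiple-testing
  correction across pathways is left to the caller.
* Only linear elastic-net response models are provided, by design; other
  learners are out of scope.
* The GMT dialect is the tab-separated Broad form; other gene-set carriers
  must be converted first.
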