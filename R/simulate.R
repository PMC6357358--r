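#' Configuration for the latent pathway-activity simulator
#'
#' The generator emulates the structure the pathway-scoring and response
#' models assume: each pathway has a latent per-sample activity
#' `a[p, s] ~ N(0, 1)`; a member gene g of pathway p follows
#' `x[g, s] = mu_g + w_g * a[p, s] + eps` with loading
#' `w_g ~ N(loading_mean, loading_sd^2)` and noise `eps ~ N(0, noise_sd^2)`
#' (genes in several pathways sum their loading terms); non-members are
#' `mu_g + eps`. One synthetic drug's log-IC50-like response is a sparse
#' linear function of a few latent activities plus noise.
#'
#' Defaults: 2000 genes, 300 samples, 100 pathways with sizes uniform in
#' `[5, 25]` built disjointly (so they fit in the gene universe), baseline
#' `mu_g ~ N(6, 1)` on the log scale, loadings `N(1, 0.25^2)`, expression
#' noise sd 0.3, 5 causal pathways with coefficient magnitude 1 and random
#' signs, response noise sd 0.5.
#'
#' @param n_genes,n_samples,n_pathways problem dimensions.
#' @param size_range integer vector `c(min, max)` of set sizes (min >= 2).
#' @param overlap_fraction fraction of each set drawn from a small shared
#'   gene pool, in `[0, 1)`; 0 builds strictly disjoint sets.
#' @param loading_mean,loading_sd member-gene loading distribution.
#' @param noise_sd expression noise standard deviation.
#' @param baseline_mean,baseline_sd per-gene baseline expression
#'   distribution.
#' @param n_causal number of causal pathways per drug (<= n_pathways).
#' @param causal_weight magnitude of the causal response coefficients.
#' @param response_noise_sd response noise standard deviation.
#' @param seed integer seed; the full dataset is deterministic given the
#'   seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_samples = 300L, n_pathways = 100L,
                       size_range = c(5L, 25L), overlap_fraction = 0,
                       loading_mean = 1, loading_sd = 0.25, noise_sd = 0.3,
                       baseline_mean = 6, baseline_sd = 1,
                       n_causal = 5L, causal_weight = 1,
                       response_noise_sd = 0.5, seed = 1L) {
  stopifnot(size_range[1L] >= 2L, size_range[2L] >= size_range[1L],
            overlap_fraction >= 0, overlap_fraction < 1,
            n_causal <= n_pathways, noise_sd >= 0, loading_sd >= 0,
            response_noise_sd >= 0)
  if (size_range[1L] > n_genes) stop("smallest set size exceeds n_genes")
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 n_pathways = as.integer(n_pathways),
                 size_range = as.integer(size_range),
                 overlap_fraction = overlap_fraction,
                 loading_mean = loading_mean, loading_sd = loading_sd,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, n_causal = as.integer(n_causal),
                 causal_weight = causal_weight,
                 response_noise_sd = response_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

.sim_ids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

#' Generate synthetic gene sets
#'
#' Sizes are uniform over `size_range`. With `overlap_fraction = 0` sets are
#' built disjointly from a random permutation of the gene universe (all
#' pairwise Jaccard indices are 0); with positive overlap, a fraction of each
#' set is drawn from a small shared pool, so expected pairwise overlap grows
#' monotonically with `overlap_fraction`.
#'
#' @param config a [sim_config()].
#' @return A `gene_set_collection` of `n_pathways` sets.
#' @export
generate_genesets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed + 11L, {
    genes <- .sim_ids("g", config$n_genes)
    sizes <- config$size_range[1L] - 1L +
      sample.int(config$size_range[2L] - config$size_range[1L] + 1L,
                 config$n_pathways, replace = TRUE)
    perm <- sample(genes)
    pool_size <- if (config$overlap_fraction > 0) {
      min(config$size_range[2L], config$n_genes - 1L)
    } else 0L
    pool <- if (pool_size > 0L) perm[seq_len(pool_size)] else character(0)
    rest <- perm[setdiff(seq_along(perm), seq_len(pool_size))]
    cursor <- 0L
    sets <- vector("list", config$n_pathways)
    for (p in seq_len(config$n_pathways)) {
      k_sh <- min(floor(config$overlap_fraction * sizes[p]), pool_size)
      k_un <- sizes[p] - k_sh
      if (cursor + k_un > length(rest)) {
        stop("infeasible config: gene universe exhausted while building ",
             "disjoint set members")
      }
      shared <- if (k_sh > 0L) sample(pool, k_sh) else character(0)
      sets[[p]] <- c(shared, rest[cursor + seq_len(k_un)])
      cursor <- cursor + k_un
    }
    names(sets) <- .sim_ids("pw", config$n_pathways)
    gene_sets(sets)
  })
}

#' Generate a synthetic expression matrix with latent pathway activity
#'
#' @param genesets a `gene_set_collection` (typically from
#'   [generate_genesets()]).
#' @param config a [sim_config()].
#' @return List with `expression` (genes x samples matrix), `activity`
#'   (pathways x samples latent truth) and `loadings` (per-pathway named
#'   loading vectors).
#' @export
generate_expression <- function(genesets, config) {
  stopifnot(inherits(genesets, "gene_set_collection"),
            inherits(config, "sim_config"))
  .with_seed(config$seed + 22L, {
    genes <- .sim_ids("g", config$n_genes)
    samples <- .sim_ids("s", config$n_samples)
    P <- length(genesets$sets)
    A <- matrix(stats::rnorm(P * config$n_samples), P, config$n_samples,
                dimnames = list(names(genesets$sets), samples))
    mu <- stats::rnorm(config$n_genes, config$baseline_mean,
                       config$baseline_sd)
    X <- mu + matrix(stats::rnorm(config$n_genes * config$n_samples,
                                  sd = config$noise_sd),
                     config$n_genes, config$n_samples)
    dimnames(X) <- list(genes, samples)
    loadings <- vector("list", P)
    names(loadings) <- names(genesets$sets)
    for (p in seq_len(P)) {
      m <- genesets$sets[[p]]
      w <- stats::rnorm(length(m), config$loading_mean, config$loading_sd)
      names(w) <- m
      loadings[[p]] <- w
      X[m, ] <- X[m, ] + w %o% A[p, ]
    }
    list(expression = X, activity = A, loadings = loadings)
  })
}

#' Generate synthetic drug responses from latent activities
#'
#' Each synthetic drug's response is
#' `y_s = sum over causal pathways of beta_p * a[p, s] + eta`, with
#' `|beta_p| = causal_weight`, random signs, and
#' `eta ~ N(0, response_noise_sd^2)`.
#'
#' @param truth output of [generate_expression()] (needs `$activity`).
#' @param config a [sim_config()].
#' @param n_drugs number of independent synthetic drugs (default 1), each
#'   with its own causal pathway draw.
#' @return Numeric matrix, samples x drugs; attribute `"causal"` is a named
#'   list per drug of `data.frame(pathway, weight)`.
#' @export
generate_response <- function(truth, config, n_drugs = 1L) {
  stopifnot(inherits(config, "sim_config"), is.matrix(truth$activity))
  A <- truth$activity
  .with_seed(config$seed + 33L, {
    drugs <- sprintf("drug%02d", seq_len(n_drugs))
    Y <- matrix(NA_real_, ncol(A), n_drugs,
                dimnames = list(colnames(A), drugs))
    causal <- vector("list", n_drugs)
    names(causal) <- drugs
    for (d in seq_len(n_drugs)) {
      pw <- sample(rownames(A), config$n_causal)
      beta <- config$causal_weight * sample(c(-1, 1), config$n_causal,
                                            replace = TRUE)
      Y[, d] <- drop(crossprod(A[pw, , drop = FALSE], beta)) +
        stats::rnorm(ncol(A), sd = config$response_noise_sd)
      causal[[d]] <- data.frame(pathway = pw, weight = beta,
                                stringsAsFactors = FALSE)
    }
    attr(Y, "causal") <- causal
    Y
  })
}

#' Generate a complete synthetic dataset
#'
#' Bundles [generate_genesets()], [generate_expression()] and
#' [generate_response()] under one seed.
#'
#' @param config a [sim_config()].
#' @param n_drugs number of synthetic drugs (default 1).
#' @return Object of class `synthetic_dataset`: `expression`, `genesets`,
#'   `response`, `activity` (latent truth), `loadings`, `causal`.
#' @export
simulate_dataset <- function(config = sim_config(), n_drugs = 1L) {
  gs <- generate_genesets(config)
  tr <- generate_expression(gs, config)
  y <- generate_response(tr, config, n_drugs = n_drugs)
  structure(list(expression = tr$expression, genesets = gs,
                 response = y, activity = tr$activity,
                 loadings = tr$loadings, causal = attr(y, "causal"),
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d genes x %d samples, %d pathways, %d drug(s)\n",
    nrow(x$expression), ncol(x$expression), length(x$genesets$sets),
    ncol(x$response)))
  cat("  causal pathways per drug:",
      paste(vapply(x$causal, function(d) paste(d$pathway, collapse = ","),
                   character(1)), collapse = " | "), "\n")
  invisible(x)
}
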