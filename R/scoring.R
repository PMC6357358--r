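#' Rank genes within each sample
#'
#' Genes are ranked in descending order of expression within every sample:
#' rank 1 is the most highly expressed gene. Ties receive the average of the
#' tied rank positions, which keeps the per-sample rank sum exactly
#' `G(G+1)/2`.
#'
#' @param expr numeric matrix, genes x samples, all values finite.
#' @return Numeric matrix of ranks with the same dimnames.
#' @examples
#' m <- matrix(c(5, 3, 1), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
#' rank_genes_per_sample(m)
#' @export
rank_genes_per_sample <- function(expr) {
  stopifnot(is.matrix(expr), nrow(expr) >= 2L)
  if (!all(is.finite(expr))) stop("expression contains non-finite values")
  r <- apply(expr, 2L, function(col) rank(-col, ties.method = "average"))
  dimnames(r) <- dimnames(expr)
  r
}

# Resolve a collection against the expression universe. Members absent from
# the matrix are dropped per set (counts reported via message); sets left
# empty are skipped with a warning. Returns row-index vectors per retained
# set.
.resolve_sets <- function(genesets, gene_ids, require_nonmember = FALSE) {
  stopifnot(inherits(genesets, "gene_set_collection"))
  idx <- lapply(genesets$sets, function(m) {
    i <- match(m, gene_ids)
    i[!is.na(i)]
  })
  lost <- geneset_sizes(genesets) - lengths(idx)
  if (any(lost > 0L)) {
    message(sum(lost), " member gene(s) absent from the expression matrix ",
            "were dropped across ", sum(lost > 0L), " set(s)")
  }
  drop <- lengths(idx) == 0L
  if (require_nonmember) {
    drop <- drop | lengths(idx) >= length(gene_ids)
  }
  if (any(drop)) {
    warning("omitting ", sum(drop), " set(s) with no usable members",
            if (require_nonmember) " (or covering the whole universe)" else "",
            ": ", paste(names(idx)[drop], collapse = ", "))
  }
  idx[!drop]
}

.activity <- function(scores, method, params = list()) {
  attr(scores, "method") <- method
  attr(scores, "params") <- params
  class(scores) <- c("activity_matrix", class(scores))
  scores
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("activity_matrix (%s): %d pathway(s) x %d sample(s)\n",
              attr(x, "method"), nrow(x), ncol(x)))
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  print(utils::head(y[, seq_len(min(ncol(y), 6L)), drop = FALSE], 5L), ...)
  invisible(x)
}

#' DiffRank pathway activity scores
#'
#' For each sample, genes are ranked in descending expression order (rank 1 =
#' highest) and a pathway's score is the mean rank of its member genes minus
#' the mean rank of all non-member genes. Scores lie in `[-G/2, +G/2]`; with
#' this literal orientation a pathway whose members are the most highly
#' expressed genes reaches the minimum `-G/2`. Use
#' `orient = "high_positive"` to negate scores so that high activity is
#' positive.
#'
#' @param expr numeric matrix, genes x samples (log-scale expression).
#' @param genesets a `gene_set_collection`.
#' @param orient `"literal"` (member mean rank minus non-member mean rank;
#'   default) or `"high_positive"` (negated).
#' @return An `activity_matrix`: pathways x samples.
#' @examples
#' expr <- matrix(rnorm(40), 8, 5,
#'                dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
#' gs <- gene_sets(list(pw = c("g1", "g2", "g3")))
#' diffrank_scores(expr, gs)
#' @export
diffrank_scores <- function(expr, genesets,
                            orient = c("literal", "high_positive")) {
  orient <- match.arg(orient)
  ranks <- rank_genes_per_sample(expr)
  G <- nrow(ranks)
  total <- G * (G + 1) / 2
  idx <- .resolve_sets(genesets, rownames(ranks), require_nonmember = TRUE)
  sc <- t(vapply(idx, function(i) {
    n1 <- length(i)
    n2 <- G - n1
    ms <- if (n1 == 1L) ranks[i, ] else colMeans(ranks[i, , drop = FALSE])
    ms - (total - n1 * ms) / n2
  }, numeric(ncol(ranks))))
  dimnames(sc) <- list(names(idx), colnames(ranks))
  if (orient == "high_positive") sc <- -sc
  .activity(sc, "diffrank", list(orient = orient))
}

# Per-gene standardization across samples; zero-variance rows become zero.
.standardize_rows <- function(expr) {
  mu <- rowMeans(expr)
  ctr <- expr - mu
  sd <- sqrt(rowSums(ctr^2) / (ncol(expr) - 1L))
  z <- ctr / sd
  z[sd == 0, ] <- 0
  z
}

#' Combined Z-score pathway activity
#'
#' Each gene is standardized across samples, z = (x - mean) / sd, and a
#' pathway's activity in a sample is the combined Z of its members,
#' `sum(z) / sqrt(n1)`. Under independence the combined score has unit
#' variance. Zero-variance genes contribute z = 0.
#'
#' @inheritParams diffrank_scores
#' @return An `activity_matrix`: pathways x samples.
#' @export
zscore_scores <- function(expr, genesets) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2L)
  z <- .standardize_rows(expr)
  idx <- .resolve_sets(genesets, rownames(expr))
  sc <- t(vapply(idx, function(i) {
    colSums(z[i, , drop = FALSE]) / sqrt(length(i))
  }, numeric(ncol(expr))))
  dimnames(sc) <- list(names(idx), colnames(expr))
  .activity(sc, "zscore", list())
}

#' PLAGE pathway activity (singular-vector meta-gene)
#'
#' The member-gene submatrix is standardized per gene (mean 0, sd 1 across
#' samples) and the pathway activity across samples is the right singular
#' vector of the largest singular value, i.e. the dominant sample-space
#' meta-gene. The returned activity vector has unit Euclidean norm. The SVD
#' sign is arbitrary, so it is fixed so that the activity correlates
#' non-negatively with the mean standardized member profile (tie: first
#' non-zero entry positive).
#'
#' @inheritParams diffrank_scores
#' @return An `activity_matrix`: pathways x samples; each row has unit norm.
#' @export
plage_scores <- function(expr, genesets) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2L)
  z <- .standardize_rows(expr)
  idx <- .resolve_sets(genesets, rownames(expr))
  sc <- t(vapply(idx, function(i) {
    Z <- z[i, , drop = FALSE]
    if (all(Z == 0)) {
      warning("member submatrix is zero after standardization; scores set to 0")
      return(numeric(ncol(Z)))
    }
    v <- svd(Z, nu = 0L, nv = 1L)$v[, 1L]
    d <- sum(v * colMeans(Z))
    if (d < 0) {
      v <- -v
    } else if (d == 0) {
      nz <- which(v != 0)[1L]
      if (!is.na(nz) && v[nz] < 0) v <- -v
    }
    v
  }, numeric(ncol(expr))))
  dimnames(sc) <- list(names(idx), colnames(expr))
  .activity(sc, "plage", list())
}

#' GSVA pathway activity (kernel CDF + rank random walk)
#'
#' Four stages per the gene set variation analysis algorithm for continuous
#' (log-scale) expression:
#' \enumerate{
#'   \item Per gene, a Gaussian-kernel cumulative density estimate of how
#'     high the gene is expressed in each sample:
#'     `z[g, j] = mean_k Phi((x[g, j] - x[g, k]) / h_g)` with bandwidth
#'     `h_g = kcdf_bandwidth_factor * sd_g` (floored at `1e-8` of the global
#'     sd for zero-variance genes).
#'   \item Within each sample, the kernel scores are converted to descending
#'     ranks (ties broken by gene order) and symmetrized around the list
#'     middle: `w[g, j] = |G/2 - rank[g, j]|`.
#'   \item A Kolmogorov-Smirnov-like random walk down each sample's ranked
#'     gene list: member genes add `w^tau` (normalized by the members' total
#'     weight), non-members subtract `1/(G - n1)`.
#'   \item The enrichment score is either the maximum positive deviation plus
#'     the minimum negative deviation (`difference_of_extremes`, default) or
#'     the single deviation of largest magnitude (`max_absolute`). Scores are
#'     bounded in `[-1, 1]`.
#' }
#'
#' @inheritParams diffrank_scores
#' @param tau non-negative weight exponent (default 1).
#' @param es_mode enrichment-score statistic, `"difference_of_extremes"`
#'   (default) or `"max_absolute"`.
#' @param kcdf_bandwidth_factor positive multiplier of the per-gene sd used
#'   as kernel bandwidth (default 1/4).
#' @return An `activity_matrix`: pathways x samples, values in `[-1, 1]`.
#' @export
gsva_scores <- function(expr, genesets, tau = 1,
                        es_mode = c("difference_of_extremes", "max_absolute"),
                        kcdf_bandwidth_factor = 0.25) {
  es_mode <- match.arg(es_mode)
  stopifnot(is.matrix(expr), nrow(expr) >= 2L, tau >= 0,
            kcdf_bandwidth_factor > 0)
  if (!all(is.finite(expr))) stop("expression contains non-finite values")
  G <- nrow(expr)
  n <- ncol(expr)
  global_sd <- stats::sd(as.vector(expr))
  floor_h <- max(1e-8 * global_sd, .Machine$double.xmin)
  kz <- matrix(0, G, n, dimnames = dimnames(expr))
  for (g in seq_len(G)) {
    x <- expr[g, ]
    h <- kcdf_bandwidth_factor * stats::sd(x)
    if (!is.finite(h) || h < floor_h) h <- floor_h
    kz[g, ] <- rowMeans(stats::pnorm(outer(x, x, "-") / h))
  }
  idx <- .resolve_sets(genesets, rownames(expr), require_nonmember = TRUE)
  sc <- matrix(0, length(idx), n, dimnames = list(names(idx), colnames(expr)))
  for (j in seq_len(n)) {
    ord <- order(kz[, j], decreasing = TRUE)   # ties: stable by gene order
    pos <- integer(G)
    pos[ord] <- seq_len(G)
    w <- abs(G / 2 - pos)^tau
    w_walk <- w[ord]
    for (s in seq_along(idx)) {
      i <- idx[[s]]
      n1 <- length(i)
      denom <- sum(w[i])
      steps <- rep.int(-1 / (G - n1), G)
      steps[pos[i]] <- if (denom > 0) w[i] / denom else 0
      rs <- cumsum(steps)
      mp <- max(0, max(rs))
      mn <- min(0, min(rs))
      sc[s, j] <- if (es_mode == "difference_of_extremes") {
        mp + mn
      } else if (mp >= -mn) mp else mn
    }
  }
  .activity(sc, "gsva",
            list(tau = tau, es_mode = es_mode,
                 kcdf_bandwidth_factor = kcdf_bandwidth_factor))
}

#' Score pathway activities with a chosen method
#'
#' Convenience dispatcher over the four scorers.
#'
#' @inheritParams diffrank_scores
#' @param method one of `"diffrank"`, `"zscore"`, `"plage"`, `"gsva"`.
#' @param ... method-specific arguments (see [diffrank_scores()],
#'   [gsva_scores()]).
#' @return An `activity_matrix`: pathways x samples.
#' @export
score_pathways <- function(expr, genesets,
                           method = c("diffrank", "zscore", "plage", "gsva"),
                           ...) {
  method <- match.arg(method)
  switch(method,
         diffrank = diffrank_scores(expr, genesets, ...),
         zscore = zscore_scores(expr, genesets),
         plage = plage_scores(expr, genesets),
         gsva = gsva_scores(expr, genesets, ...))
}
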