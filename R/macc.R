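# Median absolute pairwise Pearson correlation over rows of a genes x samples
# submatrix. Assumes >= 2 rows with positive variance.
.macc_raw <- function(xsub) {
  C <- stats::cor(t(xsub))
  stats::median(abs(C[upper.tri(C)]))
}

.macc_members <- function(expr, members, warn = TRUE) {
  i <- match(members, rownames(expr))
  i <- i[!is.na(i)]
  if (length(i) >= 2L) {
    v <- apply(expr[i, , drop = FALSE], 1L, stats::var)
    if (any(v == 0)) {
      if (warn) warning("dropping ", sum(v == 0),
                        " zero-variance member gene(s)")
      i <- i[v > 0]
    }
  }
  i
}

#' MACC: median absolute pairwise correlation of a pathway
#'
#' Pearson correlation coefficients are computed for all pairs of member
#' genes; the median of their absolute values summarizes the co-expression
#' coherence of the pathway. Member genes absent from the matrix are ignored;
#' zero-variance members are dropped with a warning. If fewer than two usable
#' members remain the statistic is undefined and `NA` is returned.
#'
#' @param expr numeric matrix, genes x samples (>= 3 samples).
#' @param members character vector of member gene ids (or a single set taken
#'   from a `gene_set_collection`).
#' @return A single value in `[0, 1]`, or `NA` if undefined.
#' @examples
#' expr <- matrix(rnorm(30), 6, 5,
#'                dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
#' macc(expr, c("g1", "g2", "g3"))
#' @export
macc <- function(expr, members) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3L)
  i <- .macc_members(expr, members)
  if (length(i) < 2L) {
    warning("fewer than 2 usable member genes; MACC undefined")
    return(NA_real_)
  }
  .macc_raw(expr[i, , drop = FALSE])
}

#' Permutation test of pathway co-expression coherence
#'
#' Tests whether a pathway's member genes are more correlated than expected
#' by chance. Two null schemes:
#' \describe{
#'   \item{`gene_resample` (default)}{each permutation draws a uniform random
#'     gene set of the same effective size from the expression universe and
#'     computes its MACC. This null preserves the background correlation
#'     structure of the data.}
#'   \item{`within_gene_shuffle`}{each permutation independently permutes
#'     every member gene's values across samples, destroying all inter-gene
#'     correlation.}
#' }
#' The p-value is `#(permuted MACC >= observed MACC) / n_perm` with no
#' pseudocount, so it can be exactly 0; ties count toward the numerator.
#'
#' @inheritParams macc
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed; required so runs are reproducible. The caller's
#'   RNG state is restored on exit.
#' @param null_scheme `"gene_resample"` or `"within_gene_shuffle"`.
#' @param name optional pathway name carried into the result.
#' @return Object of class `macc_test`: observed MACC, permuted MACCs,
#'   `p_value`, `n_perm`, `seed`, `null_scheme`.
#' @export
macc_permutation_test <- function(expr, members, n_perm = 1000L, seed,
                                  null_scheme = c("gene_resample",
                                                  "within_gene_shuffle"),
                                  name = NULL) {
  null_scheme <- match.arg(null_scheme)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  stopifnot(is.matrix(expr), ncol(expr) >= 3L)
  i <- .macc_members(expr, members)
  if (length(i) < 2L) stop("fewer than 2 usable member genes")
  observed <- .macc_raw(expr[i, , drop = FALSE])
  k <- length(i)
  G <- nrow(expr)
  n <- ncol(expr)

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) {
    sub <- if (null_scheme == "gene_resample") {
      expr[sample.int(G, k), , drop = FALSE]
    } else {
      t(apply(expr[i, , drop = FALSE], 1L, function(r) r[sample.int(n)]))
    }
    v <- apply(sub, 1L, stats::var)
    sub <- sub[v > 0, , drop = FALSE]
    if (nrow(sub) < 2L) return(NA_real_)
    .macc_raw(sub)
  }, numeric(1))
  p <- sum(perm >= observed, na.rm = TRUE) / n_perm
  structure(list(pathway_name = name, observed_macc = observed,
                 permuted_maccs = perm, p_value = p, n_perm = n_perm,
                 seed = seed, null_scheme = null_scheme, n_members = k),
            class = "macc_test")
}

#' @export
print.macc_test <- function(x, ...) {
  cat("MACC permutation test",
      if (!is.null(x$pathway_name)) paste0(" [", x$pathway_name, "]"), "\n",
      sep = "")
  cat(sprintf("  members: %d   observed MACC: %.4f\n",
              x$n_members, x$observed_macc))
  cat(sprintf("  null: %s   n_perm: %d   p = %.4g\n",
              x$null_scheme, x$n_perm, x$p_value))
  invisible(x)
}

#' MACC permutation tests for every set in a collection
#'
#' @param expr numeric matrix, genes x samples.
#' @param genesets a `gene_set_collection`.
#' @param n_perm,seed,null_scheme as in [macc_permutation_test()]. Per-pathway
#'   seeds are derived from `seed` so results do not depend on pathway order.
#' @return Data frame: pathway, size, observed MACC, p-value.
#' @export
macc_table <- function(expr, genesets, n_perm = 1000L, seed,
                       null_scheme = c("gene_resample",
                                       "within_gene_shuffle")) {
  null_scheme <- match.arg(null_scheme)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  res <- lapply(seq_along(genesets$sets), function(s) {
    r <- macc_permutation_test(expr, genesets$sets[[s]], n_perm = n_perm,
                               seed = (seed + s) %% .Machine$integer.max,
                               null_scheme = null_scheme,
                               name = names(genesets$sets)[s])
    data.frame(pathway = r$pathway_name, size = r$n_members,
               macc = r$observed_macc, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
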