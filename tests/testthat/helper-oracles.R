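# Independent, deliberately naive oracle implementations used to verify the
# vectorized scorers. These are plain-loop transcriptions of each method's
# definition and share no code with the package internals.

rand_expr <- function(G, n) {
  matrix(rnorm(G * n), G, n,
         dimnames = list(sprintf("g%03d", seq_len(G)),
                         sprintf("s%03d", seq_len(n))))
}

# DiffRank by direct enumeration of the member / non-member rank lists.
oracle_diffrank <- function(expr_col, mem_idx) {
  r <- rank(-expr_col, ties.method = "average")
  mean(r[mem_idx]) - mean(r[-mem_idx])
}

# Combined Z-score: standardize each gene with explicit loops, then sum.
oracle_zscore <- function(expr, mem_idx) {
  G <- nrow(expr)
  n <- ncol(expr)
  z <- matrix(0, G, n)
  for (g in seq_len(G)) {
    m <- mean(expr[g, ])
    s <- sd(expr[g, ])
    z[g, ] <- if (s == 0) 0 else (expr[g, ] - m) / s
  }
  out <- numeric(n)
  for (j in seq_len(n)) out[j] <- sum(z[mem_idx, j]) / sqrt(length(mem_idx))
  out
}

# PLAGE: dominant eigenvector of the samples x samples inner-product matrix
# of the standardized member submatrix (sign left arbitrary).
oracle_plage <- function(expr, mem_idx) {
  Z <- expr[mem_idx, , drop = FALSE]
  for (g in seq_len(nrow(Z))) {
    m <- mean(Z[g, ])
    s <- sd(Z[g, ])
    Z[g, ] <- if (s == 0) 0 else (Z[g, ] - m) / s
  }
  e <- eigen(t(Z) %*% Z, symmetric = TRUE)
  v <- e$vectors[, 1L]
  v / sqrt(sum(v^2))
}

# GSVA: literal four-stage transcription with nested loops.
oracle_gsva <- function(expr, mem_idx, tau = 1,
                        es_mode = "difference_of_extremes", bw = 0.25) {
  G <- nrow(expr)
  n <- ncol(expr)
  floor_h <- max(1e-8 * sd(as.vector(expr)), .Machine$double.xmin)
  z <- matrix(0, G, n)
  for (g in seq_len(G)) {
    h <- bw * sd(expr[g, ])
    if (!is.finite(h) || h < floor_h) h <- floor_h
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) acc <- acc + pnorm((expr[g, j] - expr[g, k]) / h)
      z[g, j] <- acc / n
    }
  }
  n1 <- length(mem_idx)
  es <- numeric(n)
  for (j in seq_len(n)) {
    ord <- order(z[, j], decreasing = TRUE)
    rnk <- integer(G)
    for (p in seq_len(G)) rnk[ord[p]] <- p
    w <- abs(G / 2 - rnk)^tau
    denom <- sum(w[mem_idx])
    rs <- numeric(G)
    run <- 0
    for (p in seq_len(G)) {
      g <- ord[p]
      run <- run + if (g %in% mem_idx) {
        if (denom > 0) w[g] / denom else 0
      } else {
        -1 / (G - n1)
      }
      rs[p] <- run
    }
    mp <- max(0, max(rs))
    mn <- min(0, min(rs))
    es[j] <- if (es_mode == "difference_of_extremes") {
      mp + mn
    } else if (mp >= -mn) mp else mn
  }
  es
}

# MACC by explicit pair enumeration.
oracle_macc <- function(expr, mem_idx) {
  k <- length(mem_idx)
  vals <- c()
  for (a in seq_len(k - 1)) {
    for (b in seq.int(a + 1, k)) {
      vals <- c(vals, abs(cor(expr[mem_idx[a], ], expr[mem_idx[b], ])))
    }
  }
  median(vals)
}
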