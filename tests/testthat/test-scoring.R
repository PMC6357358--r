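test_that("per-sample ranking is descending with average ties", {
  m <- cbind(s1 = c(a = 5, b = 3, c = 1))
  m2 <- cbind(m, s2 = c(2, 2, 1))
  r <- rank_genes_per_sample(m2)
  expect_equal(unname(r[, "s1"]), c(1, 2, 3))
  expect_equal(unname(r[, "s2"]), c(1.5, 1.5, 3))
  expect_error(rank_genes_per_sample(cbind(s1 = c(1, NA, 2))), "non-finite")
})

test_that("ranking agrees with a sort-based oracle and keeps the rank-sum", {
  set.seed(21)
  expr <- rand_expr(50, 4)
  expr[7, 2] <- expr[9, 2]  # force a tie
  r <- rank_genes_per_sample(expr)
  for (j in seq_len(ncol(expr))) {
    o <- rank(-expr[, j], ties.method = "average")
    expect_equal(unname(r[, j]), unname(o))
    expect_equal(sum(r[, j]), 50 * 51 / 2)
  }
  expect_true(all(r >= 1 & r <= 50))
})

test_that("DiffRank attains +/- G/2 on extreme rank configurations", {
  expr <- cbind(s1 = c(g1 = 9, g2 = 7, g3 = 4, g4 = 1), s2 = c(4, 1, 9, 7))
  rownames(expr) <- paste0("g", 1:4)
  gs <- gene_sets(list(top = c("g1", "g2")))
  sc <- diffrank_scores(expr, gs)
  expect_equal(unname(sc["top", "s1"]), -2)   # members hold ranks {1,2}
  expect_equal(unname(sc["top", "s2"]), 2)    # members hold ranks {3,4}
  neg <- diffrank_scores(expr, gs, orient = "high_positive")
  expect_equal(unname(neg["top", ]), -unname(sc["top", ]))
})

test_that("DiffRank matches direct enumeration and its invariants", {
  set.seed(31)
  for (rep in 1:100) {
    G <- sample(5:30, 1)
    n <- sample(1:4, 1)
    expr <- rand_expr(G, n)
    k <- sample(seq_len(G - 1), 1)
    mem <- sort(sample(G, k))
    gs <- gene_sets(list(pw = rownames(expr)[mem]))
    sc <- diffrank_scores(expr, gs)
    r <- rank_genes_per_sample(expr)
    for (j in seq_len(n)) {
      expect_equal(unname(sc["pw", j]), oracle_diffrank(expr[, j], mem),
                   tolerance = 1e-12)
      # rank-sum identity: n1 * m1 + n2 * m2 = G(G+1)/2
      m1 <- mean(r[mem, j])
      m2 <- mean(r[-mem, j])
      expect_equal(k * m1 + (G - k) * m2, G * (G + 1) / 2)
    }
    expect_true(all(abs(sc) <= G / 2 + 1e-12))
  }
})

test_that("DiffRank is invariant under strictly monotone transforms", {
  set.seed(32)
  expr <- rand_expr(40, 3)
  gs <- gene_sets(list(pw = rownames(expr)[c(3, 9, 17, 25)]))
  sc <- diffrank_scores(expr, gs)
  expr2 <- expr
  expr2[, 2] <- exp(expr2[, 2])
  expect_equal(diffrank_scores(expr2, gs), sc, tolerance = 0)
})

test_that("DiffRank omits degenerate sets with a warning", {
  expr <- rand_expr(6, 3)
  gs <- gene_sets(list(all = rownames(expr), some = rownames(expr)[1:2]))
  expect_warning(sc <- diffrank_scores(expr, gs), "omitting")
  expect_equal(rownames(sc), "some")
  gs2 <- gene_sets(list(alien = c("zz1", "zz2")))
  w <- capture_warnings(suppressMessages(sc2 <- diffrank_scores(expr, gs2)))
  expect_match(w, "omitting", all = FALSE)
  expect_equal(nrow(sc2), 0L)
})

test_that("combined Z-score reduces to known closed forms", {
  set.seed(41)
  expr <- rand_expr(10, 8)
  expr[4, ] <- expr[3, ]  # duplicated gene profile
  z3 <- (expr[3, ] - mean(expr[3, ])) / sd(expr[3, ])
  single <- zscore_scores(expr, gene_sets(list(pw = "g003")))
  expect_equal(unname(single["pw", ]), unname(z3), tolerance = 1e-12)
  dup <- zscore_scores(expr, gene_sets(list(pw = c("g003", "g004"))))
  expect_equal(unname(dup["pw", ]), unname(sqrt(2) * z3), tolerance = 1e-12)
})

test_that("Z-score matches the brute-force oracle and is standardization-invariant", {
  set.seed(42)
  for (rep in 1:25) {
    expr <- rand_expr(sample(5:20, 1), sample(3:10, 1))
    k <- sample(2:min(5, nrow(expr)), 1)
    mem <- sort(sample(nrow(expr), k))
    gs <- gene_sets(list(pw = rownames(expr)[mem]))
    sc <- zscore_scores(expr, gs)
    expect_equal(unname(sc["pw", ]), oracle_zscore(expr, mem),
                 tolerance = 1e-12)
    # shifting or positively scaling a member gene leaves scores unchanged
    expr2 <- expr
    expr2[mem[1], ] <- 3 + 2.5 * expr2[mem[1], ]
    expect_equal(zscore_scores(expr2, gs)["pw", ], sc["pw", ],
                 tolerance = 1e-10)
  }
})

test_that("Z-score treats zero-variance genes as zero contribution", {
  expr <- rand_expr(6, 5)
  expr[2, ] <- 7  # constant gene
  sc <- zscore_scores(expr, gene_sets(list(pw = c("g001", "g002"))))
  only1 <- zscore_scores(expr, gene_sets(list(pw = "g001")))
  expect_equal(unname(sc["pw", ]), unname(only1["pw", ]) / sqrt(2),
               tolerance = 1e-12)
})

test_that("PLAGE activity is the dominant singular vector with unit norm", {
  set.seed(51)
  for (rep in 1:25) {
    expr <- rand_expr(sample(6:20, 1), sample(4:10, 1))
    k <- sample(2:5, 1)
    mem <- sort(sample(nrow(expr), k))
    gs <- gene_sets(list(pw = rownames(expr)[mem]))
    v <- plage_scores(expr, gs)["pw", ]
    expect_equal(sum(v^2), 1, tolerance = 1e-12)
    o <- oracle_plage(expr, mem)
    expect_lt(min(sqrt(sum((v - o)^2)), sqrt(sum((v + o)^2))), 1e-8)
    # sign convention: non-negative projection on the mean member profile
    Z <- t(scale(t(expr[mem, , drop = FALSE])))
    expect_gte(sum(v * colMeans(Z)), 0)
  }
})

test_that("PLAGE handles rank-1 and degenerate member structure", {
  set.seed(52)
  expr <- rand_expr(8, 6)
  expr[5, ] <- 2 * expr[4, ] + 1  # perfectly correlated pair
  v_pair <- plage_scores(expr, gene_sets(list(pw = c("g004", "g005"))))["pw", ]
  z4 <- (expr[4, ] - mean(expr[4, ])) / sd(expr[4, ])
  expect_equal(abs(unname(v_pair)), abs(unname(z4 / sqrt(sum(z4^2)))),
               tolerance = 1e-12)
  v_single <- plage_scores(expr, gene_sets(list(pw = "g004")))["pw", ]
  expect_equal(abs(unname(v_single)), abs(unname(z4 / sqrt(sum(z4^2)))),
               tolerance = 1e-12)
  # affine transforms of a member gene change nothing (standardization)
  expr2 <- expr
  expr2[4, ] <- 10 + 0.1 * expr2[4, ]
  expect_equal(plage_scores(expr2, gene_sets(list(pw = c("g004", "g005")))),
               plage_scores(expr, gene_sets(list(pw = c("g004", "g005")))),
               tolerance = 1e-10)
  # all-constant member submatrix -> warning and zero scores
  expr3 <- expr
  expr3[2, ] <- 3
  expect_warning(v0 <- plage_scores(expr3, gene_sets(list(pw = "g002"))),
                 "zero after standardization")
  expect_equal(unname(v0["pw", ]), rep(0, 6))
})

test_that("GSVA matches the step-by-step oracle", {
  set.seed(61)
  for (rep in 1:20) {
    expr <- rand_expr(sample(8:20, 1), sample(4:10, 1))
    k <- sample(2:4, 1)
    mem <- sort(sample(nrow(expr), k))
    gs <- gene_sets(list(pw = rownames(expr)[mem]))
    for (mode in c("difference_of_extremes", "max_absolute")) {
      sc <- gsva_scores(expr, gs, es_mode = mode)
      expect_equal(unname(sc["pw", ]), oracle_gsva(expr, mem, es_mode = mode),
                   tolerance = 1e-10)
    }
  }
  # non-default tau
  expr <- rand_expr(12, 5)
  mem <- c(2L, 7L, 9L)
  gs <- gene_sets(list(pw = rownames(expr)[mem]))
  sc <- gsva_scores(expr, gs, tau = 0.5)
  expect_equal(unname(sc["pw", ]), oracle_gsva(expr, mem, tau = 0.5),
               tolerance = 1e-10)
})

test_that("GSVA scores are bounded and sample-separable", {
  set.seed(62)
  expr <- rand_expr(30, 8)
  gs <- gene_sets(list(a = rownames(expr)[1:5], b = rownames(expr)[10:20]))
  sc <- gsva_scores(expr, gs)
  expect_true(all(sc >= -1 & sc <= 1))
  # permuting sample columns permutes score columns identically
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  sc_p <- gsva_scores(expr[, perm], gs)
  expect_equal(matrix(sc_p, nrow(sc_p)), matrix(sc[, perm], nrow(sc)),
               tolerance = 1e-12)
  # members that are the top-ranked genes of a sample score positive
  expr2 <- expr
  expr2[1:5, 1] <- expr2[1:5, 1] + 50
  sc2 <- gsva_scores(expr2, gs)
  expect_gt(sc2["a", 1], 0)
})

test_that("all four scorers are deterministic", {
  set.seed(71)
  expr <- rand_expr(25, 6)
  gs <- gene_sets(list(a = rownames(expr)[2:7], b = rownames(expr)[c(1, 9, 12)]))
  for (m in c("diffrank", "zscore", "plage", "gsva")) {
    expect_identical(score_pathways(expr, gs, m), score_pathways(expr, gs, m))
  }
})
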