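make_expr <- function(values, labels) {
  expression_matrix(values, labels)
}

test_that("geometric means match closed forms and the AM-GM inequality", {
  v <- matrix(c(2, 8, 5, 5), nrow = 1,
              dimnames = list("g1", paste0("s", 1:4)))
  ex <- make_expr(v, c("A", "A", "B", "B"))
  gm <- geometric_mean_by_subtype(ex)
  expect_equal(unname(gm["g1", "A"]), 4)
  expect_equal(unname(gm["g1", "B"]), 5)
  # AM-GM on random positive fixtures, equality iff constant
  withr::with_seed(12, {
    for (i in 1:15) {
      x <- rexp(6) + 0.1
      m <- matrix(rep(x, 2), nrow = 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), paste0("s", 1:6)))
      ex2 <- make_expr(m, rep("A", 6))
      g <- geometric_mean_by_subtype(ex2)["a", "A"]
      expect_lte(g, mean(x) + 1e-12)
      if (sd(x) > 0) expect_lt(g, mean(x))
    }
  })
  bad <- v
  bad[1, 2] <- -1
  expect_error(expression_matrix(bad, c("A", "A", "B", "B")), "positive")
})

test_that("lognormal geometric means concentrate on exp(mu)", {
  mu <- 3
  sigma <- 0.6
  n <- 400
  withr::with_seed(44, {
    vals <- matrix(exp(rnorm(n, mu, sigma)), nrow = 1,
                   dimnames = list("g", paste0("s", 1:n)))
  })
  ex <- make_expr(vals, rep("A", n))
  gm <- geometric_mean_by_subtype(ex)["g", "A"]
  se <- sigma / sqrt(n)
  expect_lt(abs(log(gm) - mu), 3 * se)
})

test_that("multiclass selection finds a strongly shifted gene and respects fdr", {
  K <- 3
  nk <- 6
  labels <- rep(c("c1", "c2", "c3"), each = nk)
  hits <- 0
  runs <- 12
  for (r in seq_len(runs)) {
    withr::with_seed(500 + r, {
      base <- matrix(exp(rnorm(51 * K * nk, 0, 0.4)), nrow = 51)
      rownames(base) <- c("SHIFTED", sprintf("N%02d", 1:50))
      colnames(base) <- paste0("s", seq_len(K * nk))
      # class means shifted by 5 pooled (log-scale) SDs for one gene
      shift <- c(0, 5 * 0.4 / log(2), 10 * 0.4 / log(2))[match(labels,
                                                        c("c1", "c2", "c3"))]
      base["SHIFTED", ] <- base["SHIFTED", ] * 2^shift
    })
    sel <- select_differential_tfs(make_expr(base, labels), fdr = 0.1,
                                   n_perm = 100, seed = 600 + r)
    if ("SHIFTED" %in% sel$gene_id) hits <- hits + 1
  }
  expect_gte(hits / runs, 0.95)
})

test_that("null expression yields few selections and fdr=0 yields none", {
  labels <- rep(c("c1", "c2", "c3", "c4"), each = 5)
  fracs <- vapply(1:4, function(r) {
    withr::with_seed(700 + r, {
      vals <- matrix(exp(rnorm(150 * 20, 2, 0.5)), nrow = 150,
                     dimnames = list(sprintf("g%03d", 1:150),
                                     paste0("s", 1:20)))
    })
    ex <- make_expr(vals, labels)
    nrow(select_differential_tfs(ex, fdr = 0.1, n_perm = 100,
                                 seed = 800 + r)) / 150
  }, numeric(1))
  expect_lte(mean(fracs), 0.12)
  withr::with_seed(1, {
    vals <- matrix(exp(rnorm(50 * 20, 2, 0.5)), nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   paste0("s", 1:20)))
  })
  expect_equal(nrow(select_differential_tfs(make_expr(vals, labels),
                                            fdr = 0, n_perm = 100,
                                            seed = 3)), 0L)
})

test_that("enrichment-expression correlation recovers proportionality", {
  fold <- matrix(c(1, 2, 3, 4, 5,
                   5, 4, 3, 2, 1), nrow = 2, byrow = TRUE,
                 dimnames = list(c("FP", "FN"), paste0("S", 1:5)))
  gm <- matrix(c(10, 20, 30, 40, 50,
                 10, 20, 30, 40, 50), nrow = 2, byrow = TRUE,
               dimnames = list(c("gP", "gN"), paste0("S", 1:5)))
  mapping <- data.frame(family_id = c("FP", "FN"),
                        gene_id = c("gP", "gN"))
  res <- correlate_enrichment_expression(fold, gm, mapping)
  expect_equal(res$r[res$family_id == "FP"], 1)
  expect_equal(res$r[res$family_id == "FN"], -1)
  expect_equal(res$n_subtypes, c(5L, 5L))
  # invariance under positive rescaling of either side
  res2 <- correlate_enrichment_expression(3.7 * fold, gm, mapping)
  expect_equal(res2$r, res$r)
  res3 <- correlate_enrichment_expression(fold, 0.01 * gm, mapping)
  expect_equal(res3$r, res$r)
  # zero-variance vectors are flagged undefined
  flat <- fold
  flat["FP", ] <- 2
  r4 <- correlate_enrichment_expression(flat, gm, mapping)
  expect_true(is.na(r4$r[r4$family_id == "FP"]))
})

test_that("rank-sum p-values match exhaustive enumeration and wilcox.test", {
  r <- ranksum_test(c(1, 2), c(3, 4))
  expect_equal(r$p.value, 1 / 3)
  expect_equal(r$elevated, "B")
  expect_equal(r$method, "exact enumeration")
  # identical multisets: symmetric, p = 1
  expect_equal(ranksum_test(c(1, 2), c(1, 2))$p.value, 1)
  # enumeration oracle + base wilcox.test cross-checks (tie-free cases)
  withr::with_seed(90, {
    for (i in 1:8) {
      x <- round(runif(sample(2:4, 1)), 3)
      y <- round(runif(sample(2:4, 1)), 3)
      p <- ranksum_test(x, y)$p.value
      expect_equal(p, ranksum_exact_oracle(x, y))
      expect_equal(p, stats::wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("large well-separated groups give tiny rank-sum p-values", {
  reject <- vapply(1:20, function(r) {
    withr::with_seed(1000 + r, {
      x <- rnorm(20, 5, 1)
      y <- rnorm(20, 0, 1)
    })
    ranksum_test(x, y)$p.value < 1e-4
  }, logical(1))
  expect_gte(mean(reject), 0.99)
  big <- withr::with_seed(7, ranksum_test(rnorm(20, 2), rnorm(20)))
  expect_equal(big$method, "normal approximation with tie correction")
  expect_equal(big$elevated, "A")
  v <- matrix(rep(c(1, 2, 3, 9, 10, 11), 1), nrow = 1,
              dimnames = list("g", paste0("s", 1:6)))
  ex <- make_expr(v, c("A", "A", "A", "B", "B", "B"))
  m <- ranksum_marker_test(ex, "g", "A", "B")
  expect_equal(m$elevated, "B")
  expect_error(ranksum_marker_test(ex, "nope", "A", "B"), "unknown gene")
})
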