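test_that("perfectly correlated trait pairs load PC1 equally up to sign", {
  set.seed(15)
  base <- rnorm(300)
  X <- cbind(T1 = base, T2 = base,
             T3 = rnorm(300), T4 = rnorm(300), T5 = rnorm(300))
  p <- trait_pca(X)
  l1 <- p$loadings[, 1]
  expect_equal(unname(abs(l1["T1"])), unname(abs(l1["T2"])), tolerance = 1e-8)
  expect_gt(abs(l1["T1"]), max(abs(l1[c("T3", "T4", "T5")])))
  expect_equal(sum(p$pct_var), 100, tolerance = 1e-10)
})

test_that("reconstruction from all components reproduces the standardised matrix", {
  set.seed(16)
  X <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, paste0("T", 1:8)))
  p <- trait_pca(X)
  rec <- p$prcomp$x %*% t(p$prcomp$rotation)
  expect_lt(max(abs(rec - scale(X))), 1e-8)
})

test_that("isotropic data spreads variance evenly across components", {
  set.seed(17)
  X <- matrix(rnorm(4000 * 25), 4000, 25,
              dimnames = list(NULL, paste0("T", 1:25)))
  p <- trait_pca(X)
  expect_true(all(abs(p$pct_var - 4) < 0.8))
})

test_that("constant traits are dropped and missing values mean-imputed", {
  set.seed(18)
  X <- data.frame(T1 = rnorm(30), T2 = 5, T3 = rnorm(30))
  X$T1[c(3, 7)] <- NA
  expect_warning(expect_message(p <- trait_pca(X), "2 missing"), "T2")
  expect_identical(rownames(p$loadings), c("T1", "T3"))
  expect_identical(p$n_imputed, 2L)
})

test_that("Ball-Hall values match a brute-force recomputation on small inputs", {
  set.seed(19)
  X <- matrix(rnorm(40 * 7), 40, 7, dimnames = list(NULL, paste0("T", 1:7)))
  cl <- cluster_traits(X, k_max = 7)
  tmat <- t(scale(X))
  for (k in cl$bh$k) {
    mem <- cutree(cl$hclust, k = k)
    # direct formula: mean over clusters of mean squared member-centroid dist
    vals <- vapply(unique(mem), function(g) {
      xm <- tmat[mem == g, , drop = FALSE]
      ctr <- colMeans(xm)
      mean(colSums((t(xm) - ctr)^2))
    }, numeric(1))
    expect_equal(cl$bh$index[cl$bh$k == k], mean(vals), tolerance = 1e-10)
  }
})

test_that("identical trait vectors trip the zero-drop guard: k = 1", {
  base <- rnorm(50)
  X <- matrix(rep(base, 6), 50, 6, dimnames = list(NULL, paste0("T", 1:6)))
  cl <- cluster_traits(X)
  expect_identical(cl$k, 1L)
  expect_true(all(cl$membership == 1L))
})

test_that("three well-separated trait groups select k = 3 and recover membership", {
  hits <- 0L
  for (s in 1:20) {
    g <- three_group_traits(seed = s)
    cl <- cluster_traits(g$X)
    if (cl$k == 3L &&
        all(tapply(g$truth, cl$membership, function(v) length(unique(v))) == 1)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 19L)   # >= 95% of seeded runs
})

test_that("the Ball-Hall curve is non-increasing on average for homogeneous data", {
  set.seed(20)
  diffs <- replicate(20, {
    X <- matrix(rnorm(60 * 10), 60, 10, dimnames = list(NULL, paste0("T", 1:10)))
    cl <- cluster_traits(X, k_max = 8)
    mean(diff(cl$bh$index))
  })
  expect_lt(mean(diffs), 0)
})

test_that("k_max is clamped to the number of traits", {
  set.seed(21)
  X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("T", 1:4)))
  cl <- cluster_traits(X, k_max = 10)
  expect_identical(cl$k_max, 4L)
  expect_error(cluster_traits(X[, 1:2]), "3 traits")
})
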