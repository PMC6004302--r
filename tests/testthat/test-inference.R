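test_that("ANOSIM R is 1 for perfect separation and matches vegan elsewhere", {
  x <- blocky_data(c(4, 4), c(0, 10), sd = 0.1, seed = 1)
  g <- rep(c("lo", "hi"), each = 4)
  res <- anosim_test(euclidean_matrix(x), g, n_perm = 99, seed = 1)
  expect_equal(res$value, 1)
  expect_true(res$p > 0 && res$p <= 1)
  # cross-check the statistic against vegan's implementation on looser data
  set.seed(5)
  y <- matrix(rnorm(60), 12)
  gy <- rep(c("a", "b", "c"), each = 4)
  d <- stats::dist(y)
  ours <- anosim_test(as.matrix(d), gy, n_perm = 0)$value
  ref <- vegan::anosim(d, gy, permutations = 0)$statistic
  expect_equal(ours, unname(ref), tolerance = 1e-12)
})

test_that("ANOSIM is invariant under monotone transforms of the dissimilarities", {
  set.seed(8)
  x <- matrix(rnorm(40), 10)
  g <- rep(c("a", "b"), each = 5)
  D <- as.matrix(stats::dist(x))
  r1 <- anosim_test(D, g, n_perm = 0)$value
  r2 <- anosim_test(D^3, g, n_perm = 0)$value
  expect_equal(r1, r2)
})

test_that("ANOSIM R centres on zero under random labels", {
  rs <- vapply(1:100, function(s) {
    set.seed(s)
    x <- matrix(rnorm(30), 10)
    g <- sample(rep(c("a", "b"), each = 5))
    anosim_test(as.matrix(stats::dist(x)), g, n_perm = 0)$value
  }, 0)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("permutation p agrees with exhaustive enumeration on tiny designs", {
  for (s in 1:4) {
    set.seed(s)
    x <- c(rnorm(2), rnorm(3, 1.5))
    D <- as.matrix(stats::dist(x))
    g <- c("a", "a", "b", "b", "b")
    ex <- anosim_test(D, g, exact = TRUE)
    # independent oracle: enumerate the 10 distinct relabelings via combn
    rk <- D; lt <- lower.tri(D)
    rk[lt] <- rank(D[lt]); rk <- t(rk); rk[lower.tri(rk)] <- t(rk)[lower.tri(rk)]
    stat <- function(gg) {
      same <- outer(gg, gg, "==")[lt]
      (mean(rk[lt][!same]) - mean(rk[lt][same])) / (10 / 2)
    }
    vals <- apply(utils::combn(5, 2), 2, function(ix) {
      gg <- rep("b", 5); gg[ix] <- "a"; stat(gg)
    })
    expect_equal(length(vals), 10L)
    expect_equal(ex$p, mean(vals >= ex$value - 1e-12))
  }
  # n = 7, 3 + 4 split: 35 relabelings
  set.seed(30)
  x7 <- c(rnorm(3), rnorm(4, 1))
  D7 <- as.matrix(stats::dist(x7))
  g7 <- rep(c("a", "b"), c(3, 4))
  ex7 <- anosim_test(D7, g7, exact = TRUE)
  expect_equal(ex7$p * choose(7, 3), round(ex7$p * choose(7, 3)))
})

test_that("degenerate ANOSIM inputs are refused", {
  D <- as.matrix(stats::dist(1:6))
  expect_error(anosim_test(D, c("a", rep("b", 5)), n_perm = 0), "members")
  expect_error(anosim_test(matrix(0, 4, 4), rep(c("a", "b"), 2), n_perm = 0),
               "tied")
})

test_that("RELATE is symmetric, exact on self, and matches a hand computation", {
  set.seed(2)
  x <- matrix(rnorm(24), 8)
  y <- matrix(rnorm(24), 8)
  A <- euclidean_matrix(x); B <- euclidean_matrix(y)
  expect_equal(relate(A, A, n_perm = 0)$value, 1)
  expect_equal(relate(A, B, n_perm = 0)$value, relate(B, A, n_perm = 0)$value)
  # 4-sample matrices with hand-assigned lower triangles
  tri <- function(v) {
    m <- matrix(0, 4, 4)
    m[lower.tri(m)] <- v
    m + t(m)
  }
  A4 <- tri(c(1, 2, 3, 4, 5, 6))
  B4 <- tri(c(2, 1, 3, 4, 6, 5))
  # rank differences d = (1,-1,0,0,1,-1): rho = 1 - 6*4/(6*35) = 31/35
  expect_equal(relate(A4, B4, n_perm = 0)$value, 31 / 35)
  expect_error(relate(A, euclidean_matrix(matrix(rnorm(10), 5)), n_perm = 0),
               "mismatch")
  expect_error(relate(tri(rep(1, 6)), B4, n_perm = 0), "constant")
})

test_that("RELATE matches vegan's Spearman Mantel statistic", {
  set.seed(14)
  x <- matrix(rnorm(30), 10)
  v <- rnorm(10)
  ours <- relate(euclidean_matrix(x), euclidean_matrix(v), n_perm = 0)$value
  ref <- vegan::mantel(stats::dist(x), stats::dist(v), method = "spearman",
                       permutations = 0)$statistic
  expect_equal(ours, unname(ref), tolerance = 1e-12)
})

test_that("profile Spearman handles exact monotone series and ties", {
  expect_equal(spearman_profiles(1:10, (1:10)^3)$value, 1)
  expect_equal(spearman_profiles(1:10, -(1:10))$value, -1)
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(2, 1, 3, 3, 5, 6)
  expect_equal(spearman_profiles(x, y)$value,
               cor(x, y, method = "spearman"))
  expect_error(spearman_profiles(rep(1, 5), 1:5), "constant")
  expect_error(spearman_profiles(1:2, 2:1), "n >= 3")
})

test_that("permutation p-values are super-uniform under the null", {
  ps <- vapply(1:200, function(i) {
    set.seed(5000 + i)
    x <- rnorm(12); y <- rnorm(12)
    relate(euclidean_matrix(x), euclidean_matrix(y),
           n_perm = 99, seed = i)$p
  }, 0)
  expect_true(all(ps > 0 & ps <= 1))
  for (alpha in c(0.01, 0.05, 0.10))
    expect_lte(mean(ps <= alpha), alpha + 0.04)
})

test_that("permutation streams reproduce from the recorded seed", {
  set.seed(99)
  x <- matrix(rnorm(36), 12)
  g <- rep(c("a", "b", "c"), each = 4)
  D <- as.matrix(stats::dist(x))
  a1 <- anosim_test(D, g, n_perm = 199, seed = 42)
  a2 <- anosim_test(D, g, n_perm = 199, seed = 42)
  expect_identical(a1$p, a2$p)
  expect_error(anosim_test(D, g, n_perm = 99), "seed")
})
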