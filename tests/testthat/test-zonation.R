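test_that("two well-separated blocks merge last and cut at the true boundary", {
  x <- blocky_data(c(5, 5), c(0, 6), seed = 4)
  z <- coniss(euclidean_matrix(x))
  expect_equal(unname(z$blocks[nrow(z$blocks), ]), c(1L, 10L))
  # the final merge joins blocks 1-5 and 6-10
  expect_equal(unname(z$blocks[nrow(z$blocks) - 1, ]),
               c(1L, 5L))
  zones <- cut_zones(z, 2)
  expect_equal(zones, rep(c(2L, 1L), each = 5))
})

test_that("every intermediate cluster is a contiguous depth block", {
  set.seed(9)
  for (i in 1:5) {
    x <- matrix(rnorm(14 * 4), 14)
    z <- coniss(euclidean_matrix(x))
    # blocks[step, ] records the contiguous range formed at each merge
    expect_true(all(z$blocks[, "to"] >= z$blocks[, "from"]))
    for (k in 1:14) {
      zz <- cut_zones(z, k)
      expect_equal(length(rle(zz)$values), k)  # contiguity: k runs for k zones
    }
  }
})

test_that("reversing sample order mirrors the zone boundaries", {
  set.seed(12)
  x <- rbind(matrix(rnorm(12, 0, 0.3), 4), matrix(rnorm(18, 3, 0.3), 6))
  D <- euclidean_matrix(x)
  Drev <- euclidean_matrix(x[10:1, ])
  z1 <- cut_zones(coniss(D), 2)
  z2 <- cut_zones(coniss(Drev), 2)
  expect_equal(rle(z1)$lengths, rev(rle(z2)$lengths))
})

test_that("CONISS cuts are never better than and match the exhaustive optimum when separated", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(6:10, 1)
    k <- sample(2:3, 1)
    x <- matrix(rnorm(n * 3), n)
    D <- euclidean_matrix(x)
    z <- coniss(D)
    got <- zone_dispersion(D, cut_zones(z, k))
    opt <- best_contiguous_dispersion(D$values, k)
    expect_gte(got, opt - 1e-9)
  }
  for (s in 1:5) {
    x <- blocky_data(c(4, 4, 2), c(0, 5, 10), sd = 0.1, seed = 100 + s)
    D <- euclidean_matrix(x)
    got <- zone_dispersion(D, cut_zones(coniss(D), 3))
    expect_equal(got, best_contiguous_dispersion(D$values, 3),
                 tolerance = 1e-9)
  }
})

test_that("fusion heights are cumulative dispersion and agree with Ward on separated data", {
  x <- blocky_data(c(5, 5), c(0, 8), seed = 6)
  D <- euclidean_matrix(x)
  z <- coniss(D)
  expect_true(all(diff(z$height) >= -1e-12))
  expect_equal(z$height[length(z$height)], zone_dispersion(D, rep(1L, 10)),
               tolerance = 1e-9)
  # unconstrained Ward finds the same 2-group structure when groups are
  # contiguous and well separated
  hw <- stats::hclust(stats::dist(x)^2 / 2, method = "ward.D")
  expect_equal(unname(stats::cutree(hw, 2)), c(rep(1L, 5), rep(2L, 5)))
})

test_that("broken stick keeps noise at one zone and finds strong 3-block structure", {
  ks <- vapply(1:50, function(s) {
    set.seed(s)
    z <- coniss(euclidean_matrix(matrix(rnorm(20 * 5), 20)))
    broken_stick_select(z, 8)$k
  }, 0L)
  expect_gt(mean(ks == 1L), 0.5)
  x <- blocky_data(c(10, 10, 10), c(0, 4, 8), sd = 0.2, seed = 1)
  z3 <- coniss(euclidean_matrix(x))
  expect_equal(broken_stick_select(z3, 8)$k, 3L)
  expect_error(broken_stick_select(z3, 40), "max_k")
})

test_that("cut_zones honours bounds and labels the deepest zone 1", {
  x <- blocky_data(c(3, 3), c(0, 5), seed = 2)
  z <- coniss(euclidean_matrix(x))
  expect_equal(cut_zones(z, 1), rep(1L, 6))
  expect_equal(cut_zones(z, 6), 6:1)          # singletons, deepest = 1
  expect_error(cut_zones(z, 0), "k must")
  expect_error(cut_zones(z, 7), "k must")
})
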