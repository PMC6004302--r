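test_that("probable error follows the totals-based formula", {
  m <- matrix(c(150, 0, 150, 0, 225, 225), 3, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  m[3, ] <- c(225, 225)                       # totals 150, 150, 450
  sc <- probable_error_screen(toy_counts(m))
  expect_equal(sc$s, sd(c(150, 150, 450)))    # about 173.2
  expect_equal(sc$samples$pe[1], 1.96 * sd(c(150, 150, 450)) / sqrt(150),
               tolerance = 1e-12)
  expect_lt(sc$samples$pe[1], 150)
  expect_true(all(sc$samples$pass))
})

test_that("a single-sample dataset passes iff it meets the minimum count", {
  one <- toy_counts(matrix(c(100, 60), 1, dimnames = list(NULL, c("a", "b"))))
  sc <- probable_error_screen(one)
  expect_equal(sc$s, 0)
  expect_equal(sc$samples$pe, 0)
  expect_true(sc$samples$pass)                 # total 160 >= 150
  small <- toy_counts(matrix(c(50, 60), 1,
                             dimnames = list(NULL, c("a", "b"))))
  expect_false(probable_error_screen(small)$samples$pass)
})

test_that("species standard error follows the binomial formula", {
  m <- matrix(c(50, 50, 0, 90, 10, 0), 2, 3, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  sc <- species_error_screen(toy_counts(m))
  # X = 0.5, N = 100: S = 1.96 * sqrt(0.0025) = 0.098 < 0.5 -> retained
  expect_equal(sc$se[1, "a"], 1.96 * sqrt(0.25 / 100), tolerance = 1e-12)
  expect_true(sc$taxa$pass[sc$taxa$taxon == "a"])
  # all-zero taxon can never be significant
  expect_false(sc$taxa$pass[sc$taxa$taxon == "c"])
  expect_equal(ncol(sc$screened$values), 2L)
})

test_that("species screen is invariant to taxon column order and monotone in N", {
  set.seed(42)
  m <- matrix(rmultinom(6, 200, c(0.5, 0.3, 0.15, 0.04, 0.01)), 6, 5,
              byrow = TRUE, dimnames = list(NULL, letters[1:5]))
  sc1 <- species_error_screen(toy_counts(m))
  perm <- c(3, 1, 5, 2, 4)
  sc2 <- species_error_screen(toy_counts(m[, perm]))
  expect_equal(sc1$taxa$pass[perm], sc2$taxa$pass)
  # quadrupling all counts (same proportions, larger N) never drops a taxon
  sc4 <- species_error_screen(toy_counts(m * 4))
  expect_true(all(sc4$taxa$pass[sc1$taxa$pass]))
})

test_that("transformations behave as declared", {
  cc <- toy_counts(matrix(c(10, 20, 70), 1,
                          dimnames = list(NULL, c("a", "b", "c"))))
  rel <- to_relative(cc)
  expect_equal(unname(rel$values[1, ]), c(0.10, 0.20, 0.70))
  sq <- sqrt_transform(assemblage_counts(
    matrix(c(0.25, 0.75), 1, dimnames = list(NULL, c("a", "b"))),
    mode = "relative"))
  expect_equal(unname(sq$values[1, ]), c(0.5, sqrt(0.75)))
  expect_equal(sq$mode, "transformed")
  # sqrt is not idempotent away from {0, 1}
  expect_false(isTRUE(all.equal(sqrt_transform(sq)$values, sq$values)))
  zero <- toy_counts(matrix(c(0, 0, 5, 5), 2, byrow = TRUE,
                            dimnames = list(c("z", "p"), c("a", "b"))))
  expect_error(to_relative(zero), "z")
})

test_that("reconstructed counts hit the target total exactly", {
  asm <- frame_lake_assemblage()
  cc <- reconstruct_counts(asm, 150)
  expect_equal(unname(rowSums(cc$values)), rep(150, 30))
  expect_equal(cc$mode, "counts")
})
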