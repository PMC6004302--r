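test_that("the same seed reproduces the core byte for byte", {
  cfg <- synthetic_core_config(seed = 123)
  c1 <- generate_core(cfg)
  c2 <- generate_core(cfg)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  c3 <- generate_core(synthetic_core_config(seed = 124))
  expect_false(identical(c1$counts$values, c3$counts$values))
})

test_that("assemblage rows sum exactly to their drawn totals and pass validation", {
  core <- generate_core(synthetic_core_config(seed = 7))
  expect_s3_class(core$counts, "assemblage_counts")
  expect_equal(unname(rowSums(core$counts$values)), unname(core$counts$totals))
  expect_true(all(core$counts$values == round(core$counts$values)))
  expect_equal(core$loi$organics + core$loi$carbonates +
                 core$loi$minerogenics, rep(1, 30))
  expect_s3_class(core$registry, "taxon_registry")
  # the generated bundle survives a serialization round trip through core io
  f <- withr::local_tempfile(fileext = ".csv")
  write_assemblage_table(core$counts, f)
  back <- read_assemblage_table(f, mode = "counts")
  expect_identical(back$values, core$counts$values)
})

test_that("null coupling flattens the centropyxid share; zero peaks flatten the contaminant", {
  flat <- generate_core(synthetic_core_config(beta1 = 0, seed = 5))
  expect_equal(length(unique(flat$truth$pi_centropyxid)), 1L)
  nopeak <- synthetic_core_config(peak_height = c(0, 0), seed = 5)
  expect_equal(contaminant_profile(nopeak), rep(150, 30))
})

test_that("the default coupling depresses the stress ratio inside the contaminated zone", {
  core <- generate_core(synthetic_core_config(seed = 42))
  ip <- index_profile(core$counts, core$registry)
  mid <- 7:16
  expect_lt(mean(ip$dc_ratio[mid]), mean(ip$dc_ratio[-mid]))
})

test_that("the synthetic age model carries the hiatus below the middle zone", {
  core <- generate_core(synthetic_core_config(seed = 3))
  m <- age_depth_model(core$ages, hiatus_depth = 16)
  aa <- assign_age(m, c(0, 16, 20))
  expect_equal(aa$year[1], 2012)
  expect_equal(aa$year[2], 1962)
  expect_true(is.na(aa$year[3]))
})

test_that("zonation recovery meets the pre-registered thresholds", {
  rs <- recovery_study(synthetic_core_config(), n_replicates = 50)
  expect_gte(rs$zone_rate, 0.9)
  expect_gte(rs$boundary_rate, 0.9)
  expect_gt(median(rs$replicates$relate_rho), 0)
})

test_that("a single-zone configuration mostly recovers one zone", {
  one_zone <- synthetic_core_config(beta1 = 0, peak_height = c(0, 0),
                                    seed = 11)
  # erase between-zone composition differences as well
  one_zone$base_alpha[1, ] <- one_zone$base_alpha[3, ]
  one_zone$base_alpha[2, ] <- one_zone$base_alpha[3, ]
  ks <- vapply(1:30, function(r) {
    cfg <- one_zone
    cfg$seed <- one_zone$seed + r
    core <- generate_core(cfg)
    z <- coniss(bray_curtis(to_relative(core$counts),
                            allow_untransformed = TRUE))
    broken_stick_select(z, 6)$k
  }, 0L)
  expect_gt(mean(ks == 1L), 0.5)
})

test_that("stronger coupling gives non-decreasing mean ANOSIM separation", {
  mean_R <- vapply(c(0.3, 1.2, 2.5), function(b1) {
    cfg <- synthetic_core_config(beta1 = b1, seed = 900)
    # keep zone base compositions identical so coupling is the only signal
    cfg$base_alpha[1, ] <- cfg$base_alpha[2, ]
    cfg$base_alpha[3, ] <- cfg$base_alpha[2, ]
    mean(vapply(1:30, function(r) {
      cfg$seed <- 900 + r
      core <- generate_core(cfg)
      d <- bray_curtis(sqrt_transform(to_relative(core$counts)))
      anosim_test(d, core$truth$zones, n_perm = 0)$value
    }, 0))
  }, 0)
  expect_true(all(diff(mean_R) >= -0.02))
})
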