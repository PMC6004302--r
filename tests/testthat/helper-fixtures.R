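# In-code fixtures shared across test files.

toy_registry <- function() {
  taxon_registry(data.frame(
    taxon_id = c("Centropyxis a", "Centropyxis b", "Difflugia a",
                 "Difflugia b", "Cucurbitella t", "Arcella v"),
    group = c("centropyxid", "centropyxid", "difflugiid", "difflugiid",
              "difflugiid", "other"),
    in_dc_ratio = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)))
}

toy_counts <- function(values, mode = "counts") {
  assemblage_counts(values, mode = mode)
}

# two homogeneous, well-separated blocks of multivariate samples
blocky_data <- function(sizes, centers, sd = 0.15, nvar = 3, seed = 1) {
  set.seed(seed)
  do.call(rbind, Map(function(n, mu)
    matrix(stats::rnorm(n * nvar, mu, sd), n, nvar), sizes, centers))
}

# exhaustive optimal contiguous k-partition dispersion (zonation oracle)
best_contiguous_dispersion <- function(D, k) {
  n <- nrow(D)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    zz <- rep(seq_len(k), diff(c(0, cuts[, j], n)))
    best <- min(best, zone_dispersion(D, zz))
  }
  best
}

fl_zones <- function() c(rep(3L, 6), rep(2L, 10), rep(1L, 14))
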