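# Permutation tests linking assemblages, zones and environmental
# covariates: one-way ANOSIM, RELATE-style matrix rank correlation, and
# profile-wise Spearman correlation.

perm_test_result <- function(statistic, value, p, n_perm, n, seed,
                             group_sizes = NULL) {
  structure(list(statistic = statistic, value = value, p = p,
                 n_perm = n_perm, n = n, seed = seed,
                 group_sizes = group_sizes),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s = %.4f, p = %.4g (%s, n = %d%s)\n", x$statistic, x$value,
              x$p,
              if (is.na(x$n_perm)) "exact enumeration"
              else paste0(x$n_perm, " permutations"),
              x$n,
              if (is.null(x$group_sizes)) ""
              else paste0(", groups ", paste(x$group_sizes, collapse = "/"))))
  invisible(x)
}

as_dissim_values <- function(m, what = "input") {
  if (inherits(m, "resemblance_matrix"))
    convert_resemblance(m, "dissimilarity")$values
  else if (inherits(m, "dist")) as.matrix(m)
  else {
    m <- as.matrix(m)
    if (any(abs(m - t(m)) > 1e-10)) stop("non-symmetric ", what, " matrix")
    m
  }
}

anosim_stat <- function(rk_matrix, groups, M) {
  same <- outer(groups, groups, "==")
  lt <- lower.tri(rk_matrix)
  (mean(rk_matrix[lt & !same]) - mean(rk_matrix[lt & same])) / (M / 2)
}

# all distinct arrangements of a label multiset (exact ANOSIM null)
multiset_perms <- function(labels) {
  labels <- as.character(labels)
  uniq <- unique(labels)
  counts <- table(factor(labels, levels = uniq))
  out <- list()
  rec <- function(prefix, counts) {
    if (sum(counts) == 0) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (u in names(counts)[counts > 0]) {
      counts2 <- counts
      counts2[u] <- counts2[u] - 1L
      rec(c(prefix, u), counts2)
    }
  }
  rec(character(0), counts)
  do.call(rbind, out)
}

#' One-way analysis of similarities (ANOSIM)
#'
#' Rank-based test of group separation on a dissimilarity matrix:
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` with
#' `M = n(n-1)/2` off-diagonal pairs and average ranks for ties.  `R` near 1
#' means all between-group dissimilarities exceed the within-group ones; `R`
#' near 0 means no separation.  Significance comes from random relabelings
#' of the samples (with the `+1` small-sample correction so `p` is never 0),
#' or from exhaustive enumeration of all distinct relabelings when
#' `exact = TRUE`.
#'
#' @param m dissimilarity [resemblance_matrix()], `dist` or symmetric
#'   matrix (similarity input is converted).
#' @param groups factor/vector of group labels partitioning the samples; at
#'   least 2 groups with at least 2 members each.
#' @param n_perm number of random relabelings (ignored when `exact`).
#' @param seed RNG seed, required for the permutation p-value.
#' @param exact enumerate all distinct relabelings instead of sampling.
#' @return a `perm_test` result with statistic `"ANOSIM_R"`.
#' @export
anosim_test <- function(m, groups, n_perm = 999, seed = NULL, exact = FALSE) {
  D <- as_dissim_values(m)
  n <- nrow(D)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups must label every sample")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 members each")
  lt <- lower.tri(D)
  rk <- D
  rk[lt] <- rank(D[lt])
  rk <- t(rk); rk[lower.tri(rk)] <- t(rk)[lower.tri(rk)]  # symmetrize ranks
  M <- n * (n - 1) / 2
  if (stats::var(D[lt]) == 0) stop("all dissimilarities tied")
  obs <- anosim_stat(rk, groups, M)
  if (exact) {
    perms <- multiset_perms(groups)
    vals <- apply(perms, 1, function(g) anosim_stat(rk, g, M))
    p <- mean(vals >= obs - 1e-12)
    return(perm_test_result("ANOSIM_R", obs, p, NA_integer_, n, NULL,
                            as.integer(tab)))
  }
  if (n_perm > 0) {
    if (is.null(seed)) stop("seed is required for the permutation p-value")
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      g <- sample(groups)
      if (anosim_stat(rk, g, M) >= obs - 1e-12) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_perm)
  } else p <- NA_real_
  perm_test_result("ANOSIM_R", obs, p, n_perm, n, seed, as.integer(tab))
}

#' RELATE: rank correlation between two resemblance matrices
#'
#' Spearman correlation (average-rank ties) between the matched
#' off-diagonal entries of two dissimilarity matrices over the same
#' samples, a Mantel-type statistic.  Similarity inputs are converted to
#' dissimilarity (`1 - s`) first so the sign of rho reads as "similar
#' structure, positive rho".  Significance by permuting the sample labels
#' of the second matrix, with the `+1` correction.
#'
#' @param a,b [resemblance_matrix()], `dist` or symmetric matrices over the
#'   same samples.
#' @param n_perm number of permutations.
#' @param seed RNG seed, required when `n_perm > 0`.
#' @return a `perm_test` result with statistic `"RELATE_rho"`.
#' @export
relate <- function(a, b, n_perm = 999, seed = NULL) {
  A <- as_dissim_values(a, "first")
  B <- as_dissim_values(b, "second")
  if (!all(dim(A) == dim(B))) stop("matrix size mismatch")
  n <- nrow(A)
  lt <- lower.tri(A)
  av <- A[lt]; bv <- B[lt]
  if (stats::var(av) == 0 || stats::var(bv) == 0)
    stop("constant matrix: rho undefined")
  obs <- stats::cor(av, bv, method = "spearman")
  if (n_perm > 0) {
    if (is.null(seed)) stop("seed is required for the permutation p-value")
    set.seed(seed)
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample(n)
      if (stats::cor(av, B[idx, idx][lt], method = "spearman") >=
          obs - 1e-12) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_perm)
  } else p <- NA_real_
  perm_test_result("RELATE_rho", obs, p, n_perm, n, seed)
}

#' Spearman correlation between two depth profiles
#'
#' Average-rank Spearman rho with a two-sided p-value from the t
#' approximation `t = rho * sqrt((n-2)/(1-rho^2))`, plus an optional
#' permutation p-value.
#'
#' @param x,y numeric vectors over matched depths, `n >= 3`.
#' @param n_perm optional number of permutations (0 = analytic p only).
#' @param seed RNG seed when `n_perm > 0`.
#' @return a `perm_test` result with statistic `"Spearman_rho"`; the
#'   analytic p in `$p_analytic`, permutation p (if any) in `$p`.
#' @export
spearman_profiles <- function(x, y, n_perm = 0, seed = NULL) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("constant series")
  obs <- stats::cor(x, y, method = "spearman")
  tt <- obs * sqrt((n - 2) / max(1 - obs^2, .Machine$double.eps))
  p_analytic <- 2 * stats::pt(-abs(tt), df = n - 2)
  p <- p_analytic
  if (n_perm > 0) {
    if (is.null(seed)) stop("seed is required for the permutation p-value")
    set.seed(seed)
    exceed <- sum(vapply(seq_len(n_perm), function(i)
      abs(stats::cor(x, sample(y), method = "spearman")) >= abs(obs) - 1e-12,
      FALSE))
    p <- (1 + exceed) / (1 + n_perm)
  }
  out <- perm_test_result("Spearman_rho", obs, p,
                          if (n_perm > 0) n_perm else NA_integer_, n, seed)
  out$p_analytic <- p_analytic
  out
}
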