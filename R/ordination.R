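# Non-metric multidimensional scaling of a biotic resemblance matrix, with
# zone overlay summaries used to corroborate the stratigraphic zonation.

#' Non-metric multidimensional scaling
#'
#' Kruskal-style NMDS: iterative stress-1 minimization with monotone
#' (pool-adjacent-violators) regression and weak tie handling, run from a
#' metric (principal-coordinates) start plus `n_starts - 1` seeded random
#' starts; the lowest-stress configuration wins.  The returned
#' configuration is centred and rotated to its principal axes.  The stress
#' engine is `vegan::monoMDS` (`model = "global"`, stress-1).
#'
#' @param m dissimilarity [resemblance_matrix()] or `dist`.
#' @param k number of ordination dimensions (default 2, must be `< n`).
#' @param n_starts number of starts (first is metric, rest random).
#' @param seed RNG seed for the random starts.
#' @param tol convergence tolerance on stress.
#' @param max_iter iteration cap per start (non-convergence is flagged, the
#'   best configuration is still returned).
#' @return object of class `nmds_result`: `points` (n x k), `stress`
#'   (Kruskal stress-1), `best_start`, `start_stress`, `iters`,
#'   `converged`, `seed`.
#' @export
nmds <- function(m, k = 2, n_starts = 50, seed = 1, tol = 1e-6,
                 max_iter = 500) {
  d <- if (inherits(m, "resemblance_matrix")) {
    stats::as.dist(convert_resemblance(m, "dissimilarity")$values)
  } else stats::as.dist(m)
  n <- attr(d, "Size")
  if (k >= n) stop("k must be smaller than the number of samples")
  best <- NULL
  start_stress <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    set.seed(seed + s - 1L)
    fit <- if (s == 1L) {
      vegan::monoMDS(d, k = k, model = "global", maxit = max_iter,
                     smin = tol, sfgrmin = tol * 1e-3)
    } else {
      init <- matrix(stats::runif(n * k, -1, 1), n, k)
      vegan::monoMDS(d, y = init, k = k, model = "global", maxit = max_iter,
                     smin = tol, sfgrmin = tol * 1e-3)
    }
    start_stress[s] <- fit$stress
    if (is.null(best) || fit$stress < best$fit$stress)
      best <- list(fit = fit, start = s)
  }
  pts <- scale(best$fit$points, center = TRUE, scale = FALSE)
  pts <- pts %*% svd(pts)$v           # principal-axis rotation
  colnames(pts) <- paste0("NMDS", seq_len(k))
  rownames(pts) <- labels(d) %||% paste0("S", seq_len(n))
  structure(list(points = pts, stress = best$fit$stress,
                 best_start = best$start, start_stress = start_stress,
                 iters = best$fit$iters,
                 converged = best$fit$iters < best$fit$maxits,
                 n_starts = n_starts, seed = seed),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dims, stress-1 = %.4f (best of %d starts%s)\n",
              nrow(x$points), ncol(x$points), x$stress, x$n_starts,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Overlay zones on an ordination
#'
#' Tags the configuration by zone and summarizes separation: per-zone
#' centroids, mean within-zone spread (point-to-own-centroid distance) and
#' pairwise between-centroid distances.
#'
#' @param ord an [nmds()] result.
#' @param zones vector of zone labels, one per sample.
#' @return list with `coords` (data frame of scores + zone), `centroids`,
#'   `dist_to_centroids` (samples x zones), `within_spread`,
#'   `between_centroids`.
#' @export
zone_overlay <- function(ord, zones) {
  pts <- ord$points
  if (length(zones) != nrow(pts)) stop("zone/sample mismatch")
  zl <- sort(unique(zones))
  cent <- t(vapply(zl, function(z) colMeans(pts[zones == z, , drop = FALSE]),
                   numeric(ncol(pts))))
  rownames(cent) <- as.character(zl)
  d2c <- vapply(seq_along(zl), function(j)
    sqrt(rowSums((pts - matrix(cent[j, ], nrow(pts), ncol(pts),
                               byrow = TRUE))^2)),
    numeric(nrow(pts)))
  colnames(d2c) <- as.character(zl)
  within <- mean(d2c[cbind(seq_len(nrow(pts)), match(zones, zl))])
  between <- stats::dist(cent)
  list(coords = data.frame(as.data.frame(pts), zone = zones),
       centroids = cent, dist_to_centroids = d2c,
       within_spread = within, between_centroids = between)
}
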