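# Stratigraphically constrained incremental sum-of-squares clustering
# (CONISS) with broken-stick zone-count selection.
#
# Only depth-adjacent clusters may merge.  The fusion cost is the increase
# in within-cluster dispersion, computed by the exact Ward/Lance-Williams
# recurrence on the supplied (squared) dissimilarities, so for a cluster C
# the accumulated cost equals sum_{i<j in C} d_ij^2 / |C|.

#' Stratigraphically constrained clustering (CONISS)
#'
#' Agglomerative clustering in which only stratigraphically adjacent
#' clusters may merge, with incremental sum-of-squares fusion costs.  Ties
#' in fusion cost are broken by merging the shallowest eligible pair.
#'
#' @param m a dissimilarity [resemblance_matrix()], `dist`, or symmetric
#'   matrix; samples must be in stratigraphic (down-core) order.
#' @return object of class `coniss`: `merge` (hclust-style), `cost`
#'   (incremental dispersion increase per merge), `height` (cumulative
#'   within-cluster dispersion, monotone), `blocks` (sample-index range
#'   merged at each step), `n`, `labels`.
#' @export
coniss <- function(m) {
  if (inherits(m, "resemblance_matrix")) {
    if (m$kind != "dissimilarity")
      stop("CONISS needs a dissimilarity matrix; see convert_resemblance()")
    labels <- m$sample_ids
    D <- m$values
  } else {
    D <- as.matrix(m)
    labels <- rownames(D) %||% paste0("S", seq_len(nrow(D)))
  }
  n <- nrow(D)
  if (n < 2) stop("need at least 2 samples")
  if (any(abs(D - t(D)) > 1e-10)) stop("non-symmetric input")
  # cost of merging singleton pair = d^2 / 2; LW-updated thereafter
  C <- D^2 / 2
  sz <- rep(1L, n)
  id <- -(1:n)                 # hclust convention: negatives are singletons
  active <- 1:n                # block representatives, in depth order
  lo <- 1:n; hi <- 1:n         # contiguous sample range per block
  merge <- matrix(0L, n - 1L, 2L)
  cost <- numeric(n - 1L)
  blocks <- matrix(0L, n - 1L, 2L, dimnames = list(NULL, c("from", "to")))
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    adj <- vapply(seq_len(k - 1L),
                  function(i) C[active[i], active[i + 1L]], 0)
    i <- which.min(adj)        # which.min takes the first = shallowest tie
    a <- active[i]; b <- active[i + 1L]
    cost[step] <- adj[i]
    merge[step, ] <- c(id[a], id[b])
    # Ward update of costs to every other block
    for (c in setdiff(active, c(a, b))) {
      C[a, c] <- C[c, a] <-
        ((sz[a] + sz[c]) * C[a, c] + (sz[b] + sz[c]) * C[b, c] -
           sz[c] * C[a, b]) / (sz[a] + sz[b] + sz[c])
    }
    sz[a] <- sz[a] + sz[b]
    hi[a] <- hi[b]
    id[a] <- step
    blocks[step, ] <- c(lo[a], hi[a])
    active <- active[-(i + 1L)]
  }
  structure(list(merge = merge, cost = cost, height = cumsum(cost),
                 blocks = blocks, n = n, labels = labels),
            class = "coniss")
}

#' @export
print.coniss <- function(x, ...) {
  cat(sprintf("CONISS merge tree: %d samples, total dispersion %.4g\n",
              x$n, sum(x$cost)))
  invisible(x)
}

#' Convert a CONISS tree to hclust for plotting
#'
#' @param x a [coniss()] result.
#' @param ... unused.
#' @return an `hclust` object with cumulative-dispersion heights.
#' @export
as.hclust.coniss <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = seq_len(x$n),
                 labels = x$labels, method = "coniss",
                 call = match.call(), dist.method = "supplied"),
            class = "hclust")
}

#' Broken-stick selection of the zone count
#'
#' The split into `k` zones recovers the fusion cost of the `(k-1)`-th
#' merge from the top of the tree; its share of the total dispersion is
#' compared with the broken-stick expectation `sum(1/(k:n)) / n`.  Reading
#' from `k = 2` upward, splits are accepted while the observed reduction
#' exceeds expectation; the chosen zone count is the last accepted `k`
#' before the first non-significant split (1 when already the first split
#' falls short).  This sequential reading keeps pure-noise data at a
#' single zone; `rule = "largest"` instead returns the largest significant
#' `k` regardless of gaps.
#'
#' @param z a [coniss()] result.
#' @param max_k largest zone count to examine (must not exceed `n`).
#' @param rule `"sequential"` (default) or `"largest"`.
#' @return list with `k` (chosen) and `table` (k, observed, expected,
#'   significant).
#' @export
broken_stick_select <- function(z, max_k = 10,
                                rule = c("sequential", "largest")) {
  rule <- match.arg(rule)
  n <- z$n
  if (max_k > n) stop("max_k exceeds the number of samples")
  max_k <- min(max_k, n)
  ks <- seq(2L, max_k)
  total <- sum(z$cost)
  observed <- rev(z$cost)[ks - 1L] / total
  expected <- vapply(ks, function(k) sum(1 / (k:n)) / n, 0)
  sig <- observed > expected
  k <- if (rule == "largest") {
    if (any(sig)) max(ks[sig]) else 1L
  } else {
    first_bad <- which(!sig)
    if (!length(first_bad)) max(ks)
    else if (first_bad[1] == 1L) 1L
    else ks[first_bad[1] - 1L]
  }
  list(k = k, table = data.frame(k = ks, observed = observed,
                                 expected = expected, significant = sig))
}

#' Cut a CONISS tree into zones
#'
#' @param z a [coniss()] result.
#' @param k number of zones (1 to n).
#' @return integer vector of zone labels per sample, contiguous by
#'   construction, numbered so the deepest zone is zone 1.
#' @export
cut_zones <- function(z, k) {
  n <- z$n
  if (k < 1 || k > n) stop("k must lie in [1, n]")
  # replay the first n - k merges
  grp <- seq_len(n)
  if (k < n) {
    members <- vector("list", n - 1L)
    for (step in seq_len(n - k)) {
      get_m <- function(code) if (code < 0) -code else members[[code]]
      members[[step]] <- c(get_m(z$merge[step, 1L]), get_m(z$merge[step, 2L]))
    }
    for (step in seq_len(n - k)) grp[members[[step]]] <- n + step
  }
  # contiguous blocks; renumber deepest block = zone 1
  r <- rle(grp)
  zl <- rev(seq_along(r$values))
  rep(zl, r$lengths)
}

#' Within-zone dispersion of a partition
#'
#' The objective CONISS minimizes greedily: for each zone `C`,
#' `sum_{i<j in C} d_ij^2 / |C|`, summed over zones.  Used to compare cuts
#' against exhaustively optimal contiguous partitions.
#'
#' @param m dissimilarity [resemblance_matrix()], `dist` or matrix.
#' @param zones integer zone label per sample (contiguous blocks).
#' @return numeric total within-zone dispersion.
#' @export
zone_dispersion <- function(m, zones) {
  D <- if (inherits(m, "resemblance_matrix")) m$values else as.matrix(m)
  sum(vapply(unique(zones), function(z) {
    idx <- which(zones == z)
    if (length(idx) < 2) return(0)
    sum(D[idx, idx]^2) / 2 / length(idx)
  }, 0))
}
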