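# Pairwise resemblance among samples: Bray-Curtis on (transformed)
# assemblage data, Euclidean profiles for environmental variables, and
# similarity/dissimilarity conversion.

#' Resemblance matrix container
#'
#' @param values symmetric numeric matrix (or `dist`).
#' @param kind `"dissimilarity"` or `"similarity"`.
#' @param coefficient coefficient name, e.g. `"bray_curtis"`, `"euclidean"`.
#' @param sample_ids sample labels.
#' @param transform description of any upstream transform.
#' @param bounded logical: entries bounded in `[0, 1]` (Bray-Curtis) or not
#'   (Euclidean).  Unbounded matrices refuse conversion to similarity.
#' @return object of class `resemblance_matrix`.
#' @export
resemblance_matrix <- function(values, kind = c("dissimilarity", "similarity"),
                               coefficient = "unknown", sample_ids = NULL,
                               transform = "none", bounded = NA) {
  kind <- match.arg(kind)
  m <- as.matrix(values)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-10))
    stop("resemblance matrix must be square and symmetric")
  diag_target <- if (kind == "dissimilarity") 0 else 1
  if (any(abs(diag(m) - diag_target) > 1e-10))
    stop("diagonal must be ", diag_target, " for ", kind)
  if (is.null(sample_ids))
    sample_ids <- rownames(m) %||% paste0("S", seq_len(nrow(m)))
  dimnames(m) <- list(sample_ids, sample_ids)
  if (is.na(bounded)) bounded <- all(m >= 0 & m <= 1)
  structure(list(values = m, kind = kind, coefficient = coefficient,
                 sample_ids = sample_ids, transform = transform,
                 bounded = bounded),
            class = "resemblance_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.resemblance_matrix <- function(x, ...) {
  cat(sprintf("%s matrix (%s, %s transform): %d samples\n",
              x$kind, x$coefficient, x$transform, nrow(x$values)))
  invisible(x)
}

#' @export
as.dist.resemblance_matrix <- function(m, diag = FALSE, upper = FALSE) {
  if (m$kind != "dissimilarity")
    stop("convert to dissimilarity before coercing to dist")
  stats::as.dist(m$values, diag = diag, upper = upper)
}

#' Bray-Curtis resemblance of assemblage samples
#'
#' Dissimilarity `d_jk = sum |x_j - x_k| / sum (x_j + x_k)` over taxa.  The
#' conventional pipeline square-root transforms abundances first
#' ([sqrt_transform()]); passing untransformed data requires
#' `allow_untransformed = TRUE` so the omission is explicit, never silent.
#'
#' @param counts an [assemblage_counts()] object (or plain non-negative
#'   matrix, accepted as already-transformed values).
#' @param allow_untransformed permit counts whose mode is not
#'   `"transformed"`.
#' @return a `dissimilarity` [resemblance_matrix()] with entries in `[0, 1]`.
#' @export
bray_curtis <- function(counts, allow_untransformed = FALSE) {
  if (inherits(counts, "assemblage_counts")) {
    if (counts$mode != "transformed" && !allow_untransformed)
      stop("abundances are not sqrt-transformed; apply sqrt_transform() ",
           "or set allow_untransformed = TRUE")
    vals <- counts$values
    ids <- counts$sample_ids
    tr <- if (counts$mode == "transformed") "sqrt" else "none"
  } else {
    vals <- as.matrix(counts)
    ids <- rownames(vals)
    tr <- "caller-supplied"
  }
  if (any(rowSums(vals) == 0)) stop("all-zero sample row")
  d <- vegan::vegdist(vals, method = "bray")
  resemblance_matrix(as.matrix(d), "dissimilarity", "bray_curtis",
                     sample_ids = ids, transform = tr, bounded = TRUE)
}

#' Euclidean distance matrix of an environmental profile
#'
#' For a single variable this is `|v_j - v_k|`; for a multivariate profile
#' the usual Euclidean distance across columns.
#'
#' @param values numeric vector (single variable over samples) or matrix
#'   (samples x variables); no undefined entries allowed.
#' @param sample_ids optional labels.
#' @return a `dissimilarity` [resemblance_matrix()] (unbounded).
#' @export
euclidean_matrix <- function(values, sample_ids = NULL) {
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (anyNA(v)) stop("undefined entries in profile")
  d <- as.matrix(stats::dist(v))
  resemblance_matrix(d, "dissimilarity", "euclidean",
                     sample_ids = sample_ids %||% rownames(v),
                     bounded = FALSE)
}

#' Convert between similarity and dissimilarity
#'
#' Bounded coefficients convert via `s = 1 - d`.  Unbounded matrices
#' (Euclidean) refuse conversion to similarity.
#'
#' @param m a [resemblance_matrix()].
#' @param to `"similarity"` or `"dissimilarity"`.
#' @return a [resemblance_matrix()] of the requested kind.
#' @export
convert_resemblance <- function(m, to = c("dissimilarity", "similarity")) {
  to <- match.arg(to)
  if (m$kind == to) return(m)
  if (to == "similarity" && !m$bounded)
    stop("unbounded coefficient (", m$coefficient,
         ") cannot be converted to similarity")
  out <- m
  out$values <- 1 - m$values
  out$kind <- to
  out
}
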