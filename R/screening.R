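# Count-significance screening of samples and taxa, and the standard
# abundance transformations applied ahead of resemblance analysis.

#' Probable-error screen for sample counts
#'
#' A sample passes when its total specimen count exceeds the probable error
#' `pe = 1.96 * s / sqrt(T_i)` and reaches the minimum count target.  `s` is
#' the standard deviation of per-sample totals across the dataset, so `pe`
#' shares the units of the totals it is compared against.  The
#' `"literal"` variant substitutes each taxon's fractional abundance into the
#' square root instead (a historically printed form of the formula) and
#' compares the total against the largest resulting per-taxon `pe`.
#'
#' @param counts an [assemblage_counts()] object.  Counts mode, or relative
#'   mode with `totals` recorded; relative mode without totals assumes the
#'   `min_total` target count per sample (recorded in the result).
#' @param min_total minimum specimen count per sample (default 150).
#' @param variant `"total"` (default) or `"literal"`; see Details.
#' @return object of class `screening_result`: data frame `samples` with
#'   columns `sample`, `total`, `pe`, `pass`; the `s` used; the variant;
#'   and `assumed_totals` flag.
#' @export
probable_error_screen <- function(counts, min_total = 150,
                                  variant = c("total", "literal")) {
  variant <- match.arg(variant)
  tot <- sample_totals(counts, min_total)
  s <- stats::sd(tot$totals)
  if (is.na(s)) s <- 0  # single-sample dataset
  if (variant == "total") {
    pe <- 1.96 * s / sqrt(tot$totals)
  } else {
    rel <- counts$values / rowSums(counts$values)
    pe <- apply(rel, 1, function(p) {
      p <- p[p > 0]
      max(1.96 * s / sqrt(p))
    })
  }
  pass <- tot$totals > pe & tot$totals >= min_total
  structure(list(
    samples = data.frame(sample = counts$sample_ids, total = tot$totals,
                         pe = pe, pass = pass, row.names = NULL),
    s = s, variant = variant, min_total = min_total,
    assumed_totals = tot$assumed,
    n_pass = sum(pass)), class = "screening_result")
}

#' Species standard-error screen
#'
#' Per taxon and sample the standard error of a fractional abundance `X` at
#' total count `N` is `S_X = 1.96 * sqrt(X * (1 - X) / N)`.  A taxon is
#' retained at dataset level if `S_X < X` in at least one sample.
#'
#' @inheritParams probable_error_screen
#' @return object of class `screening_result` with data frame `taxa`
#'   (`taxon`, `max_abundance`, `pass`), matrices `abundance` and `se`,
#'   `n_retained`, and the screened [assemblage_counts()] in `screened`.
#' @export
species_error_screen <- function(counts, min_total = 150) {
  tot <- sample_totals(counts, min_total)
  if (any(tot$totals == 0)) stop("sample with zero total count")
  rel <- counts$values / rowSums(counts$values)
  se <- 1.96 * sqrt(rel * (1 - rel) / tot$totals)
  sig <- se < rel                      # zero abundance never significant
  pass <- apply(sig, 2, any)
  keep <- counts
  keep$values <- counts$values[, pass, drop = FALSE]
  structure(list(
    taxa = data.frame(taxon = colnames(counts$values),
                      max_abundance = apply(rel, 2, max),
                      pass = pass, row.names = NULL),
    abundance = rel, se = se, n_retained = sum(pass),
    assumed_totals = tot$assumed, screened = keep),
    class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  if (!is.null(x$samples))
    cat(sprintf("Probable-error screen (%s variant, s = %.3g): %d of %d samples pass\n",
                x$variant, x$s, x$n_pass, nrow(x$samples)))
  if (!is.null(x$taxa))
    cat(sprintf("Species standard-error screen: %d of %d taxa retained\n",
                x$n_retained, nrow(x$taxa)))
  invisible(x)
}

# Totals for error formulas: recorded totals if available, else the minimum
# count target (documented via assumed = TRUE).
sample_totals <- function(counts, min_total) {
  if (counts$mode == "counts") {
    list(totals = rowSums(counts$values), assumed = FALSE)
  } else if (!is.null(counts$totals)) {
    list(totals = counts$totals, assumed = FALSE)
  } else {
    list(totals = rep(min_total, nrow(counts$values)), assumed = TRUE)
  }
}

#' Convert counts to relative abundances
#'
#' @param counts an [assemblage_counts()] object.
#' @return an [assemblage_counts()] in relative mode (rows sum to 1); totals
#'   preserved for downstream error formulas.
#' @export
to_relative <- function(counts) {
  rs <- rowSums(counts$values)
  if (any(rs == 0))
    stop("zero-total sample(s): ",
         paste(counts$sample_ids[rs == 0], collapse = ", "))
  out <- counts
  out$values <- counts$values / rs
  out$mode <- "relative"
  if (is.null(out$totals) && counts$mode == "counts") out$totals <- rs
  out
}

#' Square-root transform abundances
#'
#' Element-wise square root, the conventional variance-stabilizing transform
#' applied before Bray-Curtis resemblance.  The mode flag becomes
#' `"transformed"` so downstream coefficients can verify the transform was
#' applied rather than silently assuming it.
#'
#' @param counts an [assemblage_counts()] object.
#' @return transformed [assemblage_counts()].
#' @export
sqrt_transform <- function(counts) {
  out <- counts
  out$values <- sqrt(counts$values)
  out$mode <- "transformed"
  out
}

#' Reconstruct integer counts from relative abundances
#'
#' Scales each row to the target total and apportions to integers by the
#' largest-remainder method, so every reconstructed row sums exactly to its
#' target -- plain rounding would scatter totals around it.
#'
#' @param counts relative-mode [assemblage_counts()].
#' @param total target specimen count per sample (scalar or per-sample).
#' @return counts-mode [assemblage_counts()].
#' @export
reconstruct_counts <- function(counts, total = 150) {
  rel <- counts$values / rowSums(counts$values)
  total <- rep_len(total, nrow(rel))
  vals <- t(vapply(seq_len(nrow(rel)), function(i) {
    raw <- rel[i, ] * total[i]
    fl <- floor(raw)
    short <- total[i] - sum(fl)
    if (short > 0) {
      extra <- order(raw - fl, decreasing = TRUE)[seq_len(short)]
      fl[extra] <- fl[extra] + 1
    }
    fl
  }, numeric(ncol(rel))))
  colnames(vals) <- colnames(rel)
  assemblage_counts(vals, sample_ids = counts$sample_ids,
                    depth_top = counts$depth_top,
                    depth_bottom = counts$depth_bottom,
                    mode = "counts")
}
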