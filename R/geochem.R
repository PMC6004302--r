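# Geochemical covariate screening and derivation: censoring rule,
# detection-limit substitution, aluminum normalization, redox-tracer
# ratios, and redundancy reduction among element distance structures.

#' Censoring screen for geochemical variables
#'
#' An element is dropped when more than `threshold` of its entries are
#' censored (missing, below or above the detection limit).  Surviving
#' censored entries are substituted: below-DL cells get DL/2 (standard
#' practice), above-DL cells get the DL itself.
#'
#' @param profile a [geochem_profile()].
#' @param threshold maximum tolerated censored fraction (default 0.25).
#' @return list of class `screened_geochem`: `profile` (substituted,
#'   retained elements only), `dropped` (data frame element/reason/
#'   censored_fraction), `substitutions` (count per element), `threshold`.
#' @export
censoring_screen <- function(profile, threshold = 0.25) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  flags <- profile$flags
  frac <- colMeans(flags != "none")
  drop <- frac > threshold
  conc <- profile$conc
  nsub <- integer(ncol(conc))
  names(nsub) <- colnames(conc)
  for (el in colnames(conc)[!drop]) {
    below <- flags[, el] == "below_DL"
    above <- flags[, el] == "above_DL"
    conc[below, el] <- conc[below, el] / 2
    # above-DL cells keep the DL value itself
    nsub[el] <- sum(below | above)
    if (any(flags[, el] == "missing"))
      conc[flags[, el] == "missing", el] <- NA_real_
  }
  kept <- geochem_profile(profile$depth,
                          conc[, !drop, drop = FALSE],
                          flags[, !drop, drop = FALSE],
                          profile$units[!drop])
  dropped <- data.frame(element = colnames(profile$conc)[drop],
                        reason = rep("gt25pct_censored", sum(drop)),
                        censored_fraction = unname(frac[drop]),
                        row.names = NULL)
  structure(list(profile = kept, dropped = dropped,
                 substitutions = nsub[!drop], threshold = threshold,
                 substitution_rule = "below_DL -> DL/2; above_DL -> DL"),
            class = "screened_geochem")
}

#' @export
print.screened_geochem <- function(x, ...) {
  cat(sprintf("Geochemical screen: %d elements retained, %d dropped (threshold %.0f%%)\n",
              ncol(x$profile$conc), nrow(x$dropped), 100 * x$threshold))
  invisible(x)
}

#' Normalize element concentrations against aluminum
#'
#' Divides every element's ppm profile by the same-sample aluminum ppm
#' (unitless ratio), aluminum being treated as stratigraphically immobile.
#' Aluminum itself leaves the covariate set (its normalized profile is
#' identically 1).
#'
#' @param profile a [geochem_profile()] containing an uncensored `Al`
#'   column.
#' @return a [geochem_profile()] of Al-ratio profiles (unit `"ratio"`).
#' @export
aluminum_normalize <- function(profile) {
  if (!"Al" %in% colnames(profile$conc))
    stop("Al not present in profile")
  al <- profile$conc[, "Al"]
  alflag <- profile$flags[, "Al"]
  if (any(alflag != "none") || any(is.na(al)) || any(al == 0))
    stop("Al must be uncensored and non-zero at every depth")
  keep <- setdiff(colnames(profile$conc), "Al")
  conc <- profile$conc[, keep, drop = FALSE] / al
  geochem_profile(profile$depth, conc,
                  profile$flags[, keep, drop = FALSE],
                  stats::setNames(rep("ratio", length(keep)), keep))
}

#' Redox-tracer ratio series
#'
#' Ratios of redox-sensitive elements to sulfur and manganese down-core,
#' used to judge whether concentration peaks reflect deposition or
#' post-depositional mobilization.  A zero tracer at a depth yields an
#' undefined (NA) entry, never a dropped row.
#'
#' @param profile a [geochem_profile()].
#' @param numerators elements to ratio (default As, Hg, Fe, intersected
#'   with what is present).
#' @param tracers tracer elements (default S and Mn).
#' @return data frame with `depth` and one column per `numerator/tracer`
#'   pair (named e.g. `"As_S"`).
#' @export
redox_ratios <- function(profile, numerators = c("As", "Hg", "Fe"),
                         tracers = c("S", "Mn")) {
  have <- colnames(profile$conc)
  numerators <- intersect(numerators, have)
  miss <- setdiff(tracers, have)
  if (length(miss)) stop("tracer element(s) absent: ",
                         paste(miss, collapse = ", "))
  out <- data.frame(depth = profile$depth)
  for (num in numerators) for (tr in tracers) {
    v <- profile$conc[, num] / profile$conc[, tr]
    v[profile$conc[, tr] == 0] <- NA_real_
    out[[paste(num, tr, sep = "_")]] <- v
  }
  out
}

#' Redundancy reduction among element distance structures
#'
#' Second-stage resemblance analysis: each element's depth profile becomes
#' a Euclidean distance matrix over samples; the Spearman rank correlation
#' between the off-diagonal entries of every matrix pair forms the
#' element-by-element redundancy matrix.  Within any pair correlated above
#' `rho_threshold`, the member whose own RELATE rho against the biotic
#' matrix is weaker is dropped (ties broken by fewer censored entries,
#' then alphabetically).
#'
#' @param profile a [geochem_profile()].
#' @param biotic biotic dissimilarity [resemblance_matrix()] used to score
#'   which redundant element matters more to the assemblages.
#' @param rho_threshold redundancy cutoff (default 0.95).
#' @return list of class `screened_geochem` with `profile` (retained),
#'   `dropped` (element, reason, partner), `redundancy` (symmetric
#'   rank-correlation matrix), `biotic_rho` (per element).
#' @export
redundancy_reduce <- function(profile, biotic, rho_threshold = 0.95) {
  els <- colnames(profile$conc)
  if (length(els) < 2) stop("need at least 2 elements")
  if (length(profile$depth) < 3) stop("need at least 3 samples")
  dm <- lapply(els, function(el) as.vector(stats::dist(profile$conc[, el])))
  names(dm) <- els
  k <- length(els)
  red <- diag(1, k)
  dimnames(red) <- list(els, els)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    red[i, j] <- red[j, i] <- stats::cor(dm[[i]], dm[[j]],
                                         method = "spearman")
  brho <- vapply(els, function(el)
    relate(biotic, euclidean_matrix(profile$conc[, el]), n_perm = 0)$value,
    0)
  ncens <- colSums(profile$flags != "none")
  dropped <- character(0); partner <- character(0)
  keep <- els
  repeat {
    pairs <- which(red[keep, keep, drop = FALSE] > rho_threshold &
                     upper.tri(red[keep, keep, drop = FALSE]),
                   arr.ind = TRUE)
    if (!nrow(pairs)) break
    a <- keep[pairs[1, 1]]; b <- keep[pairs[1, 2]]
    # drop the member with weaker biotic rho; ties by censored count, name
    loser <- if (brho[a] != brho[b]) {
      c(a, b)[which.min(c(brho[a], brho[b]))]
    } else if (ncens[a] != ncens[b]) {
      c(a, b)[which.max(c(ncens[a], ncens[b]))]
    } else max(a, b)  # alphabetical: retain the earlier name
    dropped <- c(dropped, loser)
    partner <- c(partner, setdiff(c(a, b), loser))
    keep <- setdiff(keep, loser)
    if (length(keep) < 2) break
  }
  kept <- geochem_profile(profile$depth,
                          profile$conc[, keep, drop = FALSE],
                          profile$flags[, keep, drop = FALSE],
                          profile$units[keep])
  structure(list(profile = kept,
                 dropped = if (length(dropped))
                   data.frame(element = dropped, reason = "redundant",
                              partner = partner, row.names = NULL)
                 else data.frame(element = character(0),
                                 reason = character(0),
                                 partner = character(0)),
                 redundancy = red, biotic_rho = brho,
                 rho_threshold = rho_threshold),
            class = "screened_geochem")
}
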