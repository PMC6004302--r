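# Shannon diversity with lake-health banding and the
# difflugiid/centropyxid stress ratio.

#' Shannon diversity index of one sample
#'
#' `SDI = -sum(p_i * log(p_i))` in nats over the taxa present (zero entries
#' excluded); abundances are renormalized to proportions first, so counts
#' and proportions give the same value.
#'
#' @param abundances non-negative numeric vector with at least one positive
#'   entry.
#' @return numeric SDI (nats).
#' @seealso [sdi_band()]
#' @export
shannon_index <- function(abundances) {
  if (all(abundances == 0)) stop("all-zero sample")
  if (any(abundances < 0)) stop("negative abundance")
  p <- abundances[abundances > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Health band for an SDI value
#'
#' Lakes are classed `stable` for SDI in `[2.5, 3.5]`, `transition` for
#' `[1.5, 2.5)` and `stressed` below 1.5.  The 2.5 boundary belongs to the
#' stable band.  Values above 3.5 are reported `stable` as well (the banding
#' has no upper stress class).
#'
#' @param sdi numeric vector of SDI values.
#' @return character vector of band labels.
#' @export
sdi_band <- function(sdi) {
  ifelse(sdi >= 2.5, "stable",
         ifelse(sdi >= 1.5, "transition", "stressed"))
}

#' Difflugiid/centropyxid stress ratio of one sample
#'
#' `ratio = D / (D + C)` where `D` sums taxa with group `difflugiid` and
#' `in_dc_ratio = TRUE` and `C` sums centropyxid taxa.  Taxa with group
#' `other` and ratio-excluded difflugiids (e.g. the planktic eutrophication
#' indicator *Cucurbitella tricuspis*) enter neither term.  Values near 1
#' indicate difflugiid dominance (healthy conditions); values below the
#' conventional 0.55 cutoff flag a stressed, centropyxid-dominated
#' assemblage.
#'
#' @param abundances named non-negative numeric vector (taxon names must
#'   resolve in `registry`).
#' @param registry a [taxon_registry()].
#' @param stress_cutoff ratio below which the sample is flagged stressed.
#' @return list with `ratio`, `stressed`, and the summed `D` and `C`.
#' @export
dc_ratio <- function(abundances, registry, stress_cutoff = 0.55) {
  if (is.null(names(abundances))) stop("abundances must be named by taxon")
  reg <- resolve_taxa(registry, names(abundances))
  D <- sum(abundances[reg$group == "difflugiid" & reg$in_dc_ratio])
  C <- sum(abundances[reg$group == "centropyxid"])
  if (D + C == 0) stop("no ratio-eligible taxa present (D + C = 0)")
  r <- D / (D + C)
  list(ratio = r, stressed = r < stress_cutoff, D = D, C = C)
}

#' Down-core index profile
#'
#' Computes, per sample, the Shannon diversity index (on renormalized
#' relative abundances), its health band, species richness, and the
#' difflugiid/centropyxid stress ratio.
#'
#' @param counts an [assemblage_counts()] object.
#' @param registry a [taxon_registry()].
#' @param stress_cutoff see [dc_ratio()].
#' @return data frame of class `index_profile`: `sample`, `depth`, `sdi`,
#'   `richness`, `band`, `dc_ratio`, `dc_stressed`, in down-core order.
#' @export
index_profile <- function(counts, registry, stress_cutoff = 0.55) {
  rel <- counts$values / rowSums(counts$values)
  sdi <- apply(rel, 1, shannon_index)
  rat <- apply(rel, 1, function(row) dc_ratio(row, registry, stress_cutoff)$ratio)
  out <- data.frame(sample = counts$sample_ids, depth = counts$depth,
                    sdi = sdi, richness = rowSums(rel > 0),
                    band = sdi_band(sdi), dc_ratio = rat,
                    dc_stressed = rat < stress_cutoff, row.names = NULL)
  class(out) <- c("index_profile", "data.frame")
  out
}
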