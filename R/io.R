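# Readers, writers and validated in-memory containers for assemblage,
# geochemistry, loss-on-ignition and age-depth tables.

#' Normalize a taxon name for matching
#'
#' Matching is case-insensitive, strain quote marks (straight or curly) are
#' stripped, whitespace is collapsed, and the historical spelling variants
#' "Medilous"/"Mediolus" are treated as synonyms.
#'
#' @param x character vector of taxon names.
#' @return character vector of canonical matching keys.
#' @export
normalize_taxon_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[\"“”‘’']", "", x)
  x <- gsub("\\s+", " ", x)
  x <- sub("^medilous ", "mediolus ", x)
  x
}

#' Assemblage count/relative-abundance container
#'
#' Validated samples-by-taxa matrix indexed by down-core depth.  Samples must
#' be in strictly increasing, non-overlapping depth order.  In `"counts"`
#' mode values must be non-negative integers; in `"relative"` mode each row
#' must sum to 1 within `tolerance` (printed tables are typically rounded to
#' two decimals) and rows are renormalized to sum to exactly 1 after
#' validation.  The nominal depth of a sample is the bottom of its interval.
#'
#' @param values numeric matrix, samples x taxa, with taxon column names.
#' @param sample_ids character vector of sample labels.
#' @param depth_top,depth_bottom numeric vectors, interval bounds in cm.
#' @param mode `"counts"`, `"relative"` or `"transformed"`.
#' @param totals per-sample specimen counts; required in counts mode (derived
#'   from row sums when missing), optional in relative mode.
#' @param tolerance allowed deviation of relative-mode row sums from 1.
#' @return an object of class `assemblage_counts` with elements `values`,
#'   `sample_ids`, `depth_top`, `depth_bottom`, `depth` (nominal), `mode`,
#'   `totals`.
#' @export
assemblage_counts <- function(values, sample_ids = rownames(values),
                              depth_top = seq_len(nrow(values)) - 1,
                              depth_bottom = seq_len(nrow(values)),
                              mode = c("counts", "relative", "transformed"),
                              totals = NULL, tolerance = 0.05) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("assemblage values must carry taxon column names")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  n <- nrow(values)
  stopifnot(length(sample_ids) == n, length(depth_top) == n,
            length(depth_bottom) == n)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(values < 0)) stop("negative abundance values")
  if (any(depth_bottom <= depth_top))
    stop("each sample interval must have depth_bottom > depth_top")
  if (n > 1) {
    if (any(diff(depth_bottom) <= 0) || any(diff(depth_top) <= 0))
      stop("depths must be strictly increasing down-core")
    if (any(depth_top[-1] < depth_bottom[-n] - 1e-9))
      stop("overlapping depth intervals")
  }
  if (mode == "counts") {
    if (any(abs(values - round(values)) > 1e-8))
      stop("counts mode requires integer values")
    values <- round(values)
    if (is.null(totals)) totals <- rowSums(values)
    if (any(abs(totals - rowSums(values)) > 1e-8))
      stop("totals disagree with row sums in counts mode")
  } else if (mode == "relative") {
    rs <- rowSums(values)
    bad <- which(abs(rs - 1) > tolerance)
    if (length(bad))
      stop("relative-abundance row sum outside tolerance for sample(s): ",
           paste0(sample_ids[bad], " (", round(rs[bad], 3), ")",
                  collapse = ", "))
    if (any(rs == 0)) stop("zero-total sample in relative mode")
    values <- values / rs
  }
  rownames(values) <- sample_ids
  structure(list(values = values, sample_ids = sample_ids,
                 depth_top = depth_top, depth_bottom = depth_bottom,
                 depth = depth_bottom, mode = mode, totals = totals),
            class = "assemblage_counts")
}

#' @export
print.assemblage_counts <- function(x, ...) {
  cat(sprintf("Assemblage table: %d samples x %d taxa (%s mode), depths %g-%g cm\n",
              nrow(x$values), ncol(x$values), x$mode,
              min(x$depth_top), max(x$depth_bottom)))
  invisible(x)
}

#' Read an assemblage table
#'
#' Expects a delimited file with a header row naming the taxa and columns
#' `sample`, `depth_top`, `depth_bottom` followed by one column per taxon.
#'
#' @param path file path.
#' @param mode `"counts"` or `"relative"`.
#' @param tolerance relative-mode row-sum tolerance.
#' @param sep field delimiter.
#' @param registry optional [taxon_registry()]; unknown taxa are reported.
#' @return an [assemblage_counts()] object.
#' @export
read_assemblage_table <- function(path, mode = c("relative", "counts"),
                                  tolerance = 0.05, sep = ",",
                                  registry = NULL) {
  mode <- match.arg(mode)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  need <- c("sample", "depth_top", "depth_bottom")
  if (!all(need %in% names(df)))
    stop("assemblage table must have columns: ", paste(need, collapse = ", "))
  taxa <- setdiff(names(df), need)
  vals <- as.matrix(df[, taxa, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyDuplicated(df$depth_bottom))
    stop("duplicate depths in assemblage table")
  out <- assemblage_counts(vals, sample_ids = as.character(df$sample),
                           depth_top = df$depth_top,
                           depth_bottom = df$depth_bottom,
                           mode = mode, tolerance = tolerance)
  if (!is.null(registry)) {
    unknown <- setdiff(normalize_taxon_name(taxa),
                       normalize_taxon_name(registry$taxon_id))
    if (length(unknown))
      warning("taxa absent from registry: ", paste(unknown, collapse = ", "))
  }
  out
}

#' Write an assemblage table
#'
#' Serializes at full precision so a write/read round trip is value-exact.
#'
#' @param x an [assemblage_counts()] object.
#' @param path output file path.
#' @param sep field delimiter.
#' @export
write_assemblage_table <- function(x, path, sep = ",") {
  df <- data.frame(sample = x$sample_ids, depth_top = x$depth_top,
                   depth_bottom = x$depth_bottom, check.names = FALSE)
  # 17 significant digits guarantee an exact double round trip
  vals <- as.data.frame(apply(x$values, 2, sprintf, fmt = "%.17g"),
                        check.names = FALSE)
  utils::write.table(cbind(df, vals), path, sep = sep, row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' Taxon registry
#'
#' Assigns each taxon a functional group (`centropyxid`, `difflugiid`,
#' `other`) and an `in_dc_ratio` flag controlling inclusion in the
#' difflugiid/centropyxid stress ratio.
#'
#' @param df data frame with columns `taxon_id`, `group`, `in_dc_ratio` and
#'   optionally `display_name`, `notes`.
#' @return object of class `taxon_registry` (a validated data frame).
#' @export
taxon_registry <- function(df) {
  need <- c("taxon_id", "group", "in_dc_ratio")
  if (!all(need %in% names(df)))
    stop("taxon registry needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(normalize_taxon_name(df$taxon_id)))
    stop("duplicate taxon_id in registry")
  ok <- c("centropyxid", "difflugiid", "other")
  bad <- setdiff(unique(df$group), ok)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  df$in_dc_ratio <- as.logical(df$in_dc_ratio)
  if (anyNA(df$in_dc_ratio)) stop("in_dc_ratio must be logical")
  rownames(df) <- NULL
  class(df) <- c("taxon_registry", "data.frame")
  df
}

#' Read a taxon registry from CSV
#'
#' @param path CSV with `taxon_id`, `group`, `in_dc_ratio` columns.
#' @return a [taxon_registry()].
#' @export
read_taxon_registry <- function(path) {
  taxon_registry(utils::read.csv(path, stringsAsFactors = FALSE,
                                 check.names = FALSE))
}

#' Default registry for the 32 Frame Lake taxa
#'
#' All *Centropyxis* taxa are centropyxid; *Arcella vulgaris* is `other`;
#' *Cucurbitella tricuspis* is difflugiid-lineage but excluded from the
#' stress ratio (`in_dc_ratio = FALSE`) as a planktic eutrophication
#' indicator; the remaining difflugiid-lineage taxa (*Difflugia*,
#' *Lesquereusia*, *Lagenodifflugia*, *Pontigulasia*, *Mediolus*,
#' *Conicocassis*) enter the ratio.
#'
#' @return a [taxon_registry()] with 32 rows.
#' @export
default_taxon_registry <- function() {
  read_taxon_registry(system.file("extdata", "frame_lake_registry.csv",
                                  package = "paleoarc", mustWork = TRUE))
}

#' Look up registry rows for a set of taxa
#'
#' @param registry a [taxon_registry()].
#' @param taxa character vector of taxon names.
#' @return the registry rows in `taxa` order.
#' @export
resolve_taxa <- function(registry, taxa) {
  idx <- match(normalize_taxon_name(taxa), normalize_taxon_name(registry$taxon_id))
  if (anyNA(idx))
    stop("taxa missing from registry: ",
         paste(taxa[is.na(idx)], collapse = ", "))
  registry[idx, , drop = FALSE]
}

# ---- geochemistry ---------------------------------------------------------

#' Parse a geochemistry cell with censoring dialect
#'
#' `"<x"` parses to value `x` flagged `below_DL`; `">x"` to `x` flagged
#' `above_DL`; blank/NA to `missing`; anything else must be numeric.
#' @noRd
parse_geochem_cell <- function(cell) {
  cell <- trimws(as.character(cell))
  if (is.na(cell) || cell == "" || cell == "NA")
    return(list(value = NA_real_, flag = "missing"))
  if (startsWith(cell, "<"))
    return(list(value = as.numeric(substring(cell, 2)), flag = "below_DL"))
  if (startsWith(cell, ">"))
    return(list(value = as.numeric(substring(cell, 2)), flag = "above_DL"))
  v <- suppressWarnings(as.numeric(cell))
  if (is.na(v)) stop("non-numeric uncensored geochemistry cell: '", cell, "'")
  list(value = v, flag = "none")
}

ppm_factor <- function(unit) {
  switch(unit,
         "ppm" = 1, "mg/kg" = 1,
         "ppb" = 1e-3, "ug/kg" = 1e-3,
         "%" = 1e4, "pct" = 1e4, "percent" = 1e4,
         stop("unknown unit: '", unit, "'"))
}

#' Geochemical depth profile container
#'
#' @param depth numeric, strictly increasing depths (cm).
#' @param conc numeric matrix depth x element, concentrations in ppm.
#' @param flags character matrix of the same shape with entries in
#'   `none`, `below_DL`, `above_DL`, `missing`.
#' @param units named character vector of original units per element.
#' @return object of class `geochem_profile`.
#' @export
geochem_profile <- function(depth, conc, flags = NULL, units = NULL) {
  conc <- as.matrix(conc)
  if (ncol(conc) > 0 && is.null(colnames(conc)))
    stop("element columns must be named")
  if (is.null(flags)) {
    flags <- matrix("none", nrow(conc), ncol(conc),
                    dimnames = dimnames(conc))
    flags[is.na(conc)] <- "missing"
  }
  if (is.null(units)) units <- stats::setNames(rep("ppm", ncol(conc)), colnames(conc))
  stopifnot(length(depth) == nrow(conc), all(dim(flags) == dim(conc)))
  if (any(diff(depth) <= 0)) stop("depths must be strictly increasing")
  bad <- conc < 0 & flags == "none"
  if (any(bad, na.rm = TRUE)) stop("negative uncensored concentration")
  structure(list(depth = depth, conc = conc, flags = flags, units = units),
            class = "geochem_profile")
}

#' @export
print.geochem_profile <- function(x, ...) {
  cat(sprintf("Geochemistry profile: %d depths x %d elements (%s)\n",
              length(x$depth), ncol(x$conc),
              paste(colnames(x$conc), collapse = ", ")))
  invisible(x)
}

#' Read a geochemistry table
#'
#' One `depth` column plus one column per element.  Cells may use the
#' censoring dialect `"<x"` / `">x"`; blanks are missing.  All values are
#' converted to ppm using `unit_map`.
#'
#' @param path file path.
#' @param unit_map named character vector mapping element to its original
#'   unit (`"%"`, `"ppm"`, `"ppb"`); elements not named default to ppm.
#' @param sep field delimiter.
#' @return a [geochem_profile()] (concentrations stored in ppm).
#' @export
read_geochem_table <- function(path, unit_map = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!"depth" %in% names(df)) stop("geochemistry table needs a 'depth' column")
  depth <- as.numeric(df$depth)
  elements <- setdiff(names(df), "depth")
  conc <- matrix(NA_real_, length(depth), length(elements),
                 dimnames = list(NULL, elements))
  flags <- matrix("missing", length(depth), length(elements),
                  dimnames = list(NULL, elements))
  units <- stats::setNames(rep("ppm", length(elements)), elements)
  if (!is.null(unit_map)) units[names(unit_map)] <- unit_map
  for (el in elements) {
    f <- ppm_factor(units[[el]])
    for (i in seq_along(depth)) {
      p <- parse_geochem_cell(df[[el]][i])
      conc[i, el] <- p$value * f
      flags[i, el] <- p$flag
    }
  }
  geochem_profile(depth, conc, flags, units)
}

# ---- loss on ignition -----------------------------------------------------

#' Read a loss-on-ignition table
#'
#' Columns `depth`, `water`, `organics`, `carbonates`, `minerogenics`, all
#' fractions of mass in `[0, 1]`.  The dry-mass closure
#' organics + carbonates + minerogenics = 1 is enforced within `tolerance`
#' (printed tables rounded to two decimals close to within about 0.02).
#'
#' @param path file path.
#' @param tolerance allowed deviation of the dry-mass closure from 1.
#' @param sep field delimiter.
#' @return data frame of class `loi_table`.
#' @export
read_loi_table <- function(path, tolerance = 0.02, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("depth", "water", "organics", "carbonates", "minerogenics")
  if (!all(need %in% names(df)))
    stop("LOI table needs columns: ", paste(need, collapse = ", "))
  fr <- as.matrix(df[, need[-1]])
  if (any(fr < 0 | fr > 1)) stop("LOI fractions must lie in [0, 1]")
  if (any(diff(df$depth) <= 0)) stop("depths must be strictly increasing")
  closure <- df$organics + df$carbonates + df$minerogenics
  bad <- which(abs(closure - 1) > tolerance)
  if (length(bad))
    stop("dry-mass closure violated at depth(s): ",
         paste(df$depth[bad], collapse = ", "))
  class(df) <- c("loi_table", "data.frame")
  df
}

# ---- age-depth tie points -------------------------------------------------

#' Read an age-depth tie-point table
#'
#' Columns `depth` (cm) and an age column in calendar years AD (named
#' `age_pb210`, `age` or `year`); optional sedimentation-rate columns are
#' carried through.  Rows with a blank age are kept (flagged `NA`) so that
#' rate-only rows and sub-hiatus rows survive for annotation.
#'
#' @param path file path.
#' @param sep field delimiter.
#' @return data frame of class `age_depth_table` with columns `depth`,
#'   `year` and any extra columns from the file.
#' @export
read_age_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!"depth" %in% names(df)) stop("age table needs a 'depth' column")
  agecol <- intersect(c("age_pb210", "age", "year"), names(df))[1]
  if (is.na(agecol)) stop("age table needs an age column (age_pb210/age/year)")
  df$year <- as.numeric(df[[agecol]])
  if (any(diff(df$depth) <= 0)) stop("depths must be strictly increasing")
  class(df) <- c("age_depth_table", "data.frame")
  df
}
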