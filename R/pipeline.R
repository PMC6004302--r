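# Orchestration of the full analysis: screening -> indices -> geochemistry
# -> resemblance -> zonation -> inference -> ordination -> chronology,
# with CSV/JSON artifact output and a provenance-carrying run report.

#' Pipeline configuration
#'
#' @param counts an [assemblage_counts()] object or path to an assemblage
#'   CSV.
#' @param registry a [taxon_registry()] or path; defaults to the packaged
#'   registry when the taxa resolve in it.
#' @param loi optional `loi_table` or path.
#' @param geochem optional [geochem_profile()] or path.
#' @param ages optional `age_depth_table` or path.
#' @param mode assemblage mode when `counts` is a path.
#' @param min_total minimum specimen count for screening.
#' @param censor_threshold geochemical censoring threshold.
#' @param rho_threshold redundancy threshold for element reduction.
#' @param max_k maximum zone count for broken-stick selection.
#' @param zonation_transform transform of the relative abundances fed to
#'   CONISS: `"none"` (default) or `"sqrt"`.  The inference/ordination
#'   matrix is always the square-root Bray-Curtis one; only the zonation
#'   stage is governed here (see the methods vignette for why the
#'   untransformed matrix is the zonation default).
#' @param zonation_coefficient `"bray"` (default) or `"euclidean"`
#'   (classic squared-Euclidean CONISS).
#' @param n_perm permutations for ANOSIM/RELATE.
#' @param seed RNG seed; mandatory because permutation tests are always
#'   part of a full run.
#' @param hiatus_depth optional hiatus depth for the age model.
#' @param nmds_starts NMDS random starts.
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, registry = NULL, loi = NULL,
                            geochem = NULL, ages = NULL,
                            mode = "relative", min_total = 150,
                            censor_threshold = 0.25, rho_threshold = 0.95,
                            max_k = 10,
                            zonation_transform = c("none", "sqrt"),
                            zonation_coefficient = c("bray", "euclidean"),
                            n_perm = 999, seed,
                            hiatus_depth = NULL, nmds_starts = 50,
                            out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory for a pipeline run")
  zonation_transform <- match.arg(zonation_transform)
  zonation_coefficient <- match.arg(zonation_coefficient)
  structure(as.list(environment()), class = "pipeline_config")
}

load_input <- function(x, reader, ...) {
  if (is.character(x)) reader(x, ...) else x
}

#' Run the full assemblage analysis pipeline
#'
#' Stages, in order: input validation; probable-error and species
#' standard-error screening; diversity/stress index profile; geochemical
#' screening (censoring, aluminum normalization) when geochemistry is
#' supplied; biotic Bray-Curtis resemblance on square-root-transformed
#' relative abundances; CONISS zonation with broken-stick zone selection;
#' one-way ANOSIM across the zones; RELATE rank correlation of every
#' environmental covariate against the biotic matrix, ranked by rho; NMDS;
#' and age annotation of the zones when an age table is supplied.
#' Optional inputs that are absent skip their stages with a logged reason
#' rather than aborting.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report` with per-stage results, `skipped`
#'   (named reasons), `config`, and timing per stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(stages = list(), skipped = list(),
                 config = config, timing = c())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    report$timing[name] <<- proc.time()[["elapsed"]] - t0
    report$stages[[name]] <<- out
    out
  }

  counts <- stage("read", load_input(config$counts, read_assemblage_table,
                                     mode = config$mode))
  registry <- if (is.null(config$registry)) default_taxon_registry()
              else load_input(config$registry, read_taxon_registry)
  loi <- if (is.null(config$loi)) NULL else load_input(config$loi, read_loi_table)
  geochem <- if (is.null(config$geochem)) NULL
             else load_input(config$geochem, read_geochem_table)
  ages <- if (is.null(config$ages)) NULL else load_input(config$ages, read_age_table)

  screen_counts <- if (counts$mode == "counts") counts
                   else reconstruct_counts(counts, config$min_total)
  stage("screening", list(
    samples = probable_error_screen(screen_counts, config$min_total),
    taxa = species_error_screen(screen_counts, config$min_total)))
  stage("indices", index_profile(counts, registry))

  if (is.null(geochem)) {
    report$skipped$geochem <- "no geochemistry input supplied"
  } else {
    stage("geochem", {
      sc <- censoring_screen(geochem, config$censor_threshold)
      norm <- tryCatch(aluminum_normalize(sc$profile),
                       error = function(e) NULL)
      list(screened = sc, normalized = norm)
    })
  }

  biotic <- stage("resemblance",
                  bray_curtis(sqrt_transform(to_relative(counts))))
  zc <- stage("zonation", {
    rel <- to_relative(counts)
    zin <- if (config$zonation_transform == "sqrt") sqrt_transform(rel)
           else rel
    zmat <- if (config$zonation_coefficient == "euclidean")
      euclidean_matrix(zin$values, sample_ids = counts$sample_ids)
    else bray_curtis(zin, allow_untransformed = TRUE)
    z <- coniss(zmat)
    bs <- broken_stick_select(z, min(config$max_k, z$n))
    zones <- cut_zones(z, bs$k)
    list(tree = z, broken_stick = bs, k = bs$k, zones = zones,
         sizes = as.integer(table(zones)))
  })
  stage("anosim", if (zc$k < 2) {
    report$skipped$anosim <- "single zone: ANOSIM undefined"
    NULL
  } else anosim_test(biotic, zc$zones, n_perm = config$n_perm,
                     seed = config$seed))

  covariates <- list()
  if (!is.null(loi))
    for (v in c("water", "organics", "carbonates", "minerogenics"))
      covariates[[v]] <- loi[[v]]
  if (!is.null(geochem) && !is.null(report$stages$geochem$normalized)) {
    norm <- report$stages$geochem$normalized
    for (el in colnames(norm$conc)) covariates[[el]] <- norm$conc[, el]
  }
  if (length(covariates)) {
    stage("relate", {
      out <- lapply(names(covariates), function(v) {
        r <- tryCatch(relate(biotic, euclidean_matrix(covariates[[v]]),
                             n_perm = config$n_perm, seed = config$seed),
                      error = function(e) NULL)  # e.g. constant covariate
        data.frame(covariate = v,
                   rho = if (is.null(r)) NA_real_ else r$value,
                   p = if (is.null(r)) NA_real_ else r$p)
      })
      tab <- do.call(rbind, out)
      tab[order(-tab$rho, na.last = TRUE), ]
    })
  } else report$skipped$relate <- "no environmental covariates supplied"

  stage("ordination", {
    ord <- nmds(biotic, k = 2, n_starts = config$nmds_starts,
                seed = config$seed)
    list(nmds = ord, overlay = zone_overlay(ord, zc$zones))
  })

  if (is.null(ages)) {
    report$skipped$chronology <- "no age table supplied"
  } else {
    stage("chronology", {
      model <- age_depth_model(
        if (is.null(config$hiatus_depth)) ages
        else ages[ages$depth <= max(config$hiatus_depth), ],
        hiatus_depth = config$hiatus_depth)
      zone_tab <- data.frame(sample = counts$sample_ids,
                             depth = counts$depth, zone = zc$zones)
      aa <- assign_age(model, zone_tab$depth)
      zone_tab$year <- aa$year
      zone_tab$note <- aa$note
      zone_ages <- do.call(rbind, lapply(split(zone_tab, zone_tab$zone),
        function(zz) {
          dated <- !is.na(zz$year)
          data.frame(
            zone = zz$zone[1], n = nrow(zz), n_dated = sum(dated),
            depth_from = min(zz$depth), depth_to = max(zz$depth),
            year_from = if (any(dated)) min(zz$year[dated]) else NA_real_,
            year_to = if (any(dated)) max(zz$year[dated]) else NA_real_,
            note = if (!any(dated)) zz$note[!dated][1]
                   else if (all(dated)) "dated"
                   else paste0("partly ", zz$note[!dated][1]))
        }))
      list(model = model, samples = zone_tab, zones = zone_ages)
    })
  }

  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  z <- x$stages$zonation
  if (!is.null(z))
    cat(sprintf("  zones: %d (sizes deep-to-shallow: %s)\n", z$k,
                paste(z$sizes, collapse = "/")))
  if (!is.null(x$stages$anosim))
    cat(sprintf("  ANOSIM R = %.3f, p = %.4g\n", x$stages$anosim$value,
                x$stages$anosim$p))
  if (!is.null(x$stages$relate)) {
    cat("  RELATE (ranked):\n")
    print(utils::head(x$stages$relate, 5), row.names = FALSE)
  }
  if (!is.null(x$stages$ordination))
    cat(sprintf("  NMDS stress-1 = %.4f\n",
                x$stages$ordination$nmds$stress))
  for (s in names(x$skipped))
    cat("  skipped ", s, ": ", x$skipped[[s]], "\n", sep = "")
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Emits indices, zone table, broken-stick table, test results and ranked
#' RELATE correlations as CSV, plus a JSON run-metadata sidecar echoing the
#' configuration.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$stages$indices,
                   file.path(dir, "indices.csv"), row.names = FALSE)
  z <- report$stages$zonation
  counts <- report$stages$read
  utils::write.csv(data.frame(sample = counts$sample_ids,
                              depth = counts$depth, zone = z$zones),
                   file.path(dir, "zones.csv"), row.names = FALSE)
  utils::write.csv(z$broken_stick$table,
                   file.path(dir, "broken_stick.csv"), row.names = FALSE)
  if (!is.null(report$stages$relate))
    utils::write.csv(report$stages$relate,
                     file.path(dir, "relate_ranked.csv"), row.names = FALSE)
  meta <- list(
    package = "paleoarc",
    version = as.character(utils::packageVersion("paleoarc")),
    seed = report$config$seed, n_perm = report$config$n_perm,
    zones = z$k, zone_sizes = z$sizes,
    anosim = if (!is.null(report$stages$anosim))
      list(R = report$stages$anosim$value, p = report$stages$anosim$p),
    skipped = report$skipped, timing = as.list(report$timing))
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
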