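# Accessors for the packaged Frame Lake (Yellowknife, NWT) core dataset:
# a 30-sample x 32-taxon Arcellinida relative-abundance record with
# loss-on-ignition fractions, published diversity/stress index values,
# lead-210/ash-layer ages and radiocarbon dates.

fl_path <- function(file) {
  system.file("extdata", file, package = "paleoarc", mustWork = TRUE)
}

#' Frame Lake assemblage table
#'
#' 30 samples (1 cm resolution, 0-30 cm) by 32 Arcellinida taxa, relative
#' abundances rounded to two decimals as published.
#'
#' @return an [assemblage_counts()] in relative mode.
#' @export
frame_lake_assemblage <- function() {
  read_assemblage_table(fl_path("frame_lake_assemblage.csv"),
                        mode = "relative", tolerance = 0.05)
}

#' Frame Lake loss-on-ignition fractions
#'
#' @return a `loi_table` data frame (depth, water, organics, carbonates,
#'   minerogenics).
#' @export
frame_lake_loi <- function() read_loi_table(fl_path("frame_lake_loi.csv"))

#' Frame Lake published index values
#'
#' The Shannon diversity index and difflugiid/centropyxid ratio as printed
#' alongside the assemblage table, for comparison with recomputed values.
#'
#' @return data frame `sample`, `sdi`, `dc_ratio`.
#' @export
frame_lake_printed_indices <- function() {
  utils::read.csv(fl_path("frame_lake_printed_indices.csv"),
                  stringsAsFactors = FALSE)
}

#' Frame Lake lead-210 / ash-layer age table
#'
#' Depth rows with the lead-210 age model (years AD) and the two published
#' sedimentation-rate columns.  Ages printed below the 17 cm unconformity
#' are downward extrapolations and are excluded by the default age model
#' (see [frame_lake_age_model()]).
#'
#' @return an `age_depth_table` data frame.
#' @export
frame_lake_ages <- function() read_age_table(fl_path("frame_lake_ages.csv"))

#' Default Frame Lake age-depth model
#'
#' Piecewise-linear model over the 21 tie points above the 17 cm
#' unconformity; queries below it return the early-Holocene sentinel
#' (the sub-hiatus radiocarbon date is 7,230 +/- 128 BP).
#'
#' @return an [age_depth_model()].
#' @export
frame_lake_age_model <- function() {
  ages <- frame_lake_ages()
  age_depth_model(ages[ages$depth <= 17, ], hiatus_depth = 17,
                  below_note = "below unconformity, age > 7,000 BP")
}

#' Frame Lake radiocarbon dates
#'
#' Published uncalibrated radiocarbon ages for the upper core.  The upper
#' 15 cm dates are stratigraphically jumbled (allochthonous carbon) and are
#' shipped as annotation only; they never enter the age model.
#'
#' @return data frame `interval_cm`, `c14_age_bp`, `c14_err`, `f14c`,
#'   `f14c_err`.
#' @export
frame_lake_radiocarbon <- function() {
  utils::read.csv(fl_path("frame_lake_radiocarbon.csv"),
                  stringsAsFactors = FALSE)
}
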