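# Age-depth modelling from tie points (210Pb ages, dated ash layers) with
# hard-hiatus support, and sedimentation-rate series.

#' Build an age-depth model from tie points
#'
#' Piecewise-linear interpolation between (depth, calendar year AD) tie
#' points, split into independent segments at hiatus depths.  Within a
#' segment age must strictly increase (year decrease) with depth.  Tie
#' points falling below a hiatus with no further tie points are excluded
#' from interpolation; queries there return the hiatus' sentinel note
#' instead of a number.  Extrapolation beyond the modelled range is
#' refused.
#'
#' @param ties data frame with columns `depth` and `year` (an
#'   `age_depth_table` from [read_age_table()] works as is); rows with `NA`
#'   year are ignored for interpolation.
#' @param hiatus_depth optional numeric vector of hiatus depths (cm).
#' @param below_note sentinel string returned for queries below the last
#'   hiatus when no deeper segment exists (e.g. `"below unconformity, age
#'   > 7,000 BP"`).
#' @return object of class `age_depth_model` with `segments` (list of tie
#'   data frames), `hiatuses`, `below_note`, `range`.
#' @export
age_depth_model <- function(ties, hiatus_depth = NULL,
                            below_note = "below unconformity, age > 7,000 BP") {
  ties <- as.data.frame(ties)
  stopifnot(all(c("depth", "year") %in% names(ties)))
  ties <- ties[!is.na(ties$year), c("depth", "year")]
  ties <- ties[order(ties$depth), ]
  hiatus_depth <- sort(hiatus_depth)
  edges <- c(-Inf, hiatus_depth, Inf)
  segments <- list()
  for (i in seq_len(length(edges) - 1)) {
    seg <- ties[ties$depth > edges[i] & ties$depth <= edges[i + 1] |
                  (i == 1 & ties$depth == edges[i]), , drop = FALSE]
    # a segment is usable only with >= 2 tie points
    if (nrow(seg) >= 2) {
      if (any(diff(seg$year) >= 0))
        stop("age reversal within a segment (year must decrease with depth)")
      segments[[length(segments) + 1L]] <-
        list(ties = seg, from = if (i == 1) min(seg$depth) else edges[i],
             to = min(max(seg$depth), edges[i + 1]))
    } else if (nrow(seg) == 1 && i < length(edges) - 1) {
      stop("segment between hiatuses has a single tie point")
    }
  }
  if (!length(segments)) stop("need >= 2 tie points in some segment")
  structure(list(segments = segments, hiatuses = hiatus_depth,
                 below_note = below_note,
                 range = range(ties$depth)),
            class = "age_depth_model")
}

#' @export
print.age_depth_model <- function(x, ...) {
  cat(sprintf("Age-depth model: %d segment(s), %s hiatus(es), depths %g-%g cm\n",
              length(x$segments), length(x$hiatuses), x$range[1], x$range[2]))
  invisible(x)
}

#' Query ages from an age-depth model
#'
#' @param model an [age_depth_model()].
#' @param depth numeric vector of depths (cm).
#' @return data frame `depth`, `year` (NA where no age is defined), `note`
#'   (`"interpolated"`, `"tie point"`, the hiatus sentinel, or
#'   `"outside model range"`).
#' @export
assign_age <- function(model, depth) {
  year <- rep(NA_real_, length(depth))
  note <- rep("outside model range", length(depth))
  for (seg in model$segments) {
    inside <- depth >= min(seg$ties$depth) & depth <= max(seg$ties$depth)
    if (any(inside)) {
      year[inside] <- stats::approx(seg$ties$depth, seg$ties$year,
                                    xout = depth[inside])$y
      note[inside] <- ifelse(depth[inside] %in% seg$ties$depth,
                             "tie point", "interpolated")
    }
  }
  if (length(model$hiatuses)) {
    h_last <- max(model$hiatuses)
    has_lower_segment <- any(vapply(model$segments, function(s)
      min(s$ties$depth) > h_last, FALSE))
    if (!has_lower_segment)
      note[is.na(year) & depth > h_last] <- model$below_note
  }
  data.frame(depth = depth, year = year, note = note)
}

#' Sedimentation rates between successive tie points
#'
#' Per-interval rate `= delta depth / delta year` (cm/yr) within each
#' segment of the model.
#'
#' @param model an [age_depth_model()].
#' @return data frame `depth_top`, `depth_bottom`, `rate`.
#' @export
sedimentation_rates <- function(model) {
  out <- do.call(rbind, lapply(model$segments, function(seg) {
    t <- seg$ties
    dy <- -diff(t$year)
    if (any(dy == 0)) stop("zero year difference between tie points")
    data.frame(depth_top = t$depth[-nrow(t)], depth_bottom = t$depth[-1],
               rate = diff(t$depth) / dy)
  }))
  rownames(out) <- NULL
  out
}

#' Mean sedimentation rate over a depth window
#'
#' @param model an [age_depth_model()].
#' @param from,to depth window (cm).
#' @return mean of the interval rates whose midpoints fall in the window.
#' @export
mean_sedimentation_rate <- function(model, from, to) {
  r <- sedimentation_rates(model)
  mid <- (r$depth_top + r$depth_bottom) / 2
  mean(r$rate[mid >= from & mid <= to])
}

#' Convert calendar year AD to years before present (1950 datum)
#'
#' @param year calendar years AD.
#' @return years BP.
#' @export
year_to_bp <- function(year) 1950 - year
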