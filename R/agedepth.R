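#' Date core horizons from an age-depth model
#'
#' Assigns calendar dates to sediment depths from radiometrically anchored
#' (depth, date) points: depths inside the anchored range are linearly
#' interpolated between bracketing anchors; deeper depths are extrapolated
#' with a second-order polynomial fitted to all anchors. Extrapolated (or
#' interpolated) dates earlier than `floor_date` (default 1750 CE, below
#' which sediment chronologies become unreliable) are excluded with a
#' reason.
#'
#' @param anchors data frame with columns `depth_cm` (increasing) and
#'   `date_CE` (strictly decreasing with depth); at least 2 anchors for
#'   interpolation, 3 for extrapolation.
#' @param depths depths (cm) to date.
#' @param floor_date earliest admissible date.
#' @return data frame `depth_cm`, `date_CE` (NA when excluded), `method`
#'   (`"interpolated"`, `"extrapolated"`, `"anchor"`), and `excluded`
#'   (reason or NA). The quadratic fit's R-squared is attached as
#'   attribute `r_squared` when extrapolation is used.
#' @examples
#' date_horizons(data.frame(depth_cm = c(0, 10), date_CE = c(2016, 1916)),
#'               depths = 5)
#' @export
date_horizons <- function(anchors, depths, floor_date = 1750) {
  stopifnot(is.data.frame(anchors),
            all(c("depth_cm", "date_CE") %in% names(anchors)))
  anchors <- anchors[order(anchors$depth_cm), , drop = FALSE]
  if (nrow(anchors) < 2L) stop("need at least 2 anchors")
  if (is.unsorted(-anchors$date_CE, strictly = TRUE)) {
    stop("anchor dates must strictly decrease with depth")
  }
  inside <- depths >= min(anchors$depth_cm) & depths <= max(anchors$depth_cm)
  dates <- rep(NA_real_, length(depths))
  method <- ifelse(depths %in% anchors$depth_cm, "anchor",
                   ifelse(inside, "interpolated", "extrapolated"))
  if (any(inside)) {
    dates[inside] <- approx(anchors$depth_cm, anchors$date_CE,
                            xout = depths[inside])$y
  }
  r2 <- NA_real_
  if (any(!inside)) {
    if (nrow(anchors) < 3L) {
      stop("quadratic extrapolation needs at least 3 anchors")
    }
    quad <- lm(date_CE ~ depth_cm + I(depth_cm^2), data = anchors)
    r2 <- suppressWarnings(summary(quad))$r.squared
    dates[!inside] <- predict(quad,
                              data.frame(depth_cm = depths[!inside]))
  }
  excluded <- ifelse(!is.na(dates) & dates < floor_date,
                     sprintf("date %.0f CE earlier than the %.0f CE floor",
                             dates, floor_date),
                     NA_character_)
  dates[!is.na(excluded)] <- NA_real_
  out <- data.frame(depth_cm = depths, date_CE = dates, method = method,
                    excluded = excluded, stringsAsFactors = FALSE)
  attr(out, "r_squared") <- r2
  out
}

#' Catchment-to-lake area ratio
#'
#' Ratio of watershed to lake area, reported to three significant figures.
#' Sites without a defined lake area (rivers) yield `NA`.
#'
#' @param watershed_area,lake_area areas in the same unit (km^2).
#' @return numeric ratio(s) rounded to 3 significant figures, `NA` where
#'   either area is missing or non-positive.
#' @examples
#' catchment_ratio(800, 11.2)   # 71.4
#' catchment_ratio(0.95, 0.13)  # 7.31
#' @export
catchment_ratio <- function(watershed_area, lake_area) {
  out <- ifelse(is.na(watershed_area) | is.na(lake_area) |
                  watershed_area <= 0 | lake_area <= 0,
                NA_real_, signif(watershed_area / lake_area, 3))
  out
}

#' Geomorphological site metadata
#'
#' Reads the bundled table of the nine study sites (abbreviation, country,
#' coordinates, lake and watershed areas, peak total mercury) shipped as
#' plain TSV under `inst/extdata`.
#'
#' @return data frame, one row per site.
#' @export
site_metadata <- function() {
  path <- system.file("extdata", "site_metadata.tsv", package = "paleoNe",
                      mustWork = TRUE)
  read_tsv_checked(path, required = c("site_id", "lake_area_km2",
                                      "watershed_area_km2"))
}
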