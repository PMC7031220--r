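#' Effective population size trajectories
#'
#' Constructs a deterministic effective-population-size function of calendar
#' time, `Ne(t)`. Trajectories are the ground truth of the coalescent
#' simulator and the estimand of the skyline sampler. Time is measured in
#' calendar years CE and Ne on the coalescent scale (effective individuals
#' times generation time, in years).
#'
#' Supported forms:
#' \describe{
#'   \item{`constant`}{`Ne(t) = base_ne`.}
#'   \item{`exponential`}{`Ne(t) = base_ne * exp(steepness * (t - breakpoint_date))`,
#'     anchored so `Ne(breakpoint_date) = base_ne`.}
#'   \item{`piecewise_constant`}{step function through `grid` knots
#'     `(date_CE, ne)`; left of the first knot the first value applies.}
#'   \item{`sigmoidal_breakpoint`}{logistic increase
#'     `Ne(t) = base_ne * (1 + (fold_change - 1) / (1 + exp(-steepness * (t - breakpoint_date))))`,
#'     rising from `base_ne` to `base_ne * fold_change` with midpoint at
#'     `breakpoint_date`.}
#' }
#'
#' @param kind one of `"constant"`, `"exponential"`, `"piecewise_constant"`,
#'   `"sigmoidal_breakpoint"`.
#' @param base_ne baseline Ne, must be positive.
#' @param fold_change ratio of late to early Ne (sigmoidal form); must be
#'   >= 1 so the trajectory is monotone non-decreasing.
#' @param breakpoint_date calendar year CE of the logistic midpoint (or the
#'   anchor date of the exponential form).
#' @param steepness per-year logistic rate (sigmoidal) or growth rate
#'   (exponential); non-negative for the sigmoidal form.
#' @param grid data frame with columns `date_CE` and `ne` for the piecewise
#'   form; knots must be strictly increasing in time with positive values.
#'
#' @return an object of class `ne_trajectory`; evaluate it with [ne_at()].
#' @seealso [ne_at()], [simulate_genealogy()]
#' @examples
#' traj <- ne_trajectory("sigmoidal_breakpoint", base_ne = 100,
#'                       fold_change = 10, breakpoint_date = 1784,
#'                       steepness = 0.05)
#' ne_at(traj, c(1700, 1784, 1900))
#' @export
ne_trajectory <- function(kind = c("constant", "exponential",
                                   "piecewise_constant",
                                   "sigmoidal_breakpoint"),
                          base_ne = 1, fold_change = 1,
                          breakpoint_date = 1800, steepness = 0.05,
                          grid = NULL) {
  kind <- match.arg(kind)
  if (kind != "piecewise_constant") {
    if (!is.numeric(base_ne) || length(base_ne) != 1L || !is.finite(base_ne) ||
        base_ne <= 0) {
      stop("'base_ne' must be a single positive number, got: ",
           deparse(base_ne))
    }
  }
  if (kind == "sigmoidal_breakpoint") {
    if (fold_change < 1 || steepness < 0) {
      stop("sigmoidal trajectories must be monotone non-decreasing: ",
           "need fold_change >= 1 and steepness >= 0")
    }
  }
  if (kind == "piecewise_constant") {
    if (is.null(grid) || !all(c("date_CE", "ne") %in% names(grid)) ||
        nrow(grid) < 1L) {
      stop("piecewise_constant requires a 'grid' with columns date_CE, ne")
    }
    if (is.unsorted(grid$date_CE, strictly = TRUE)) {
      stop("piecewise knots must be strictly ordered in time")
    }
    if (any(grid$ne <= 0)) stop("piecewise Ne values must be positive")
  }
  structure(list(kind = kind, base_ne = base_ne, fold_change = fold_change,
                 breakpoint_date = breakpoint_date, steepness = steepness,
                 grid = grid),
            class = "ne_trajectory")
}

#' Evaluate an Ne trajectory at calendar dates
#'
#' @param traj an [ne_trajectory()] object.
#' @param dates_CE numeric vector of calendar years.
#' @return numeric vector of Ne values, all positive.
#' @export
ne_at <- function(traj, dates_CE) {
  stopifnot(inherits(traj, "ne_trajectory"), is.numeric(dates_CE))
  out <- switch(traj$kind,
    constant = rep(traj$base_ne, length(dates_CE)),
    exponential = traj$base_ne *
      exp(traj$steepness * (dates_CE - traj$breakpoint_date)),
    sigmoidal_breakpoint = traj$base_ne *
      (1 + (traj$fold_change - 1) /
         (1 + exp(-traj$steepness * (dates_CE - traj$breakpoint_date)))),
    piecewise_constant = {
      idx <- findInterval(dates_CE, traj$grid$date_CE)
      traj$grid$ne[pmax(idx, 1L)]
    })
  if (any(!is.finite(out)) || any(out <= 0)) {
    stop("trajectory evaluates to a non-positive or non-finite Ne")
  }
  out
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("Ne trajectory [", x$kind, "]\n", sep = "")
  switch(x$kind,
    constant = cat("  Ne =", x$base_ne, "\n"),
    exponential = cat("  base Ne ", x$base_ne, " at ", x$breakpoint_date,
                      " CE, rate ", x$steepness, "/yr\n", sep = ""),
    sigmoidal_breakpoint = cat("  ", x$base_ne, " -> ",
                               x$base_ne * x$fold_change,
                               ", midpoint ", x$breakpoint_date,
                               " CE, steepness ", x$steepness, "/yr\n",
                               sep = ""),
    piecewise_constant = cat("  ", nrow(x$grid), " knots spanning ",
                             min(x$grid$date_CE), "-", max(x$grid$date_CE),
                             " CE\n", sep = ""))
  invisible(x)
}
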