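#' Assemble the multi-site Ne-versus-date table
#'
#' Binds per-site posterior Ne trajectories (see [summarize_trajectory()])
#' into the long-format table consumed by the trend models, optionally
#' joining a covariate (e.g. total mercury). Dates before `floor_date`
#' (default 1750 CE, the validity floor of the sediment chronologies) are
#' dropped and counted in the `"clipped"` attribute. Missing covariate
#' values are imputed by the overall mean of the observed values.
#'
#' @param trajectories named list: site ID -> data frame with `date_CE`
#'   and `ne_median`.
#' @param grid optional vector of dates to retain (defaults to all).
#' @param covariates optional data frame `site_id`, `date_CE`, plus one
#'   covariate column; joined on site and date.
#' @param floor_date earliest admissible calendar date.
#' @return data frame `site_id`, `date_CE`, `ne_median` (plus covariate),
#'   with attribute `clipped` = number of rows removed by the date floor.
#' @export
assemble_ne_table <- function(trajectories, grid = NULL, covariates = NULL,
                              floor_date = 1750) {
  if (length(trajectories) == 0L) stop("no trajectories supplied")
  stopifnot(!is.null(names(trajectories)))
  rows <- lapply(names(trajectories), function(s) {
    tr <- trajectories[[s]]
    stopifnot(all(c("date_CE", "ne_median") %in% names(tr)))
    data.frame(site_id = s, date_CE = tr$date_CE, ne_median = tr$ne_median,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(grid)) tab <- tab[tab$date_CE %in% grid, , drop = FALSE]
  n_before <- nrow(tab)
  tab <- tab[tab$date_CE >= floor_date, , drop = FALSE]
  clipped <- n_before - nrow(tab)
  if (nrow(tab) == 0L) stop("no rows remain after the date floor")
  if (anyDuplicated(tab[, c("site_id", "date_CE")])) {
    stop("duplicated (site, date) pairs")
  }
  if (!is.null(covariates)) {
    cov_col <- setdiff(names(covariates), c("site_id", "date_CE"))
    stopifnot(length(cov_col) == 1L)
    key <- paste(tab$site_id, tab$date_CE)
    ckey <- paste(covariates$site_id, covariates$date_CE)
    val <- covariates[[cov_col]][match(key, ckey)]
    val[is.na(val)] <- mean(val, na.rm = TRUE)
    tab[[cov_col]] <- val
  }
  rownames(tab) <- NULL
  attr(tab, "clipped") <- clipped
  tab
}

#' Random-forest trend model with stratified repeated splits
#'
#' Fits random forests of `n_trees` trees to the Ne table, repeating a
#' stratified 80/20 train/test split `n_splits` times: every site
#' contributes proportionally to each test set so class imbalance among
#' sites does not bias the held-out score. The per-split prediction
#' accuracy is the pseudo-R-squared `1 - SSE/SST` on the test rows. The
#' response is `log10(ne_median)` by default (skyline posteriors are
#' scale-heavy); use `log10_response = FALSE` for the natural scale.
#'
#' @param table output of [assemble_ne_table()].
#' @param predictors character vector of predictor columns (default date
#'   and site).
#' @param n_trees trees per forest (default 5000).
#' @param n_splits number of random splits (default 10).
#' @param test_frac held-out fraction per split (default 0.2).
#' @param log10_response model `log10(ne_median)` (default `TRUE`).
#' @param seed integer seed.
#' @return object of class `rf_trend` holding the fitted forests, split
#'   memberships and per-split pseudo-R-squared scores.
#' @export
fit_rf <- function(table, predictors = c("date_CE", "site_id"),
                   n_trees = 5000, n_splits = 10, test_frac = 0.2,
                   log10_response = TRUE, seed = 1) {
  stopifnot(all(predictors %in% names(table)), length(predictors) >= 1L,
            "ne_median" %in% names(table))
  df <- table[, predictors, drop = FALSE]
  if ("site_id" %in% predictors) df$site_id <- factor(df$site_id)
  df$.y <- if (log10_response) log10(table$ne_median) else table$ne_median
  n <- nrow(df)
  strata <- if ("site_id" %in% predictors) table$site_id else
    rep("all", n)
  small <- names(which(table(strata) < 5))
  if (length(small)) {
    warning("sites with < 5 rows (", paste(small, collapse = ", "),
            "); falling back to a global split")
    strata <- rep("all", n)
  }
  with_seed(seed, {
    models <- vector("list", n_splits)
    test_rows <- vector("list", n_splits)
    r2 <- numeric(n_splits)
    for (s in seq_len(n_splits)) {
      te <- unlist(lapply(split(seq_len(n), strata), function(idx) {
        sample(idx, max(1L, round(length(idx) * test_frac)))
      }), use.names = FALSE)
      tr <- setdiff(seq_len(n), te)
      # with <= 3 predictors, per-split feature subsampling only injects
      # noise; consider every predictor at each split (bootstrap still
      # decorrelates the trees)
      fit <- ranger::ranger(.y ~ ., data = df[tr, , drop = FALSE],
                            num.trees = n_trees,
                            mtry = length(predictors),
                            num.threads = 1,
                            seed = sample.int(2^31 - 1, 1L))
      pred <- predict(fit, df[te, , drop = FALSE],
                      num.threads = 1)$predictions
      y_te <- df$.y[te]
      r2[s] <- 1 - sum((y_te - pred)^2) / sum((y_te - mean(y_te))^2)
      models[[s]] <- fit
      test_rows[[s]] <- sort(te)
    }
    structure(list(models = models, test_rows = test_rows,
                   pseudo_r2 = r2, data = df, table = table,
                   predictors = predictors,
                   log10_response = log10_response,
                   config = list(n_trees = n_trees, n_splits = n_splits,
                                 test_frac = test_frac, seed = seed)),
              class = "rf_trend")
  })
}

#' @export
print.rf_trend <- function(x, ...) {
  cat("Random-forest trend model:", x$config$n_trees, "trees,",
      x$config$n_splits, "stratified splits\n")
  cat(sprintf("  mean held-out pseudo-R2: %.3f (range %.3f-%.3f)\n",
              mean(x$pseudo_r2), min(x$pseudo_r2), max(x$pseudo_r2)))
  invisible(x)
}

#' Partial dependence of the trend model on one predictor
#'
#' True partial dependence: for each grid value the predictor is clamped
#' to it in every *training* row of a split (the other predictors keep
#' their empirical joint distribution), predictions are averaged over the
#' rows, and the resulting per-model curves are averaged across the
#' splits.
#'
#' @param fit an `rf_trend`.
#' @param predictor predictor name (default `"date_CE"`).
#' @param grid evaluation grid (defaults to the sorted unique observed
#'   values).
#' @return data frame of class `pd_curve` with the grid column and `pd`
#'   (average prediction, on the modelling scale of the response).
#' @export
partial_dependence <- function(fit, predictor = "date_CE", grid = NULL) {
  stopifnot(inherits(fit, "rf_trend"))
  if (!predictor %in% fit$predictors) {
    stop("unknown predictor: ", predictor)
  }
  if (is.null(grid)) grid <- sort(unique(fit$data[[predictor]]))
  n_splits <- length(fit$models)
  acc <- matrix(0, length(grid), n_splits)
  for (s in seq_len(n_splits)) {
    train <- setdiff(seq_len(nrow(fit$data)), fit$test_rows[[s]])
    base <- fit$data[train, fit$predictors, drop = FALSE]
    big <- base[rep(seq_len(nrow(base)), times = length(grid)), ,
                drop = FALSE]
    big[[predictor]] <- rep(grid, each = nrow(base))
    pred <- predict(fit$models[[s]], big, num.threads = 1)$predictions
    acc[, s] <- colMeans(matrix(pred, nrow(base), length(grid)))
  }
  out <- data.frame(grid, pd = rowMeans(acc))
  names(out)[1L] <- predictor
  attr(out, "per_split") <- acc
  attr(out, "log10_response") <- fit$log10_response
  class(out) <- c("pd_curve", "data.frame")
  out
}

#' Predictor-omission sensitivity of the trend model
#'
#' Refits the random forest without one predictor and reports the mean
#' held-out pseudo-R-squared with and without it, quantifying how much of
#' the model's accuracy that predictor carries.
#'
#' @param table the Ne table.
#' @param predictor predictor to omit.
#' @param predictors full predictor set.
#' @param ... passed to [fit_rf()] (both fits share the same seed, so the
#'   split memberships agree).
#' @return list `with`, `without` (mean pseudo-R2) and `delta`.
#' @export
omission_sensitivity <- function(table, predictor = "date_CE",
                                 predictors = c("date_CE", "site_id"),
                                 ...) {
  stopifnot(predictor %in% predictors)
  reduced <- setdiff(predictors, predictor)
  if (length(reduced) == 0L) {
    stop("cannot omit the only predictor")
  }
  full <- fit_rf(table, predictors = predictors, ...)
  part <- fit_rf(table, predictors = reduced, ...)
  list(with = mean(full$pseudo_r2), without = mean(part$pseudo_r2),
       delta = mean(full$pseudo_r2) - mean(part$pseudo_r2),
       full = full, reduced = part)
}

#' Single-breakpoint segmented regression
#'
#' Fits the two-segment continuous linear model
#' `y = b0 + b1 x + b2 (x - psi)_+` by iterative linearisation
#' (refitting `y ~ x + (x - psi)_+ + I(x > psi)` and updating
#' `psi <- psi - gamma_hat / b2_hat` until the auxiliary coefficient
#' `gamma` vanishes). The confidence interval for `psi` uses the delta
#' method, `SE(psi) = SE(gamma_hat) / |b2_hat|` at convergence, with a
#' normal quantile at `ci_level`; a percentile case-resampling bootstrap
#' is available via `ci_method = "bootstrap"`.
#'
#' @param x numeric predictor (calendar dates) or a `pd_curve`.
#' @param y response; ignored when `x` is a `pd_curve`.
#' @param psi_start starting breakpoint (default 1800).
#' @param ci_level confidence level for the breakpoint (default 0.99).
#' @param ci_method `"delta"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap replicates (default 999).
#' @param tol convergence tolerance on the breakpoint update, years.
#' @param max_iter maximum linearisation iterations.
#' @param seed seed for the bootstrap.
#' @return object of class `breakpoint_fit`: breakpoint `psi`, its CI,
#'   left/right slopes, adjusted R-squared, iteration trace and the final
#'   two-segment `lm`.
#' @examples
#' x <- seq(1750, 2000, by = 5)
#' y <- ifelse(x < 1800, 0, 0.1 * (x - 1800))
#' segmented_fit(x, y)
#' @export
segmented_fit <- function(x, y = NULL, psi_start = 1800, ci_level = 0.99,
                          ci_method = c("delta", "bootstrap"),
                          n_boot = 999, tol = 1e-8, max_iter = 100,
                          seed = 1) {
  ci_method <- match.arg(ci_method)
  if (inherits(x, "pd_curve")) {
    y <- x$pd
    x <- x[[1L]]
  }
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 6L) stop("need at least 6 points")
  if (psi_start <= min(x) || psi_start >= max(x)) {
    stop("starting breakpoint must lie inside the data range")
  }
  core <- segmented_core(x, y, psi_start, tol, max_iter)
  psi <- core$psi
  z <- qnorm(1 - (1 - ci_level) / 2)
  if (ci_method == "delta") {
    ci <- c(psi - z * core$se_psi, psi + z * core$se_psi)
  } else {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(x), replace = TRUE)
        out <- tryCatch(
          segmented_core(x[idx], y[idx], psi_start, tol, max_iter)$psi,
          error = function(e) NA_real_)
        out
      }, numeric(1))
    })
    boots <- boots[!is.na(boots)]
    ci <- unname(quantile(boots, c((1 - ci_level) / 2,
                                   1 - (1 - ci_level) / 2)))
  }
  structure(list(psi = psi, ci = ci, ci_level = ci_level,
                 ci_method = ci_method,
                 slopes = core$slopes, adj_r2 = core$adj_r2,
                 se_psi = core$se_psi, trace = core$trace,
                 lm = core$fit, x = x, y = y,
                 converged = TRUE),
            class = "breakpoint_fit")
}

segmented_core <- function(x, y, psi_start, tol = 1e-8, max_iter = 100) {
  psi <- psi_start
  trace <- numeric(0)
  lo <- min(x); hi <- max(x)
  damp <- 1
  prev_step <- Inf
  for (it in seq_len(max_iter)) {
    U <- pmax(x - psi, 0)
    V <- as.numeric(x > psi)
    fit <- lm(y ~ x + U + V)
    cf <- coef(fit)
    b2 <- cf[["U"]]
    gam <- if (is.na(cf[["V"]])) 0 else cf[["V"]]
    if (is.na(b2) || b2 == 0) {
      stop(structure(class = c("segmented_error", "error", "condition"),
                     list(message = "degenerate fit: no slope change",
                          call = sys.call(-1), psi_trace = trace)))
    }
    # step-halving damping guards against the oscillation the raw
    # linearisation update is prone to near coarse grids
    step <- damp * gam / b2
    if (abs(step) >= abs(prev_step)) {
      damp <- damp / 2
      step <- damp * gam / b2
    }
    prev_step <- step
    psi_new <- psi - step
    trace <- c(trace, psi_new)
    if (psi_new <= lo || psi_new >= hi) {
      stop(structure(class = c("segmented_error", "error", "condition"),
                     list(message = sprintf(
                       "breakpoint escaped the data range [%g, %g] at iteration %d",
                       lo, hi, it),
                       call = sys.call(-1), psi_trace = trace)))
    }
    psi <- psi_new
    if (abs(step) < tol) break
    if (it == max_iter) {
      stop(structure(class = c("segmented_error", "error", "condition"),
                     list(message = "segmented fit did not converge",
                          call = sys.call(-1), psi_trace = trace)))
    }
  }
  # SE of psi by the delta method from the last linearisation
  se_gam <- tryCatch(suppressWarnings(summary(fit))$coefficients["V", "Std. Error"],
                     error = function(e) NA_real_)
  se_psi <- if (is.na(se_gam)) 0 else se_gam / abs(coef(fit)[["U"]])
  final <- lm(y ~ x + pmax(x - psi, 0))
  cf <- coef(final)
  list(psi = psi, se_psi = se_psi,
       slopes = c(left = unname(cf[2L]), right = unname(cf[2L] + cf[3L])),
       adj_r2 = suppressWarnings(summary(final))$adj.r.squared,
       trace = trace, fit = final)
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat("Segmented regression (single breakpoint)\n")
  cat(sprintf("  breakpoint: %.1f CE  [%.1f, %.1f] (%d%% CI, %s)\n",
              x$psi, x$ci[1], x$ci[2], round(100 * x$ci_level),
              x$ci_method))
  cat(sprintf("  slopes: %.4g (before) -> %.4g (after)\n",
              x$slopes["left"], x$slopes["right"]))
  cat(sprintf("  adjusted R2: %.3f\n", x$adj_r2))
  invisible(x)
}

#' @export
summary.breakpoint_fit <- function(object, ...) {
  print(object)
  cat("  iterations:", length(object$trace), "\n")
  invisible(object)
}

#' @export
coef.breakpoint_fit <- function(object, ...) {
  c(psi = object$psi, object$slopes)
}

#' @export
confint.breakpoint_fit <- function(object, parm = "psi", level = NULL, ...) {
  if (!is.null(level) && level != object$ci_level) {
    z <- qnorm(1 - (1 - level) / 2)
    return(c(object$psi - z * object$se_psi,
             object$psi + z * object$se_psi))
  }
  object$ci
}

#' @export
predict.breakpoint_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  cf <- coef(object$lm)
  unname(cf[1L] + cf[2L] * x + cf[3L] * pmax(x - object$psi, 0))
}

#' @export
residuals.breakpoint_fit <- function(object, ...) {
  object$y - predict(object)
}

#' @export
plot.breakpoint_fit <- function(x, ...) {
  plot(x$x, x$y, xlab = "date (CE)", ylab = "response", ...)
  ox <- sort(x$x)
  lines(ox, predict(x, ox), lwd = 2)
  abline(v = x$psi, lty = 4, col = "blue")
  abline(v = x$ci, lty = 3, col = "blue")
  invisible(x)
}

#' Exhaustive grid-search breakpoint oracle
#'
#' Independent verification of [segmented_fit()]: for every interior grid
#' value as candidate breakpoint, fit the two-segment continuous least
#' squares model and return the RSS-minimising candidate (ties broken by
#' the earliest date).
#'
#' @param x numeric predictor or `pd_curve`.
#' @param y response (ignored for a `pd_curve`).
#' @return the RSS-minimising breakpoint, with the RSS profile attached as
#'   attribute `profile`.
#' @export
breakpoint_grid_oracle <- function(x, y = NULL) {
  if (inherits(x, "pd_curve")) {
    y <- x$pd
    x <- x[[1L]]
  }
  ox <- order(x)
  x <- x[ox]; y <- y[ox]
  cand <- unique(x[x > min(x) & x < max(x)])
  rss <- vapply(cand, function(psi) {
    sum(resid(lm(y ~ x + pmax(x - psi, 0)))^2)
  }, numeric(1))
  best <- cand[which(rss == min(rss))]
  psi <- min(best)  # earliest-date tie rule
  attr(psi, "profile") <- data.frame(psi = cand, rss = rss)
  psi
}
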