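#' Coalescent interval decomposition of a timed genealogy
#'
#' Sweeps a binary timed tree from the most recent tip backwards and
#' returns the ordered inter-event intervals with their active lineage
#' count and terminating event type. This is the sufficient summary behind
#' every skyline computation: interval lengths `w`, lineage counts `k`,
#' and which events are coalescences.
#'
#' @param tt a `timed_tree` (see [simulate_genealogy()]).
#' @return data frame with columns `w` (years), `k` (lineages during the
#'   interval), `event` (`"coalescence"` or `"sampling"`), and
#'   `end_height`; attributes `root_height`, `n_tips` and
#'   `most_recent_date`.
#' @export
coalescent_intervals <- function(tt) {
  stopifnot(inherits(tt, "timed_tree"))
  tree <- tt$tree
  n_tip <- ape::Ntip(tree)
  if (tree$Nnode != n_tip - 1L) {
    stop("tree is not strictly binary (", tree$Nnode, " internal nodes for ",
         n_tip, " tips)")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  h <- node_heights(tt)
  tip_h <- h[seq_len(n_tip)]
  coal_h <- h[(n_tip + 1L):(2L * n_tip - 1L)]
  samp <- aggregate(list(n = rep(1L, n_tip)), by = list(h = tip_h), FUN = sum)
  ev <- rbind(data.frame(h = samp$h, type = "sampling", n = samp$n),
              data.frame(h = coal_h, type = "coalescence", n = 1L))
  # sampling first among coincident heights so k is counted correctly
  ev <- ev[order(ev$h, ev$type == "coalescence"), , drop = FALSE]
  k <- 0L
  prev <- ev$h[1L]
  out <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (i > 1L) {
      out[[i]] <- data.frame(w = ev$h[i] - prev, k = k, event = ev$type[i],
                             end_height = ev$h[i])
    }
    k <- if (ev$type[i] == "sampling") k + ev$n[i] else k - 1L
    if (k < 1L && i < nrow(ev)) stop("lineage count dropped below 1")
    prev <- ev$h[i]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "root_height") <- max(coal_h)
  attr(res, "n_tips") <- n_tip
  attr(res, "most_recent_date") <- tt$most_recent_date
  res
}

#' Classic skyline estimator
#'
#' Closed-form per-interval estimate of Ne: for each interval ending in a
#' coalescence, `Ne_hat = k (k - 1) w / 2`. Serves as the analytic oracle
#' for the Bayesian sampler.
#'
#' @param intervals output of [coalescent_intervals()].
#' @return data frame of coalescent-terminated intervals with `ne_hat`.
#' @export
classic_skyline <- function(intervals) {
  co <- intervals[intervals$event == "coalescence", , drop = FALSE]
  co$ne_hat <- co$k * (co$k - 1) * co$w / 2
  rownames(co) <- NULL
  co
}

# Exact integral of 1/Ne(h) over [a, b] for a step function given by
# `at` (ascending heights where values change; vals[i] applies on
# [at[i], at[i+1])) -- vals[1] also applies below at[1].
step_inv_integral <- function(a, b, at, vals) {
  if (b <= a) return(0)
  pts <- sort(unique(c(a, at[at > a & at < b], b)))
  mids <- (pts[-1L] + pts[-length(pts)]) / 2
  idx <- pmax(findInterval(mids, at), 1L)
  sum(diff(pts) / vals[idx])
}

step_value <- function(h, at, vals) vals[pmax(findInterval(h, at), 1L)]

#' Heterochronous coalescent log-likelihood
#'
#' Log-likelihood of a piecewise-constant Ne(t) given the coalescent
#' intervals of a timed tree:
#' `log L = sum_events -log Ne(t_event) - sum_intervals k(k-1)/2 * Int dt / Ne(t)`,
#' with the integral computed exactly for piecewise-constant Ne.
#'
#' @param intervals output of [coalescent_intervals()].
#' @param ne either a single positive number (constant Ne) or a data frame
#'   with columns `height` (ascending, years before the most recent tip)
#'   and `ne`, interpreted as a step function whose first value also
#'   applies below the first height.
#' @return log-likelihood (numeric scalar).
#' @export
coalescent_loglik <- function(intervals, ne) {
  if (is.numeric(ne) && length(ne) == 1L) {
    ne <- data.frame(height = 0, ne = ne)
  }
  stopifnot(is.data.frame(ne), all(c("height", "ne") %in% names(ne)))
  if (any(ne$ne <= 0)) stop("Ne must be positive everywhere")
  at <- ne$height
  vals <- ne$ne
  ll <- 0
  start <- intervals$end_height - intervals$w
  for (i in seq_len(nrow(intervals))) {
    ll <- ll - intervals$k[i] * (intervals$k[i] - 1) / 2 *
      step_inv_integral(start[i], intervals$end_height[i], at, vals)
    if (intervals$event[i] == "coalescence") {
      ll <- ll - log(step_value(intervals$end_height[i], at, vals))
    }
  }
  ll
}

# Per-tree sufficient statistics for a grouped skyline: event counts e_g and
# weighted interval sums S_g with logL = sum_g -e_g log Ne_g - S_g / Ne_g.
skyline_stats <- function(tt, n_groups, group_sizes = NULL) {
  iv <- coalescent_intervals(tt)
  n_events <- sum(iv$event == "coalescence")
  if (n_groups > n_events) {
    stop("n_groups (", n_groups, ") exceeds coalescent events (", n_events, ")")
  }
  if (is.null(group_sizes)) {
    base <- n_events %/% n_groups
    rem <- n_events %% n_groups
    group_sizes <- rep(base, n_groups)
    if (rem > 0) {  # remainder spread from the past end
      group_sizes[(n_groups - rem + 1L):n_groups] <-
        group_sizes[(n_groups - rem + 1L):n_groups] + 1L
    }
  }
  stopifnot(sum(group_sizes) == n_events, all(group_sizes >= 1L))
  g_of_event <- rep(seq_len(n_groups), times = group_sizes)
  # interval i is governed by the group of the next coalescence at/after it
  coal_seen <- cumsum(iv$event == "coalescence")
  next_coal <- pmin(coal_seen + (iv$event != "coalescence"), n_events)
  g_of_interval <- g_of_event[next_coal]
  A <- iv$k * (iv$k - 1) / 2 * iv$w
  e_g <- vapply(seq_len(n_groups), function(g) {
    sum(iv$event == "coalescence" & g_of_interval == g)
  }, numeric(1))
  S_g <- vapply(seq_len(n_groups), function(g) sum(A[g_of_interval == g]),
                numeric(1))
  coal_heights <- iv$end_height[iv$event == "coalescence"]
  list(e = e_g, S = S_g, coal_heights = coal_heights,
       group_sizes = group_sizes, intervals = iv,
       classic = classic_skyline(iv))
}

grouped_loglik <- function(ne, e, S) sum(-e * log(ne) - S / ne)

#' Grouped Bayesian skyline sampler
#'
#' Fits the piecewise-constant (grouped) skyline coalescent model to one
#' timed genealogy or a sample of genealogies by Metropolis-Hastings.
#' Coalescent intervals are merged into `n_groups` contiguous groups of
#' near-equal event counts (the remainder spread from the past end); the
#' per-group Ne values receive independent log-uniform priors centred on
#' the classic-skyline scale and are updated with multiplier proposals.
#' With several trees, `combine = "mix"` treats them as a posterior sample
#' and mixes over them with uniform tree moves (one proposal per
#' iteration), while `combine = "pool"` treats them as independent
#' genealogies of the same population and sums their log-likelihoods.
#' Chains run in duplicate by default and are pooled after burn-in.
#'
#' @param trees a `timed_tree` or a list of them (all with the same
#'   `most_recent_date`).
#' @param n_groups number of skyline groups `m` (default 25); must not
#'   exceed the number of coalescent events of any tree.
#' @param chain_length iterations per chain (each iteration sweeps all
#'   groups once).
#' @param thin record every `thin`-th iteration.
#' @param burn_in fraction of each chain discarded, in `[0, 0.5]`.
#' @param proposal_scale width of the log-space multiplier proposal.
#' @param n_chains number of duplicate chains (default 2).
#' @param combine `"mix"` or `"pool"`; ignored for a single tree.
#' @param prior_factor half-width of the log-uniform prior in factors of
#'   the classic-skyline scale (default `1e3`).
#' @param stochastic_groups draw the group sizes at random (a uniform
#'   composition) at initialisation instead of the even split.
#' @param ess_floor effective-sample-size level below which a warning is
#'   recorded in the fit (not an error).
#' @param seed integer seed.
#' @return object of class `skyline_fit` with posterior `draws`
#'   (iterations x groups), per-draw `tree_index`, `loglik` trace,
#'   per-group `ess`, the grouped statistics, and the configuration.
#'   Summarise on a calendar grid with [summarize_trajectory()].
#' @export
skyline_fit <- function(trees, n_groups = 25, chain_length = 10000,
                        thin = 10, burn_in = 0.10, proposal_scale = 1.0,
                        n_chains = 2, combine = c("mix", "pool"),
                        prior_factor = 1e3, stochastic_groups = FALSE,
                        ess_floor = 100, seed = 1) {
  combine <- match.arg(combine)
  if (inherits(trees, "timed_tree")) trees <- list(trees)
  stopifnot(length(trees) >= 1L, all(vapply(trees, inherits, TRUE,
                                            "timed_tree")))
  if (chain_length < 1 || thin < 1 || n_chains < 1) {
    stop("chain settings must be positive")
  }
  if (burn_in < 0 || burn_in > 0.5) stop("burn_in must be in [0, 0.5]")
  m <- as.integer(n_groups)
  with_seed(seed, {
    stats <- lapply(trees, function(tt) {
      gs <- NULL
      if (stochastic_groups) {
        ne_events <- ape::Ntip(tt$tree) - 1L
        cuts <- sort(sample.int(ne_events - 1L, m - 1L))
        gs <- diff(c(0L, cuts, ne_events))
      }
      skyline_stats(tt, m, group_sizes = gs)
    })
    n_tree <- length(stats)
    Emat <- do.call(rbind, lapply(stats, `[[`, "e"))
    Smat <- do.call(rbind, lapply(stats, `[[`, "S"))
    pooled_e <- colSums(Emat)
    pooled_S <- colSums(Smat)
    # classic-skyline scale anchors both the init and the prior support
    scale0 <- mean(unlist(lapply(stats, function(s) s$classic$ne_hat)))
    scale0 <- max(scale0, .Machine$double.eps)
    lo <- scale0 / prior_factor
    hi <- scale0 * prior_factor
    init <- pmin(pmax(colSums(Smat) / pmax(colSums(Emat), 1), lo), hi)

    n_keep <- floor(chain_length / thin)
    first_keep <- floor(n_keep * burn_in) + 1L
    draws_all <- list()
    tree_idx_all <- integer(0)
    ll_all <- numeric(0)
    for (chain in seq_len(n_chains)) {
      ne <- init
      cur_tree <- 1L
      e <- if (combine == "pool") pooled_e else Emat[cur_tree, ]
      S <- if (combine == "pool") pooled_S else Smat[cur_tree, ]
      ll <- grouped_loglik(ne, e, S)
      draws <- matrix(NA_real_, n_keep, m)
      tree_rec <- integer(n_keep)
      ll_rec <- numeric(n_keep)
      for (it in seq_len(chain_length)) {
        if (combine == "mix" && n_tree > 1L) {
          prop_tree <- sample.int(n_tree, 1L)
          ll_prop <- grouped_loglik(ne, Emat[prop_tree, ], Smat[prop_tree, ])
          if (log(runif(1L)) < ll_prop - ll) {
            cur_tree <- prop_tree
            e <- Emat[cur_tree, ]
            S <- Smat[cur_tree, ]
            ll <- ll_prop
          }
        }
        fac <- exp(proposal_scale * (runif(m) - 0.5))
        u <- log(runif(m))
        for (g in seq_len(m)) {
          ne_new <- ne[g] * fac[g]
          if (ne_new < lo || ne_new > hi) next
          dll <- -e[g] * (log(ne_new) - log(ne[g])) -
            S[g] * (1 / ne_new - 1 / ne[g])
          if (u[g] < dll) {
            ne[g] <- ne_new
            ll <- ll + dll
          }
        }
        if (it %% thin == 0L) {
          rec <- it %/% thin
          draws[rec, ] <- ne
          tree_rec[rec] <- cur_tree
          ll_rec[rec] <- ll
        }
      }
      keep <- first_keep:n_keep
      draws_all[[chain]] <- draws[keep, , drop = FALSE]
      tree_idx_all <- c(tree_idx_all, tree_rec[keep])
      ll_all <- c(ll_all, ll_rec[keep])
    }
    draws <- do.call(rbind, draws_all)
    colnames(draws) <- sprintf("group%02d", seq_len(m))
    ess <- apply(draws, 2, ess_autocorr)
    structure(list(draws = draws, tree_index = tree_idx_all,
                   loglik = ll_all, ess = ess,
                   low_ess = any(ess < ess_floor),
                   stats = stats, trees = trees,
                   most_recent_date = trees[[1L]]$most_recent_date,
                   config = list(n_groups = m, chain_length = chain_length,
                                 thin = thin, burn_in = burn_in,
                                 proposal_scale = proposal_scale,
                                 n_chains = n_chains, combine = combine,
                                 prior = c(lo, hi), seed = seed)),
              class = "skyline_fit")
  })
}

# Initial-monotone-sequence flavoured ESS: n / (1 + 2 sum rho_k) with the
# autocorrelation sum truncated at the first non-positive lag.
ess_autocorr <- function(x) {
  n <- length(x)
  if (n < 10L || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  neg <- which(rho <= 0)
  if (length(neg)) rho <- rho[seq_len(neg[1L] - 1L)]
  max(1, n / (1 + 2 * sum(rho)))
}

#' @export
print.skyline_fit <- function(x, ...) {
  cat("Grouped Bayesian skyline fit\n")
  cat("  trees:", length(x$trees), " groups:", x$config$n_groups,
      " chains:", x$config$n_chains, "x", x$config$chain_length,
      "(burn-in ", x$config$burn_in, ")\n")
  cat("  posterior draws:", nrow(x$draws),
      " min ESS:", round(min(x$ess)), "\n")
  if (x$low_ess) cat("  warning: ESS below floor for some groups\n")
  invisible(x)
}

#' @export
summary.skyline_fit <- function(object, ...) {
  med <- apply(object$draws, 2, median)
  hpd <- apply(object$draws, 2, hpd_interval)
  out <- data.frame(group = seq_along(med), ne_median = med,
                    hpd_lo = hpd[1, ], hpd_hi = hpd[2, ],
                    ess = object$ess)
  rownames(out) <- NULL
  out
}

#' @export
coef.skyline_fit <- function(object, ...) {
  apply(object$draws, 2, median)
}

#' @export
plot.skyline_fit <- function(x, grid = NULL, ...) {
  if (is.null(grid)) {
    lo <- x$most_recent_date - min(vapply(x$stats, function(s)
      max(s$coal_heights), numeric(1)))
    grid <- seq(lo, x$most_recent_date, length.out = 100)
  }
  tr <- summarize_trajectory(x, grid)
  plot(tr$date_CE, tr$ne_median, type = "s", log = "y",
       xlab = "date (CE)", ylab = "Ne", ...)
  lines(tr$date_CE, tr$hpd_lo, type = "s", lty = 2)
  lines(tr$date_CE, tr$hpd_hi, type = "s", lty = 2)
  invisible(tr)
}

# Shortest-interval HPD on sorted draws.
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1L], x[n]))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- starts[which.min(widths)]
  c(x[i], x[i + m])
}

#' Posterior Ne trajectory on a calendar grid
#'
#' Converts a [skyline_fit()] posterior into median and 95% HPD Ne values
#' at calendar dates, using `date_CE = most_recent_date - height`. For each
#' posterior draw the group whose most recent coalescent event is at or
#' beyond the grid height supplies the Ne value (the oldest group extends
#' to the root).
#'
#' @param fit a `skyline_fit`.
#' @param calendar_grid numeric vector of dates CE, inside
#'   `[root date, most recent tip date]` for every tree in the fit.
#' @return data frame `date_CE`, `ne_median`, `hpd_lo`, `hpd_hi`.
#' @export
summarize_trajectory <- function(fit, calendar_grid) {
  stopifnot(inherits(fit, "skyline_fit"))
  mrd <- fit$most_recent_date
  root_min <- min(vapply(fit$stats, function(s) max(s$coal_heights),
                         numeric(1)))
  lo_date <- mrd - root_min
  if (any(calendar_grid < lo_date - 1e-9) || any(calendar_grid > mrd + 1e-9)) {
    stop(sprintf("grid outside tree span; valid range is [%.1f, %.1f] CE",
                 lo_date, mrd))
  }
  h <- mrd - calendar_grid
  m <- fit$config$n_groups
  n_draw <- nrow(fit$draws)
  # per tree: map height -> group via coalescent-event heights
  group_of_h <- lapply(fit$stats, function(s) {
    g_of_event <- rep(seq_len(m), times = s$group_sizes)
    function(hh) {
      idx <- findInterval(hh, s$coal_heights,
                          left.open = TRUE) + 1L
      g_of_event[pmin(idx, length(g_of_event))]
    }
  })
  out <- matrix(NA_real_, n_draw, length(h))
  for (ti in unique(fit$tree_index)) {
    rows <- which(fit$tree_index == ti)
    gidx <- group_of_h[[ti]](h)
    out[rows, ] <- fit$draws[rows, gidx, drop = FALSE]
  }
  med <- apply(out, 2, median)
  hpd <- apply(out, 2, hpd_interval)
  data.frame(date_CE = calendar_grid, ne_median = med,
             hpd_lo = hpd[1, ], hpd_hi = hpd[2, ])
}
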