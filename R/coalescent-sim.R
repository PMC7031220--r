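#' Serial sampling design for one sediment core
#'
#' Describes how many genealogy tips are sampled from each dated horizon of
#' a core. Horizons are given youngest first; heights (years before the most
#' recent sample) are derived as `most_recent_date - date_CE`.
#'
#' @param site_id site label.
#' @param horizons data frame with columns `date_CE` (deposition date,
#'   strictly decreasing with depth) and `n_tips` (>= 1 per horizon).
#' @param most_recent_date reference date for height zero; defaults to the
#'   youngest horizon.
#' @return object of class `sampling_design`.
#' @export
sampling_design <- function(site_id, horizons,
                            most_recent_date = max(horizons$date_CE)) {
  stopifnot(is.data.frame(horizons),
            all(c("date_CE", "n_tips") %in% names(horizons)))
  if (is.unsorted(rev(horizons$date_CE), strictly = TRUE) &&
      is.unsorted(horizons$date_CE, strictly = TRUE)) {
    stop("horizon dates must be strictly ordered")
  }
  horizons <- horizons[order(horizons$date_CE, decreasing = TRUE), ,
                       drop = FALSE]
  if (any(horizons$n_tips < 1)) stop("tip counts must be >= 1")
  if (anyDuplicated(horizons$date_CE)) {
    stop("horizon dates must be distinct")
  }
  structure(list(site_id = as.character(site_id), horizons = horizons,
                 most_recent_date = most_recent_date),
            class = "sampling_design")
}

# Piecewise-constant approximation of the coalescent intensity integrand
# 1/Ne on a height grid (height = years before `most_recent_date`).
# Beyond `h_max` the deep-past value is held constant, which is exact for
# every trajectory kind except the exponential (whose grid is simply built
# long enough to contain the root with overwhelming probability and
# extended on demand).
intensity_grid <- function(traj, most_recent_date, h_max, step = 0.1) {
  h_max <- max(h_max, step)
  n <- ceiling(h_max / step)
  breaks <- seq(0, by = step, length.out = n + 1L)
  mids <- breaks[-1L] - step / 2
  inv <- 1 / ne_at(traj, most_recent_date - mids)
  list(breaks = breaks, inv = inv,
       cum = c(0, cumsum(inv * step)),
       tail_inv = 1 / ne_at(traj, most_recent_date - h_max),
       step = step, most_recent_date = most_recent_date)
}

# Height beyond which the trajectory is (numerically) constant going into
# the past, measured from `most_recent_date`.
trajectory_constant_depth <- function(traj, most_recent_date) {
  switch(traj$kind,
    constant = 0,
    sigmoidal_breakpoint = {
      if (traj$steepness == 0 || traj$fold_change == 1) 0
      else max(0, most_recent_date - (traj$breakpoint_date - 16 / traj$steepness))
    },
    piecewise_constant = max(0, most_recent_date - min(traj$grid$date_CE)),
    exponential = Inf)
}

# C(h): cumulative integral of 1/Ne from height 0 to h.
cum_intensity <- function(g, h) {
  n <- length(g$breaks)
  if (h >= g$breaks[n]) {
    g$cum[n] + (h - g$breaks[n]) * g$tail_inv
  } else {
    i <- findInterval(h, g$breaks)
    g$cum[i] + (h - g$breaks[i]) * g$inv[i]
  }
}

# Solve C(h*) - C(h0) = a for h*; returns Inf only if the tail rate is zero
# (cannot happen: Ne is finite and positive).
invert_intensity <- function(g, h0, a) {
  target <- cum_intensity(g, h0) + a
  n <- length(g$breaks)
  if (target > g$cum[n]) {
    g$breaks[n] + (target - g$cum[n]) / g$tail_inv
  } else {
    j <- findInterval(target, g$cum, rightmost.closed = TRUE)
    j <- min(max(j, 1L), n - 1L)
    g$breaks[j] + (target - g$cum[j]) / g$inv[j]
  }
}

#' Simulate a heterochronous coalescent genealogy
#'
#' Simulates a binary genealogy for serially sampled tips under a
#' deterministic Ne trajectory. Going backwards in time, `k` active lineages
#' coalesce with instantaneous rate `k(k-1) / (2 Ne(t))`; waiting times are
#' drawn by exact inversion of the cumulative intensity computed on a
#' piecewise-constant approximation of `Ne(t)` (default 0.1-year steps, so
#' the constant and piecewise-constant kinds are handled exactly).
#'
#' @param design a [sampling_design()].
#' @param traj an [ne_trajectory()]; must be positive over the whole range
#'   the simulation visits.
#' @param seed integer seed; the caller's RNG state is restored on exit.
#' @param grid_step height discretisation of the intensity integrand, years.
#' @return object of class `timed_tree`: a list with `tree` (an
#'   [ape::read.tree()] phylogeny with branch lengths in years), `tip_dates`
#'   (data frame `tip`, `date_CE`), and `most_recent_date`.
#' @examples
#' d <- sampling_design("A", data.frame(date_CE = c(2000, 1950),
#'                                      n_tips = c(3, 3)))
#' tt <- simulate_genealogy(d, ne_trajectory("constant", base_ne = 200),
#'                          seed = 1)
#' ape::Ntip(tt$tree)
#' @export
simulate_genealogy <- function(design, traj, seed = NULL, grid_step = 0.1) {
  stopifnot(inherits(design, "sampling_design"),
            inherits(traj, "ne_trajectory"))
  n_total <- sum(design$horizons$n_tips)
  if (n_total < 2L) stop("need at least 2 tips overall")
  with_seed(seed, {
    mrd <- design$most_recent_date
    heights <- mrd - design$horizons$date_CE
    # grid long enough for the constant-tail analytic extension to be exact
    depth <- trajectory_constant_depth(traj, mrd)
    if (!is.finite(depth)) {
      # exponential: take a generous envelope, the tail extends analytically
      depth <- max(heights) + 100 / traj$steepness
    }
    g <- intensity_grid(traj, mrd, max(max(heights), depth) + grid_step,
                        step = grid_step)

    ord <- order(heights)
    samp_h <- heights[ord]
    samp_n <- design$horizons$n_tips[ord]
    samp_idx <- ord  # horizon index (1 = youngest) per sampling event

    frag <- character(0)     # newick fragment per active lineage
    top_h <- numeric(0)      # height of each active lineage's top node
    tip_names <- character(0)
    tip_dates <- numeric(0)

    add_tips <- function(ev) {
      hz <- samp_idx[ev]
      labs <- sprintf("%s_h%02d_t%02d", design$site_id, hz,
                      seq_len(samp_n[ev]))
      frag <<- c(frag, labs)
      top_h <<- c(top_h, rep(samp_h[ev], samp_n[ev]))
      tip_names <<- c(tip_names, labs)
      tip_dates <<- c(tip_dates, rep(mrd - samp_h[ev], samp_n[ev]))
    }

    t_cur <- samp_h[1L]
    add_tips(1L)
    next_ev <- 2L
    repeat {
      k <- length(frag)
      if (k < 2L && next_ev > length(samp_h)) break
      h_samp <- if (next_ev <= length(samp_h)) samp_h[next_ev] else Inf
      h_coal <- if (k >= 2L) {
        invert_intensity(g, t_cur, 2 * rexp(1L) / (k * (k - 1)))
      } else Inf
      if (h_coal < h_samp) {
        pair <- sample.int(k, 2L)
        merged <- sprintf("(%s:%.15g,%s:%.15g)",
                          frag[pair[1L]], h_coal - top_h[pair[1L]],
                          frag[pair[2L]], h_coal - top_h[pair[2L]])
        frag <- c(frag[-pair], merged)
        top_h <- c(top_h[-pair], h_coal)
        t_cur <- h_coal
      } else {
        t_cur <- h_samp
        add_tips(next_ev)
        next_ev <- next_ev + 1L
      }
    }
    tree <- ape::read.tree(text = paste0(frag, ";"))
    structure(list(tree = tree,
                   tip_dates = data.frame(tip = tip_names,
                                          date_CE = tip_dates,
                                          stringsAsFactors = FALSE),
                   most_recent_date = mrd),
              class = "timed_tree")
  })
}

#' @export
print.timed_tree <- function(x, ...) {
  cat("Timed genealogy:", ape::Ntip(x$tree), "tips,",
      length(unique(x$tip_dates$date_CE)), "sampling dates,",
      "most recent", x$most_recent_date, "CE\n")
  invisible(x)
}

# Node heights (years before most_recent_date) for tips and internal nodes,
# anchored on the sidecar tip dates.
node_heights <- function(tt) {
  tree <- tt$tree
  depths <- ape::node.depth.edgelength(tree)
  tip_h <- tt$most_recent_date -
    tt$tip_dates$date_CE[match(tree$tip.label, tt$tip_dates$tip)]
  root_h <- depths[1L] + tip_h[1L]  # depth(tip) + height(tip) is constant
  h <- root_h - depths
  # guard against drift between branch lengths and sidecar dates
  if (max(abs(h[seq_len(ape::Ntip(tree))] - tip_h)) > 1e-6) {
    stop("tip heights inconsistent with sidecar dates")
  }
  h[seq_len(ape::Ntip(tree))] <- tip_h
  h
}

#' Time to the most recent common ancestor
#'
#' @param tt a `timed_tree`.
#' @return root height in years before the most recent sampling date.
#' @export
tmrca <- function(tt) {
  stopifnot(inherits(tt, "timed_tree"))
  max(node_heights(tt))
}
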