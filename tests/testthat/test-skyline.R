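hand_tree <- function() {
  # 2 tips at 2010 (heights 0), 1 tip at 2005 (height 5);
  # coalescences at heights 3 and 8
  make_timed_tree("((a:3,b:3):5,c:3);", c(a = 2010, b = 2010, c = 2005))
}

test_that("interval decomposition matches hand-traced event lists", {
  two <- two_tip_tree(10)
  iv <- coalescent_intervals(two)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$w, 10)
  expect_equal(iv$k, 2L)
  expect_equal(iv$event, "coalescence")

  iv3 <- coalescent_intervals(hand_tree())
  expect_equal(iv3$w, c(3, 2, 3))
  expect_equal(iv3$k, c(2L, 1L, 2L))
  expect_equal(iv3$event, c("coalescence", "sampling", "coalescence"))
  expect_equal(attr(iv3, "root_height"), 8)
})

test_that("interval lengths sum to the root height on simulated trees", {
  set.seed(21)
  for (i in 1:5) {
    tt <- simulate_genealogy(serial_design(c(2000, 1970, 1940), c(4, 4, 4)),
                             ne_trajectory("constant", base_ne = 200),
                             seed = i)
    iv <- coalescent_intervals(tt)
    expect_equal(sum(iv$w), attr(iv, "root_height"), tolerance = 1e-9)
  }
})

test_that("classic skyline equals k(k-1)w/2 exactly", {
  iv <- data.frame(w = c(10, 1, 0), k = c(2, 5, 4),
                   event = "coalescence", end_height = c(10, 11, 11))
  expect_equal(classic_skyline(iv)$ne_hat, c(10, 10, 0))
})

test_that("coalescent log-likelihood matches closed forms", {
  iv <- coalescent_intervals(two_tip_tree(10))
  # density (1/Ne) exp(-tau/Ne): logL = -ln 10 - 1
  expect_equal(coalescent_loglik(iv, 10), -log(10) - 1, tolerance = 1e-12)
  # doubling Ne as tau -> 0 changes logL by -ln 2
  iv0 <- coalescent_intervals(two_tip_tree(1e-9))
  expect_equal(coalescent_loglik(iv0, 20) - coalescent_loglik(iv0, 10),
               -log(2), tolerance = 1e-6)
  expect_error(coalescent_loglik(iv, -1), "positive")
})

test_that("constant-Ne MLE equals the classic skyline on one interval", {
  iv <- coalescent_intervals(two_tip_tree(10))
  opt <- optimize(function(n) coalescent_loglik(iv, n), c(0.1, 500),
                  maximum = TRUE)
  expect_equal(opt$maximum, classic_skyline(iv)$ne_hat, tolerance = 1e-4)
})

test_that("piecewise log-likelihood agrees with a quadrature oracle", {
  set.seed(31)
  for (rep in 1:5) {
    tt <- simulate_genealogy(serial_design(c(2000, 1950), c(5, 5)),
                             ne_trajectory("constant", base_ne = 300),
                             seed = rep)
    iv <- coalescent_intervals(tt)
    bks <- sort(runif(4, 0, attr(iv, "root_height")))
    ne <- data.frame(height = c(0, bks), ne = exp(runif(5, 3, 7)))
    # oracle: integrate 1/Ne over each interval, splitting at the step
    # breakpoints so the quadrature sees smooth pieces
    ne_fun <- function(h) ne$ne[pmax(findInterval(h, ne$height), 1)]
    ll_oracle <- 0
    start <- iv$end_height - iv$w
    for (i in seq_len(nrow(iv))) {
      cuts <- sort(unique(c(start[i], ne$height[ne$height > start[i] &
                                                  ne$height < iv$end_height[i]],
                            iv$end_height[i])))
      intg <- sum(vapply(seq_len(length(cuts) - 1L), function(j) {
        integrate(function(h) 1 / ne_fun(h), cuts[j], cuts[j + 1L],
                  rel.tol = 1e-12)$value
      }, numeric(1)))
      ll_oracle <- ll_oracle - iv$k[i] * (iv$k[i] - 1) / 2 * intg
      if (iv$event[i] == "coalescence") {
        ll_oracle <- ll_oracle - log(ne_fun(iv$end_height[i]))
      }
    }
    expect_equal(coalescent_loglik(iv, ne), ll_oracle, tolerance = 1e-8)
  }
})

test_that("skyline MCMC is deterministic given a seed", {
  tt <- simulate_genealogy(flat_design(20),
                           ne_trajectory("constant", base_ne = 300),
                           seed = 4)
  a <- skyline_fit(tt, n_groups = 4, chain_length = 2000, seed = 5)
  b <- skyline_fit(tt, n_groups = 4, chain_length = 2000, seed = 5)
  expect_identical(a$draws, b$draws)
})

test_that("group medians track classic-skyline estimates when m = events", {
  tt <- simulate_genealogy(flat_design(30),
                           ne_trajectory("constant", base_ne = 500),
                           seed = 6)
  iv <- coalescent_intervals(tt)
  m <- sum(iv$event == "coalescence")
  fit <- skyline_fit(tt, n_groups = m, chain_length = 30000, thin = 10,
                     seed = 7)
  med <- coef(fit)
  cs <- classic_skyline(iv)$ne_hat
  expect_gte(cor(med, cs, method = "spearman"), 0.8)
})

test_that("constant-Ne truth is recovered with calibrated HPD coverage", {
  truth <- 400
  tr <- ne_trajectory("constant", base_ne = truth)
  covered <- matrix(NA, 20, 5)
  within2x <- logical(20)
  for (r in 1:20) {
    tt <- simulate_genealogy(flat_design(50), tr, seed = 700 + r,
                             grid_step = 1)
    fit <- skyline_fit(tt, n_groups = 5, chain_length = 6000, seed = r)
    s <- summary(fit)
    covered[r, ] <- s$hpd_lo <= truth & truth <= s$hpd_hi
    within2x[r] <- all(s$ne_median > truth / 2 & s$ne_median < truth * 2)
  }
  # per-group 95% HPD coverage calibrated: each group covers the truth in
  # at least 17 of 20 replicates
  expect_true(all(colSums(covered) >= 17))
  expect_gte(mean(within2x), 0.8)
})

test_that("MCMC posterior matches dense grid integration on a 2-group toy", {
  tt <- hand_tree()
  fit <- skyline_fit(tt, n_groups = 2, chain_length = 50000, thin = 5,
                     proposal_scale = 1.5, seed = 8)
  stats <- paleoNe:::skyline_stats(tt, 2)
  lo <- fit$config$prior[1]; hi <- fit$config$prior[2]
  lg <- seq(log(lo), log(hi), length.out = 2000)
  # independent posterior per group under the factorised likelihood and
  # flat-in-log prior
  for (g in 1:2) {
    dens <- exp(-stats$e[g] * lg - stats$S[g] / exp(lg))
    dens <- dens / sum(dens)
    cdf_grid <- cumsum(dens)
    draws <- sort(log(fit$draws[, g]))
    qs <- seq(0.05, 0.95, by = 0.05)
    q_mcmc <- quantile(draws, qs)
    q_grid <- lg[vapply(qs, function(p) which(cdf_grid >= p)[1], 1L)]
    # total-variation style check via quantile agreement in log space
    expect_lt(max(abs(q_mcmc - q_grid)), 0.12)
    # and binned TV distance below 0.05
    bins <- seq(min(draws) - 0.2, max(draws) + 0.2, length.out = 25)
    p_mcmc <- hist(draws, breaks = bins, plot = FALSE)$counts
    p_mcmc <- p_mcmc / sum(p_mcmc)
    p_grid <- diff(c(0, approx(lg, cdf_grid, xout = bins[-1],
                               yleft = 0, yright = 1)$y))
    p_grid[p_grid < 0] <- 0
    expect_lt(sum(abs(p_mcmc - p_grid)) / 2, 0.05)
  }
})

test_that("more pooled trees shrink the HPD monotonically in expectation", {
  tr <- ne_trajectory("constant", base_ne = 300)
  width <- function(n_trees, seed) {
    trees <- lapply(seq_len(n_trees), function(i) {
      simulate_genealogy(flat_design(15), tr, seed = seed * 100 + i,
                         grid_step = 1)
    })
    fit <- skyline_fit(trees, n_groups = 3, chain_length = 4000,
                       combine = "pool", seed = seed)
    s <- summary(fit)
    mean(log(s$hpd_hi) - log(s$hpd_lo))
  }
  w_small <- mean(vapply(1:3, function(s) width(3, s), numeric(1)))
  w_large <- mean(vapply(1:3, function(s) width(12, s), numeric(1)))
  expect_lt(w_large, w_small)
})

test_that("sigmoidal Ne increase puts the steepest estimated slope near the truth", {
  # a sharp (steepness 0.2/yr) ten-fold increase, reconstructed from three
  # pooled 90-tip genealogies, puts the steepest summarised slope at the
  # logistic midpoint within the skyline's temporal resolution
  tr <- ne_trajectory("sigmoidal_breakpoint", base_ne = 100,
                      fold_change = 10, breakpoint_date = 1884,
                      steepness = 0.2)
  d <- serial_design(seq(2010, 1760, by = -50), rep(15, 6))
  hits <- vapply(1:20, function(r) {
    trees <- lapply(1:3, function(j) {
      simulate_genealogy(d, tr, seed = 40 + r * 10 + j, grid_step = 0.5)
    })
    fit <- skyline_fit(trees, n_groups = 8, chain_length = 5000,
                       combine = "pool", seed = r)
    grid <- seq(1800, 1970, by = 10)
    s <- summarize_trajectory(fit, grid)
    slope <- diff(log(s$ne_median)) / diff(grid)
    at <- grid[which.max(slope)] + 5
    abs(at - 1884) <= 20
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("trajectory summaries respect the tree span and step structure", {
  tt <- simulate_genealogy(flat_design(20),
                           ne_trajectory("constant", base_ne = 300),
                           seed = 9)
  fit <- skyline_fit(tt, n_groups = 4, chain_length = 2000, seed = 10)
  expect_error(summarize_trajectory(fit, c(2300)), "valid range")
  one <- summarize_trajectory(fit, 1995)
  expect_equal(nrow(one), 1L)
  expect_true(one$hpd_lo <= one$ne_median & one$ne_median <= one$hpd_hi)
  # a grid inside one group is flat
  grid <- seq(1999, 2000, by = 0.5)
  tr <- summarize_trajectory(fit, grid)
  expect_true(length(unique(tr$ne_median)) <= fit$config$n_groups)
})

test_that("invalid sampler settings are rejected", {
  tt <- two_tip_tree(10)
  expect_error(skyline_fit(tt, n_groups = 2), "exceeds coalescent events")
  expect_error(skyline_fit(tt, n_groups = 1, chain_length = 0), "positive")
  expect_error(skyline_fit(tt, n_groups = 1, burn_in = 0.9), "burn_in")
})
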