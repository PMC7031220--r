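#' Molecular clock model
#'
#' A strict or uncorrelated-lognormal relaxed clock. The lognormal is
#' parameterised so that the *arithmetic* mean of the branch-rate
#' distribution equals `mean_rate` (the convention of the common Bayesian
#' phylogenetic samplers), i.e. `meanlog = log(mean_rate) - lognormal_sdev^2/2`.
#'
#' @param mean_rate expected substitution rate, substitutions/site/year.
#' @param lognormal_sdev log-space standard deviation (dimensionless).
#' @param mode `"strict"` (all branches share `mean_rate`) or
#'   `"uncorrelated_lognormal"` (i.i.d. branch rates).
#' @return object of class `clock_model`.
#' @export
clock_model <- function(mean_rate = 0.001, lognormal_sdev = 1.0,
                        mode = c("uncorrelated_lognormal", "strict")) {
  mode <- match.arg(mode)
  stopifnot(mean_rate > 0, lognormal_sdev >= 0)
  structure(list(mean_rate = mean_rate, lognormal_sdev = lognormal_sdev,
                 mode = mode),
            class = "clock_model")
}

#' General time-reversible substitution model with Gamma rate variation
#'
#' @param exchangeabilities six non-negative relative rates in the order
#'   AC, AG, AT, CG, CT, GT.
#' @param base_frequencies four equilibrium frequencies (A, C, G, T)
#'   summing to one.
#' @param gamma_shape shape of the Gamma distribution of site rates.
#' @param n_categories number of discrete Gamma categories (1 disables
#'   among-site rate variation).
#' @return object of class `substitution_model` carrying the rate matrix
#'   scaled to one expected substitution per unit branch length and its
#'   eigendecomposition.
#' @export
substitution_model <- function(exchangeabilities = rep(1, 6),
                               base_frequencies = rep(0.25, 4),
                               gamma_shape = 1, n_categories = 4L) {
  stopifnot(length(exchangeabilities) == 6L, all(exchangeabilities >= 0),
            length(base_frequencies) == 4L, gamma_shape > 0,
            n_categories >= 1L)
  if (any(base_frequencies <= 0) ||
      abs(sum(base_frequencies) - 1) > 1e-12) {
    stop("base_frequencies must be positive and sum to 1 (within 1e-12)")
  }
  pi <- base_frequencies
  # symmetric relative-rate matrix, order AC, AG, AT, CG, CT, GT
  R <- matrix(0, 4, 4)
  R[1, 2] <- R[2, 1] <- exchangeabilities[1]
  R[1, 3] <- R[3, 1] <- exchangeabilities[2]
  R[1, 4] <- R[4, 1] <- exchangeabilities[3]
  R[2, 3] <- R[3, 2] <- exchangeabilities[4]
  R[2, 4] <- R[4, 2] <- exchangeabilities[5]
  R[3, 4] <- R[4, 3] <- exchangeabilities[6]
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix: all exchangeabilities zero?")
  Q <- Q / mu
  # reversible Q: symmetrise with sqrt(pi) similarity for a stable eigensystem
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(exchangeabilities = exchangeabilities,
                 base_frequencies = pi, gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories), Q = Q,
                 eigval = eig$values,
                 left = diag(1 / sp) %*% eig$vectors,
                 right = t(eig$vectors) %*% diag(sp)),
            class = "substitution_model")
}

# Transition probability matrix P(d) for expected distance d (subs/site).
transition_matrix <- function(model, d) {
  P <- model$left %*% (exp(model$eigval * d) * model$right)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Quantile-based discrete Gamma categories, normalised to mean one.
gamma_category_rates <- function(shape, k) {
  if (k == 1L) return(1)
  r <- qgamma((seq_len(k) - 0.5) / k, shape = shape, rate = shape)
  r / mean(r)
}

#' Simulate per-branch substitution rates
#'
#' Draws one rate per edge of a timed genealogy under a [clock_model()].
#' Rates are i.i.d. lognormal with arithmetic mean `mean_rate` in relaxed
#' mode, and constant in strict mode (or when `lognormal_sdev = 0`).
#'
#' @param tt a `timed_tree` from [simulate_genealogy()].
#' @param clock a [clock_model()].
#' @param seed integer seed.
#' @return numeric vector of rates aligned with `tt$tree$edge` rows.
#' @export
simulate_branch_rates <- function(tt, clock, seed = NULL) {
  stopifnot(inherits(tt, "timed_tree"), inherits(clock, "clock_model"))
  if (any(tt$tree$edge.length < 0)) stop("tree has negative branch lengths")
  n_edge <- nrow(tt$tree$edge)
  if (clock$mode == "strict" || clock$lognormal_sdev == 0) {
    return(rep(clock$mean_rate, n_edge))
  }
  with_seed(seed, {
    s <- clock$lognormal_sdev
    rlnorm(n_edge, meanlog = log(clock$mean_rate) - s^2 / 2, sdlog = s)
  })
}

#' Simulate sequences along a timed genealogy
#'
#' Evolves nucleotide sequences from a stationary root down the tree under
#' a GTR model with discrete-Gamma site-rate categories and the supplied
#' per-branch rates. Each site keeps its category along the whole tree;
#' sites are independent given the category.
#'
#' @param tt a `timed_tree`.
#' @param rates per-edge substitution rates (substitutions/site/year),
#'   aligned with `tt$tree$edge`; see [simulate_branch_rates()].
#' @param model a [substitution_model()].
#' @param length number of sites (>= 1).
#' @param seed integer seed.
#' @return character matrix (tips x sites) over A, C, G, T with tip labels
#'   as row names.
#' @export
simulate_sequences <- function(tt, rates, model, length, seed = NULL) {
  stopifnot(inherits(tt, "timed_tree"),
            inherits(model, "substitution_model"), length >= 1)
  tree <- ape::reorder.phylo(tt$tree, "cladewise")
  if (length(rates) != nrow(tree$edge)) {
    stop("need one rate per edge (", nrow(tree$edge), ")")
  }
  with_seed(seed, {
    L <- as.integer(length)
    k <- model$n_categories
    cat_rate <- gamma_category_rates(model$gamma_shape, k)
    site_cat <- if (k == 1L) rep(1L, L) else sample.int(k, L, replace = TRUE)
    n_tip <- ape::Ntip(tree)
    n_node <- n_tip + tree$Nnode
    states <- matrix(0L, n_node, L)
    root <- n_tip + 1L
    states[root, ] <- sample.int(4L, L, replace = TRUE,
                                 prob = model$base_frequencies)
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1L]
      ch <- tree$edge[e, 2L]
      d <- tree$edge.length[e] * rates[e]
      child <- states[p, ]
      for (cc in seq_len(k)) {
        P <- transition_matrix(model, d * cat_rate[cc])
        for (b in 1:4) {
          idx <- which(states[p, ] == b & site_cat == cc)
          if (length(idx)) {
            child[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                     prob = P[b, ])
          }
        }
      }
      states[ch, ] <- child
    }
    out <- matrix(c("A", "C", "G", "T")[states[seq_len(n_tip), , drop = FALSE]],
                  n_tip, L)
    rownames(out) <- tree$tip.label
    out
  })
}
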