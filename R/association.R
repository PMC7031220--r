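#' Association Index of a trait on a rooted tree
#'
#' Computes the Association Index
#' `AI = sum_i (1 - f_i) / 2^(n_i - 1)` over the internal nodes `i` of a
#' rooted binary tree, where `n_i` is the number of tips descending from
#' node `i` and `f_i` the frequency of the most common trait value among
#' them. Lower values indicate stronger clustering of the trait (here, the
#' deposition horizon) on the phylogeny.
#'
#' @param tree a rooted binary `phylo` or `timed_tree`.
#' @param traits named character/factor vector mapping every tip label to
#'   its categorical horizon label.
#' @return the AI value (non-negative scalar).
#' @examples
#' tr <- ape::read.tree(text = "((A1,A2),(B1,B2));")
#' association_index(tr, c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
#' @export
association_index <- function(tree, traits) {
  if (inherits(tree, "timed_tree")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  if (!all(tree$tip.label %in% names(traits))) {
    stop("unlabeled tips: ",
         paste(setdiff(tree$tip.label, names(traits)), collapse = ", "))
  }
  clades <- clade_membership(tree)
  lab <- as.character(traits[tree$tip.label])
  ai_from_clades(clades, lab)
}

# tip-index sets of every internal node (including the root)
clade_membership <- function(tree) {
  pp <- ape::prop.part(tree)
  lapply(seq_along(pp), function(i) pp[[i]])
}

ai_from_clades <- function(clades, lab) {
  sum(vapply(clades, function(idx) {
    n <- length(idx)
    f <- max(tabulate(factor(lab[idx]))) / n
    (1 - f) / 2^(n - 1)
  }, numeric(1)))
}

#' Permutation test of phylogeny-deposition-date association
#'
#' For each of `n_trees` genealogies subsampled from a posterior tree
#' sample, computes the observed Association Index and `n_perm` null
#' values under uniform permutation of the tip labels' traits. Following
#' the BaTS convention, association means the observed AI falls *below*
#' the null, and the one-sided, add-one-corrected P value is
#' `(1 + #(null <= observed of its tree)) / (1 + n_trees * n_perm)`,
#' pairing each null draw with the observed AI of its own tree. A pooled
#' comparison against the merged null distribution is available with
#' `pairing = "pooled"`.
#'
#' @param trees a `timed_tree`, `phylo`, `multiPhylo`, or list of these.
#' @param traits named vector mapping tip labels to horizon labels; at
#'   least two distinct values are required.
#' @param n_trees number of trees to subsample (without replacement if
#'   possible).
#' @param n_perm permutations per tree.
#' @param pairing `"per_tree"` (default) or `"pooled"`.
#' @param seed integer seed.
#' @return object of class `ai_test` with the observed AIs, null draws
#'   and P value.
#' @export
ai_permutation_test <- function(trees, traits, n_trees = 100, n_perm = 100,
                                pairing = c("per_tree", "pooled"),
                                seed = 1) {
  pairing <- match.arg(pairing)
  trees <- as_tree_list(trees)
  if (length(unique(as.character(traits))) < 2L) {
    stop("need at least two distinct trait labels for a permutation test")
  }
  if (n_trees > length(trees)) {
    stop("n_trees (", n_trees, ") exceeds available trees (",
         length(trees), ")")
  }
  if (n_perm < 1) stop("n_perm must be >= 1")
  with_seed(seed, {
    pick <- if (n_trees == length(trees)) seq_len(n_trees) else
      sample.int(length(trees), n_trees)
    obs <- numeric(n_trees)
    null_le <- 0L
    null_draws <- matrix(NA_real_, n_trees, n_perm)
    for (i in seq_len(n_trees)) {
      tree <- trees[[pick[i]]]
      clades <- clade_membership(tree)
      lab <- as.character(traits[tree$tip.label])
      if (anyNA(lab)) stop("unlabeled tip in tree ", pick[i])
      obs[i] <- ai_from_clades(clades, lab)
      for (p in seq_len(n_perm)) {
        null_draws[i, p] <- ai_from_clades(clades, sample(lab))
      }
      null_le <- null_le + sum(null_draws[i, ] <= obs[i])
    }
    p_value <- if (pairing == "per_tree") {
      (1 + null_le) / (1 + n_trees * n_perm)
    } else {
      (1 + sum(null_draws <= median(obs))) / (1 + length(null_draws))
    }
    structure(list(observed = obs, null = null_draws, p_value = p_value,
                   n_trees = n_trees, n_perm = n_perm, pairing = pairing),
              class = "ai_test")
  })
}

as_tree_list <- function(trees) {
  if (inherits(trees, "timed_tree")) return(list(trees$tree))
  if (inherits(trees, "phylo")) return(list(trees))
  if (inherits(trees, "multiPhylo")) return(unclass(trees))
  stopifnot(is.list(trees), length(trees) >= 1L)
  lapply(trees, function(t) if (inherits(t, "timed_tree")) t$tree else t)
}

#' @export
print.ai_test <- function(x, ...) {
  cat("Association Index permutation test (", x$pairing, ")\n", sep = "")
  cat(sprintf("  trees: %d  permutations/tree: %d\n", x$n_trees, x$n_perm))
  cat(sprintf("  median observed AI: %.4f  median null AI: %.4f\n",
              median(x$observed), median(x$null)))
  cat(sprintf("  P = %.4g (one-sided, AI below null = association)\n",
              x$p_value))
  invisible(x)
}
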