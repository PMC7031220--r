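#' Variant-by-sample abundance matrix
#'
#' Container for variant counts across the samples of a multi-site study:
#' an integer matrix (variants x samples) plus per-sample metadata and,
#' optionally, the variant sequences.
#'
#' @param counts non-negative integer matrix; rownames are variant IDs
#'   (unique), colnames are sample IDs.
#' @param samples data frame with columns `sample_id`, `site_id`,
#'   `date_CE`, `is_control`, one row per matrix column.
#' @param sequences optional named character vector of variant sequences.
#' @return object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(counts, samples, sequences = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) == 0L || !is.null(rownames(counts)),
            !is.null(colnames(counts)), is.data.frame(samples),
            all(c("sample_id", "site_id", "date_CE", "is_control") %in%
                  names(samples)))
  if (anyDuplicated(rownames(counts))) stop("duplicate variant IDs")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!identical(colnames(counts), as.character(samples$sample_id))) {
    stop("sample metadata must match matrix columns (same order)")
  }
  structure(list(counts = counts, samples = samples, sequences = sequences),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("Abundance matrix:", nrow(x$counts), "variants x",
      ncol(x$counts), "samples (",
      sum(x$samples$is_control), "control )\n")
  invisible(x)
}

#' Exact-match dereplication of per-sample sequence sets
#'
#' Collapses identical sequences into variants and tabulates their counts
#' per sample. Total reads are conserved per sample. Variant IDs are
#' assigned deterministically: decreasing total abundance, ties broken by
#' sequence order.
#'
#' @param sequences_per_sample named list; each element a character vector
#'   of (possibly repeated) sequences observed in that sample.
#' @param samples optional sample metadata as for [abundance_matrix()];
#'   defaults to bare records with unknown site and date.
#' @return an [abundance_matrix()] with variant sequences attached.
#' @export
dereplicate <- function(sequences_per_sample, samples = NULL) {
  stopifnot(is.list(sequences_per_sample),
            !is.null(names(sequences_per_sample)))
  ids <- names(sequences_per_sample)
  all_seq <- unlist(sequences_per_sample, use.names = FALSE)
  if (length(all_seq) == 0L) {
    counts <- matrix(integer(0), 0, length(ids),
                     dimnames = list(character(0), ids))
  } else {
    if (any(!nzchar(all_seq))) stop("sequences must be non-empty strings")
    tab <- table(all_seq)
    uniq <- names(tab)[order(-as.integer(tab), names(tab))]
    counts <- vapply(sequences_per_sample, function(s) {
      tabulate(match(s, uniq), nbins = length(uniq))
    }, integer(length(uniq)))
    counts <- matrix(counts, nrow = length(uniq),
                     dimnames = list(sprintf("v%04d", seq_along(uniq)), ids))
  }
  if (is.null(samples)) {
    samples <- data.frame(sample_id = ids, site_id = NA_character_,
                          date_CE = NA_real_, is_control = FALSE,
                          stringsAsFactors = FALSE)
  }
  seqs <- if (length(all_seq)) setNames(uniq, rownames(counts)) else NULL
  abundance_matrix(counts, samples, sequences = seqs)
}

#' Remove variants present in the negative control
#'
#' Drops, from all samples, every variant with a nonzero count in any
#' control sample (presence-based kit-contamination removal), and reports
#' the removed fraction to one decimal place.
#'
#' @param mat an [abundance_matrix()] with at least one control sample.
#' @return list with `matrix` (filtered) and `report` (`n_total`,
#'   `n_removed`, `pct`, and `pct_label` such as `"1.4%"`).
#' @export
remove_control_variants <- function(mat) {
  stopifnot(inherits(mat, "abundance_matrix"))
  ctrl <- which(mat$samples$is_control)
  if (length(ctrl) == 0L) {
    stop("no control sample present; control-based removal expects ",
         "at least one sample flagged is_control = TRUE")
  }
  n_total <- nrow(mat$counts)
  in_ctrl <- rowSums(mat$counts[, ctrl, drop = FALSE] > 0) > 0
  n_removed <- sum(in_ctrl)
  pct <- if (n_total > 0) 100 * n_removed / n_total else 0
  kept <- mat$counts[!in_ctrl, , drop = FALSE]
  out <- abundance_matrix(kept, mat$samples,
                          sequences = mat$sequences[rownames(kept)])
  list(matrix = out,
       report = list(n_total = n_total, n_removed = n_removed,
                     removed_ids = rownames(mat$counts)[in_ctrl],
                     pct = pct, pct_label = sprintf("%.1f%%", pct)))
}

#' Remove within-site cross-sample variants
#'
#' Within each target site, only variants with a nonzero count in exactly
#' one (non-control) sample of that site survive; variants occurring in
#' more than one sample of the site are zeroed there, guarding against
#' cross-sample contamination. The rule is strictly per site: a variant
#' shared across two *different* sites is kept in both.
#'
#' @param mat an [abundance_matrix()].
#' @param site site ID to filter, or `NULL` for every site.
#' @return filtered [abundance_matrix()]; variants left with no counts
#'   anywhere are dropped.
#' @export
remove_cross_sample_variants <- function(mat, site = NULL) {
  stopifnot(inherits(mat, "abundance_matrix"))
  sites <- unique(mat$samples$site_id[!mat$samples$is_control])
  sites <- sites[!is.na(sites)]
  if (!is.null(site)) {
    if (!site %in% sites) stop("unknown site: ", site)
    sites <- site
  }
  counts <- mat$counts
  for (s in sites) {
    cols <- which(mat$samples$site_id %in% s & !mat$samples$is_control)
    if (length(cols) < 2L) next
    n_occ <- rowSums(counts[, cols, drop = FALSE] > 0)
    counts[n_occ > 1L, cols] <- 0L
  }
  keep <- rowSums(counts) > 0
  kept <- counts[keep, , drop = FALSE]
  abundance_matrix(kept, mat$samples, sequences = mat$sequences[rownames(kept)])
}

#' Remove sequences spanning low-occupancy alignment columns
#'
#' Column occupancy is the fraction of non-gap characters in that column.
#' A sequence carrying a non-gap character in any column whose occupancy is
#' below `threshold` is removed. Because removals change occupancy, the
#' rule is iterated to a fixed point by default (a single pass is available
#' via `iterate = FALSE`).
#'
#' @param alignment character matrix over `A,C,G,T,-`, rows = sequences.
#' @param threshold occupancy threshold in (0, 1]; default 0.10.
#' @param iterate iterate to a fixed point (default) or apply one pass.
#' @return the filtered alignment (possibly with zero rows).
#' @export
occupancy_filter <- function(alignment, threshold = 0.10, iterate = TRUE) {
  stopifnot(is.matrix(alignment))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]")
  }
  repeat {
    if (nrow(alignment) == 0L) break
    occ <- colMeans(alignment != "-")
    low <- occ < threshold & occ > 0
    if (!any(low)) break
    bad <- rowSums(alignment[, low, drop = FALSE] != "-") > 0
    if (!any(bad)) break
    alignment <- alignment[!bad, , drop = FALSE]
    if (!iterate) break
  }
  alignment
}

#' Cap a sample at its most phylogenetically diverse variants
#'
#' When a sample holds more than `cap` variants, they are reduced to `cap`
#' representatives: Ward's hierarchical clustering (`ward.D2`) on patristic
#' distances is cut into `cap` groups and each group contributes its medoid
#' (the member minimising the summed distance to the rest of the group).
#' Ties are broken by highest abundance, then lexicographic variant ID.
#'
#' @param variant_ids variants present in the sample.
#' @param tree_or_distance a `phylo`/`timed_tree` (patristic distances are
#'   computed from it) or a symmetric distance matrix containing all
#'   `variant_ids`.
#' @param cap maximum number of variants to keep (default 50).
#' @param abundance optional named numeric vector used for tie-breaking.
#' @return character vector of at most `cap` representative variant IDs,
#'   in their input order.
#' @export
phylodiversity_cap <- function(variant_ids, tree_or_distance, cap = 50,
                               abundance = NULL) {
  variant_ids <- as.character(variant_ids)
  if (length(variant_ids) <= cap) return(variant_ids)
  D <- if (inherits(tree_or_distance, "timed_tree")) {
    ape::cophenetic.phylo(tree_or_distance$tree)
  } else if (inherits(tree_or_distance, "phylo")) {
    ape::cophenetic.phylo(tree_or_distance)
  } else {
    as.matrix(tree_or_distance)
  }
  if (!all(variant_ids %in% rownames(D))) {
    stop("patristic distances missing for: ",
         paste(setdiff(variant_ids, rownames(D)), collapse = ", "))
  }
  D <- D[variant_ids, variant_ids, drop = FALSE]
  grp <- cutree(hclust(as.dist(D), method = "ward.D2"), k = cap)
  reps <- vapply(split(variant_ids, grp), function(members) {
    sub <- D[members, members, drop = FALSE]
    tot <- rowSums(sub)
    cand <- members[tot == min(tot)]
    if (length(cand) > 1L && !is.null(abundance)) {
      ab <- abundance[cand]
      ab[is.na(ab)] <- -Inf
      cand <- cand[ab == max(ab)]
    }
    sort(cand)[1L]
  }, character(1L))
  variant_ids[variant_ids %in% reps]
}
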