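#' Default configuration of a synthetic multi-site core study
#'
#' Returns the study design used throughout the package's validation work:
#' four sites, each a stack of six dated horizons (1760-2010 CE, every 50
#' years) contributing ten genealogy tips, with site-specific baseline Ne
#' and a shared ten-fold sigmoidal Ne increase whose logistic midpoint is
#' the year 1784. Sequences evolve under GTR+Gamma with an uncorrelated
#' lognormal clock (mean 0.001 substitutions/site/year, log-sd 1).
#'
#' @param n_sites,n_horizons,tips_per_horizon design dimensions.
#' @param breakpoint_date shared logistic midpoint, CE.
#' @param fold_change late/early Ne ratio.
#' @param steepness logistic rate per year.
#' @param base_ne baseline Ne per site (recycled to `n_sites`).
#' @param kit_rate,cross_rate contamination intensities in `[0, 1]`.
#' @param seq_length simulated amplicon length, bp.
#' @return configuration list for [generate_core_study()].
#' @export
core_study_config <- function(n_sites = 4, n_horizons = 6,
                              tips_per_horizon = 10,
                              breakpoint_date = 1784, fold_change = 10,
                              steepness = 0.1,
                              base_ne = c(80, 120, 160, 240),
                              kit_rate = 0.05, cross_rate = 0.05,
                              seq_length = 300) {
  dates <- seq(2010, by = -50, length.out = n_horizons)
  base_ne <- rep_len(base_ne, n_sites)
  sites <- lapply(seq_len(n_sites), function(i) {
    list(site_id = sprintf("S%d", i),
         horizons = data.frame(date_CE = dates,
                               n_tips = tips_per_horizon),
         trajectory = ne_trajectory("sigmoidal_breakpoint",
                                    base_ne = base_ne[i],
                                    fold_change = fold_change,
                                    breakpoint_date = breakpoint_date,
                                    steepness = steepness))
  })
  list(sites = sites, breakpoint_date = breakpoint_date,
       clock = clock_model(0.001, 1.0, "uncorrelated_lognormal"),
       substitution = substitution_model(
         exchangeabilities = c(1, 3, 1, 1, 3, 1),
         base_frequencies = c(0.30, 0.20, 0.25, 0.25),
         gamma_shape = 0.5, n_categories = 4L),
       seq_length = seq_length,
       kit_rate = kit_rate, cross_rate = cross_rate,
       mean_reads_per_tip = 10)
}

#' Generate a synthetic multi-site sediment-core study
#'
#' Simulates, per site, a heterochronous genealogy under the site's Ne
#' trajectory, relaxed-clock branch rates and GTR+Gamma sequences; tips
#' are binned into their horizon's sample, read counts are drawn per tip,
#' and exact dereplication produces the variant abundance matrix. Kit and
#' cross-sample contaminant variants are then injected (see
#' [inject_contamination()]) together with a negative-control sample, and
#' the complete ground truth is returned alongside. Each site consumes an
#' independently forked RNG stream, so adding a site leaves the others
#' unchanged.
#'
#' @param config a [core_study_config()] list.
#' @param seed integer master seed.
#' @return list of class `core_study`: `matrix` (an [abundance_matrix()]
#'   including the control), `genealogies` (named list of `timed_tree`),
#'   and `truth` (trajectories, shared breakpoint date, contaminant IDs,
#'   config and seed).
#' @export
generate_core_study <- function(config = core_study_config(), seed = 1) {
  site_ids <- vapply(config$sites, `[[`, character(1), "site_id")
  if (anyDuplicated(site_ids)) {
    stop("conflicting site labels: ",
         paste(site_ids[duplicated(site_ids)], collapse = ", "))
  }
  if (length(config$sites) < 1L) stop("need at least one site")
  genealogies <- list()
  seq_by_sample <- list()
  meta <- list()
  for (i in seq_along(config$sites)) {
    site <- config$sites[[i]]
    if (nrow(site$horizons) < 2L) stop("need >= 2 horizons per site")
    site_seed <- fork_seed(seed, i)
    design <- sampling_design(site$site_id, site$horizons)
    tt <- simulate_genealogy(design, site$trajectory, seed = site_seed)
    rates <- simulate_branch_rates(tt, config$clock,
                                   seed = fork_seed(site_seed, 1L))
    aln <- simulate_sequences(tt, rates, config$substitution,
                              config$seq_length,
                              seed = fork_seed(site_seed, 2L))
    genealogies[[site$site_id]] <- tt
    reads <- with_seed(fork_seed(site_seed, 3L), {
      1L + rpois(nrow(aln), config$mean_reads_per_tip - 1)
    })
    hz <- as.integer(sub(".*_h(\\d+)_t.*", "\\1", rownames(aln)))
    for (h in sort(unique(hz))) {
      sid <- sprintf("%s_h%02d", site$site_id, h)
      idx <- which(hz == h)
      seq_by_sample[[sid]] <- rep(apply(aln[idx, , drop = FALSE], 1, paste,
                                        collapse = ""),
                                  times = reads[idx])
      meta[[sid]] <- data.frame(sample_id = sid, site_id = site$site_id,
                                date_CE = design$horizons$date_CE[h],
                                is_control = FALSE,
                                stringsAsFactors = FALSE)
    }
  }
  seq_by_sample[["CTRL"]] <- character(0)
  meta[["CTRL"]] <- data.frame(sample_id = "CTRL", site_id = NA_character_,
                               date_CE = NA_real_, is_control = TRUE,
                               stringsAsFactors = FALSE)
  samples <- do.call(rbind, meta[names(seq_by_sample)])
  rownames(samples) <- NULL
  mat <- dereplicate(seq_by_sample, samples = samples)
  contaminated <- inject_contamination(mat, config$kit_rate,
                                       config$cross_rate,
                                       seed = fork_seed(seed, 0L),
                                       seq_length = config$seq_length)
  truth <- list(trajectories = setNames(lapply(config$sites, `[[`,
                                               "trajectory"), site_ids),
                breakpoint_date = config$breakpoint_date,
                kit_ids = contaminated$kit_ids,
                cross_ids = contaminated$cross_ids,
                config = config, seed = seed)
  structure(list(matrix = contaminated$matrix, genealogies = genealogies,
                 truth = truth),
            class = "core_study")
}

#' @export
print.core_study <- function(x, ...) {
  cat("Synthetic core study:", length(x$genealogies), "sites,",
      ncol(x$matrix$counts), "samples,", nrow(x$matrix$counts),
      "variants\n")
  cat("  shared breakpoint:", x$truth$breakpoint_date, "CE;",
      length(x$truth$kit_ids), "kit and", length(x$truth$cross_ids),
      "cross contaminants\n")
  invisible(x)
}

#' Inject kit and cross-sample contaminant variants
#'
#' Emulates the two contamination modes the downstream filters remove:
#' *kit* contaminants are novel variants added to the negative control and
#' to a random subset of samples; *cross* contaminants duplicate an
#' existing single-sample variant into a second sample of the same site.
#' Injected IDs are reported so synthetic studies carry perfect ground
#' truth for filter validation.
#'
#' @param mat an [abundance_matrix()] (with a control sample for kit
#'   injection to have a target).
#' @param kit_rate fraction of the final variant roster made of kit
#'   contaminants, in `[0, 1]`.
#' @param cross_rate fraction of each site's single-sample variants to
#'   duplicate, in `[0, 1]`.
#' @param seed integer seed.
#' @param seq_length length of generated contaminant sequences.
#' @return list `matrix`, `kit_ids`, `cross_ids`.
#' @export
inject_contamination <- function(mat, kit_rate, cross_rate, seed = 1,
                                 seq_length = 300) {
  stopifnot(inherits(mat, "abundance_matrix"),
            kit_rate >= 0, kit_rate <= 1, cross_rate >= 0, cross_rate <= 1)
  if (kit_rate == 0 && cross_rate == 0) {
    return(list(matrix = mat, kit_ids = character(0),
                cross_ids = character(0)))
  }
  with_seed(seed, {
    counts <- mat$counts
    seqs <- mat$sequences
    samples <- mat$samples
    ctrl <- which(samples$is_control)
    n_real <- nrow(counts)
    # kit_rate is the contaminant share of the final roster:
    # n_kit / (n_real + n_kit) = kit_rate
    n_kit <- round(kit_rate * n_real / (1 - min(kit_rate, 0.999)))
    kit_ids <- character(0)
    if (n_kit > 0 && length(ctrl) > 0) {
      kit_ids <- sprintf("kit%03d", seq_len(n_kit))
      kit_seq <- vapply(seq_len(n_kit), function(i) {
        paste(sample(c("A", "C", "G", "T"), seq_length, replace = TRUE),
              collapse = "")
      }, character(1))
      add <- matrix(0L, n_kit, ncol(counts),
                    dimnames = list(kit_ids, colnames(counts)))
      add[, ctrl] <- 1L + rpois(n_kit * length(ctrl), 4)
      target <- which(!samples$is_control)
      for (i in seq_len(n_kit)) {
        hit <- target[runif(length(target)) < 0.5]
        if (length(hit) == 0L) hit <- sample(target, 1L)
        add[i, hit] <- 1L + rpois(length(hit), 2)
      }
      counts <- rbind(counts, add)
      if (!is.null(seqs)) seqs <- c(seqs, setNames(kit_seq, kit_ids))
    }
    cross_ids <- character(0)
    sites <- unique(samples$site_id[!samples$is_control])
    sites <- sites[!is.na(sites)]
    for (s in sites) {
      cols <- which(samples$site_id %in% s)
      if (length(cols) < 2L) next
      occ <- rowSums(counts[, cols, drop = FALSE] > 0)
      single <- setdiff(rownames(counts)[occ == 1L], kit_ids)
      n_cross <- round(cross_rate * length(single))
      if (n_cross == 0L) next
      chosen <- sample(single, n_cross)
      for (v in chosen) {
        src <- cols[counts[v, cols] > 0]
        dst <- setdiff(cols, src)
        if (length(dst) > 1L) dst <- dst[sample.int(length(dst), 1L)]
        counts[v, dst] <- 1L + rpois(1L, 2)
      }
      cross_ids <- c(cross_ids, chosen)
    }
    list(matrix = abundance_matrix(counts, samples, sequences = seqs),
         kit_ids = kit_ids, cross_ids = cross_ids)
  })
}
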