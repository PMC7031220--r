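# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# Hand-built timed tree from a newick string plus tip dates.
make_timed_tree <- function(newick, dates, most_recent = max(dates)) {
  tree <- ape::read.tree(text = newick)
  structure(list(tree = tree,
                 tip_dates = data.frame(tip = names(dates),
                                        date_CE = unname(dates),
                                        stringsAsFactors = FALSE),
                 most_recent_date = most_recent),
            class = "timed_tree")
}

# Two contemporaneous tips coalescing `tau` years ago.
two_tip_tree <- function(tau, date = 2000) {
  make_timed_tree(sprintf("(a:%g,b:%g);", tau, tau),
                  c(a = date, b = date))
}

# Small abundance matrix from an explicit count table.
make_matrix <- function(counts, sites, dates = NULL, controls = NULL) {
  ids <- colnames(counts)
  samples <- data.frame(sample_id = ids, site_id = sites,
                        date_CE = dates %||% rep(NA_real_, length(ids)),
                        is_control = controls %||% rep(FALSE, length(ids)),
                        stringsAsFactors = FALSE)
  abundance_matrix(counts, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Single-site design used by several simulator tests.
flat_design <- function(n_tips, date = 2000, site = "X") {
  sampling_design(site, data.frame(date_CE = date, n_tips = n_tips))
}

serial_design <- function(dates, tips_each, site = "X") {
  sampling_design(site, data.frame(date_CE = dates, n_tips = tips_each))
}
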