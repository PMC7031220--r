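#' Read and write FASTA alignments
#'
#' Thin wrappers around the `ape` FASTA machinery operating on plain
#' character matrices (rows = sequences, columns = sites), the alignment
#' representation used by the filters.
#'
#' @param path file path.
#' @param alignment character matrix over `A,C,G,T,-` with row names.
#' @return `read_fasta` returns a character matrix; `write_fasta` the path,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  bin <- ape::read.FASTA(path)
  if (length(bin) == 0L) stop("no FASTA records in ", path)
  mat <- toupper(as.character(as.matrix(bin)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1,
                                       dimnames = list(names(bin), NULL))
  mat
}

#' @rdname read_fasta
#' @export
write_fasta <- function(alignment, path) {
  stopifnot(is.matrix(alignment), !is.null(rownames(alignment)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alignment))) {
    writeLines(c(paste0(">", rownames(alignment)[i]),
                 paste(alignment[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Read and write timed genealogies
#'
#' Newick serialisation for `timed_tree` objects, with the tip dates in a
#' sidecar TSV (`tip`, `date_CE`) rather than parsed from labels.
#'
#' @param tt a `timed_tree`.
#' @param path Newick file path; the sidecar is `<path>.dates.tsv`.
#' @return `read_timed_tree` returns a `timed_tree`; `write_timed_tree`
#'   the path, invisibly.
#' @export
write_timed_tree <- function(tt, path) {
  stopifnot(inherits(tt, "timed_tree"))
  ape::write.tree(tt$tree, file = path)
  write_tsv(tt$tip_dates, paste0(path, ".dates.tsv"))
  invisible(path)
}

#' @rdname write_timed_tree
#' @param most_recent_date reference date; defaults to the youngest tip.
#' @export
read_timed_tree <- function(path, most_recent_date = NULL) {
  tree <- ape::read.tree(path)
  dates <- read_tsv_checked(paste0(path, ".dates.tsv"),
                            required = c("tip", "date_CE"))
  if (!all(tree$tip.label %in% dates$tip)) {
    stop("sidecar dates missing for some tips")
  }
  structure(list(tree = tree,
                 tip_dates = dates[match(tree$tip.label, dates$tip), ,
                                   drop = FALSE],
                 most_recent_date = most_recent_date %||%
                   max(dates$date_CE)),
            class = "timed_tree")
}

#' Read a posterior tree sample
#'
#' Reads a collection of trees from a NEXUS trees block (translate tables
#' supported) or a multi-tree Newick file, dispatching on the file's first
#' non-blank line.
#'
#' @param path file path.
#' @return list of `phylo` objects.
#' @export
read_tree_sample <- function(path) {
  first <- ""
  con <- file(path, "r")
  on.exit(close(con))
  while (!nzchar(trimws(first))) first <- readLines(con, n = 1L)
  trees <- if (grepl("#NEXUS", first, ignore.case = TRUE)) {
    ape::read.nexus(path)
  } else {
    ape::read.tree(path)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!is.null(attr(trees, "TipLabel"))) {
    trees <- ape::.uncompressTipLabel(trees)
  }
  lapply(unclass(trees), function(t) {
    attr(t, "order") <- NULL
    t
  })
}

#' Tabular input/output with column checking
#'
#' @param path TSV file path.
#' @param required columns that must be present; a missing column is an
#'   error naming it.
#' @return data frame.
#' @export
read_tsv_checked <- function(path, required = character(0)) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  }
  tab
}

#' @rdname read_tsv_checked
#' @param x data frame to write.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a study configuration file
#'
#' YAML configuration controlling the simulator and analysis defaults;
#' unknown keys are passed through to [core_study_config()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(core_study_config, cfg)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run byte-for-byte: the seed, a
#' hash of the configuration, package and R versions, and md5 checksums of
#' the input files.
#'
#' @param path output JSON path.
#' @param config configuration object (hashed after serialisation).
#' @param seed integer seed.
#' @param inputs character vector of input file paths to checksum.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = character(0)) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2, compress = FALSE)
  manifest <- list(
    seed = as.integer(seed),
    config_md5 = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("paleoNe")),
    r_version = as.character(getRversion()),
    inputs = as.list(setNames(unname(tools::md5sum(inputs)),
                              basename(inputs))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
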