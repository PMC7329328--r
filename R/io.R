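# Readers and writers for the pipeline's TSV table formats, run
# configuration, and the results manifest.

#' Run configuration with pipeline defaults
#'
#' Collects the tunable parameters of the pipeline with their standard
#' defaults: read-depth and detection filters (strict `> 5000` reads,
#' `> 5` samples), pseudocount 1, 100 fitting restarts, the 1.48
#' ln-unit kinetics growth threshold, 10,000 permutations, and a
#' mandatory seed for every stochastic stage.
#'
#' @param seed Integer seed (mandatory; every stochastic stage derives
#'   from it).
#' @param min_reads,min_samples,pseudocount,n_restarts,n_perm,
#'   kinetics_threshold Pipeline parameters; see the function signature
#'   for defaults.
#' @param bounds A [gompertz_bounds()] object.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed, min_reads = 5000, min_samples = 5,
                       pseudocount = 1, n_restarts = 100, n_perm = 10000,
                       kinetics_threshold = 1.48,
                       bounds = gompertz_bounds()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed)) {
    stop("'seed' is mandatory: every stochastic stage must be seeded")
  }
  stopifnot(min_reads >= 0, min_samples >= 0, pseudocount >= 0,
            n_restarts >= 1, n_perm >= 1, kinetics_threshold >= 0,
            inherits(bounds, "gompertz_bounds"))
  structure(
    list(seed = as.integer(seed), min_reads = min_reads,
         min_samples = min_samples, pseudocount = pseudocount,
         n_restarts = n_restarts, n_perm = n_perm,
         kinetics_threshold = kinetics_threshold, bounds = bounds),
    class = "run_config")
}

#' Read an SV count table from TSV
#'
#' Expects a tab-separated file with a header row of SV identifiers and a
#' first column of sample ids.  Counts must be non-negative integers;
#' malformed cells are reported with their row and column coordinates.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix, samples x SVs, with sample ids as rownames.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("empty or malformed count table: ", path)
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s): ", paste(unique(ids[duplicated(ids)]),
                                           collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  bad <- which(vapply(vals, function(col) {
    !is.numeric(col) || any(!is.finite(col)) || any(col < 0) ||
      any(col != floor(col))
  }, logical(1L)))
  if (length(bad) > 0L) {
    col <- bad[1L]
    row <- which(!is.numeric(vals[[col]]) | !is.finite(vals[[col]]) |
                   vals[[col]] < 0 | vals[[col]] != floor(vals[[col]]))[1L]
    stop("non-integer count at sample \"", ids[row], "\", SV \"",
         names(vals)[col], "\"")
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Read a qPCR totals table from TSV
#'
#' Two columns: sample id and total 16S concentration (arbitrary
#' calibrated units).
#'
#' @param path Path to the TSV file.
#' @return Named numeric vector of concentrations.
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("qPCR table needs sample-id and value columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample id(s) in qPCR table")
  vals <- df[[2L]]
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("qPCR concentrations must be finite numbers")
  }
  stats::setNames(vals, ids)
}

#' Read a sample metadata table from TSV
#'
#' @param path Path to a TSV keyed by a `sample` column.
#' @return Data frame with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) {
    stop("metadata must contain a 'sample' column")
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample id(s) in metadata")
  df
}

#' Write result tables with a run summary and manifest
#'
#' Writes each table as TSV (matrices gain a leading `sample` / id
#' column; column order is deterministic), plus a `run_summary.json`
#' recording the configuration, seed, package version, and an MD5
#' checksum of every file written.
#'
#' @param tables Named list of matrices or data frames.
#' @param config A [run_config()] (or any list; stored as-is in the
#'   summary).
#' @param out_dir Output directory, created if needed.
#' @param force Overwrite existing files (default `FALSE`; a collision
#'   without `force` is refused).
#' @return Invisibly, a data frame manifest of `file` and `md5`.
#' @export
write_results <- function(tables, config, out_dir, force = FALSE) {
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("'tables' must be a fully named list")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- file.path(out_dir, paste0(names(tables), ".tsv"))
  summary_file <- file.path(out_dir, "run_summary.json")
  existing <- c(files, summary_file)[file.exists(c(files, summary_file))]
  if (length(existing) > 0L && !force) {
    stop("refusing to overwrite existing file(s): ",
         paste(basename(existing), collapse = ", "),
         " (use force = TRUE)")
  }
  for (i in seq_along(tables)) {
    tab <- tables[[i]]
    if (is.matrix(tab)) {
      tab <- data.frame(id = rownames(tab), tab, check.names = FALSE)
    }
    utils::write.table(tab, files[i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  cfg <- config
  if (inherits(cfg, "run_config")) {
    cfg$bounds <- list(lower = as.list(unclass(cfg$bounds)$lower),
                       upper = as.list(unclass(cfg$bounds)$upper))
    cfg <- unclass(cfg)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  summary <- list(
    package = "dropcult",
    version = as.character(utils::packageVersion("dropcult")),
    config = cfg,
    files = manifest
  )
  jsonlite::write_json(summary, summary_file, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest <- rbind(manifest,
                    data.frame(file = basename(summary_file),
                               md5 = unname(tools::md5sum(summary_file))))
  invisible(manifest)
}
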