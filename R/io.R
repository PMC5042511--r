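#' Write a remodeling trajectory to CSV
#'
#' One row per simulated day, comma-separated, '.' decimal, header row,
#' units embedded in the column names.
#'
#' @param result A `remodel_result` (or any list with `$trajectory`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(result, path) {
  tr <- if (is.data.frame(result)) result else result$trajectory
  stopifnot(!is.null(tr))
  utils::write.csv(tr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the seed, a hash of the configuration, and the package version,
#' which together suffice to reproduce a run bit-exactly.
#'
#' @param config The `remodel_config` used.
#' @param seed The seed used.
#' @param path Output path.
#' @param extra Optional named list of additional entries.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, seed, path, extra = list()) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the jsonlite package is required to write run manifests")
  }
  cfg_chr <- yaml::as.yaml(unclass(config))
  manifest <- c(list(
    seed = seed,
    config_hash = digest_chr(cfg_chr),
    package = "tendonadapt",
    version = as.character(utils::packageVersion("tendonadapt")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Small dependency-free string checksum (djb2, hex).
digest_chr <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
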