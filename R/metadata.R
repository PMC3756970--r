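#' Write a run-metadata sidecar
#'
#' Records configuration digest, seed and software versions next to run
#' artifacts for provenance.
#'
#' @param path output YAML path.
#' @param config a [ModelConfig-class] (optional).
#' @param seed seed used (optional).
#' @param extra named list of additional fields.
#' @return `path`, invisibly.
#' @export
writeRunMetadata <- function(path, config = NULL, seed = NULL, extra = list()) {
  meta <- c(list(
    package = "invasionCA",
    version = as.character(packageVersion("invasionCA")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  if (!is.null(config)) meta$config_md5 <- configDigest(config)
  if (!is.null(seed)) meta$seed <- as.integer(seed)
  yaml::write_yaml(meta, path)
  invisible(path)
}
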