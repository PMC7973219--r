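#' Read a network configuration from a YAML file
#'
#' The file holds a flat mapping of [network_config()] arguments, with the
#' neuron parameter sets nested under `adex`, `adex_mnp` and `nsi` (each a
#' mapping of the corresponding constructor's arguments). Missing entries
#' keep the shipped calibration defaults.
#'
#' @param path YAML file
#' @return A [network_config()].
#' @export
read_network_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configurations requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  ctor <- function(f, x) do.call(f, x[intersect(names(x), names(formals(f)))])
  args <- list()
  if (!is.null(raw$adex)) args$adex <- ctor(adex_params, raw$adex)
  if (!is.null(raw$adex_mnp)) args$adex_mnp <- ctor(adex_params, raw$adex_mnp)
  if (!is.null(raw$nsi)) args$nsi <- ctor(nsi_params, raw$nsi)
  scalar <- setdiff(names(raw), c("adex", "adex_mnp", "nsi"))
  ok <- intersect(scalar, names(formals(network_config)))
  bad <- setdiff(scalar, ok)
  if (length(bad)) stop("unknown configuration fields: ",
                        paste(bad, collapse = ", "))
  do.call(network_config, c(args, raw[ok]))
}

#' Write a network configuration as YAML
#'
#' @param config a [network_config()]
#' @param path output file
#' @export
write_network_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("writing YAML configurations requires the 'yaml' package")
  }
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::write_yaml(strip(config), path)
}
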