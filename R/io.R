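#' Read and write patient registries as CSV
#'
#' The registry schema is the one produced by [generate_registry()]:
#' one row per patient with exclusion flags as a `;`-separated string
#' and the split assignment written back as a column.
#'
#' @param registry a registry data.frame.
#' @param path CSV path.
#' @return the path (writer) / the registry data.frame (reader).
#' @export
write_registry <- function(registry, path) {
  stopifnot(is.data.frame(registry))
  write.csv(registry, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(exclusion_flags = "character"))
  df$exclusion_flags[is.na(df$exclusion_flags)] <- ""
  if ("split" %in% names(df)) df$split[is.na(df$split)] <- ""
  df
}

#' Write a feature table as CSV keyed by case id
#'
#' @param features numeric matrix (cases x features) with row names.
#' @param path CSV path.
#' @export
write_features_csv <- function(features, path) {
  write.csv(data.frame(id = rownames(features), features,
                       check.names = FALSE),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Save or load a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path YAML path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(sim_config, y)
}
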