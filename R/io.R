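# Plain-text configuration and results I/O.

#' Read a configuration file
#'
#' Flat key-value text: one `key = value` per line, `#` comments and blank
#' lines ignored. Values are parsed as logical (`true`/`false`), numeric, or
#' bare strings (for the mode enums). Keys are merged over the documented
#' defaults; unknown keys and out-of-range values are rejected with the
#' offending name.
#'
#' @param path configuration file.
#' @return a validated [world_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  overrides <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("cannot parse configuration line: '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parsed <- if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) num else gsub("^['\"]|['\"]$", "", val)
    }
    overrides[[key]] <- parsed
  }
  modify_config(world_config(), overrides)
}

#' Write a configuration file
#'
#' @param config a [world_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  fmt <- function(v) {
    if (is.logical(v)) tolower(as.character(v))
    else if (is.numeric(v)) format(v, digits = 17, scientific = TRUE)
    else as.character(v)
  }
  writeLines(paste(names(config), "=", vapply(config, fmt, character(1))),
             path)
  invisible(path)
}

#' Write simulation results as tidy CSV
#'
#' A single run writes one row per tick. A [run_replicates()] summary writes
#' the per-tick mean and standard deviation of every metric with `_mean` /
#' `_sd` column suffixes.
#'
#' @param x a metrics data.frame or a `replicate_summary`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (inherits(x, "replicate_summary")) {
    mu <- x$mean
    sdv <- x$sd
    names(mu) <- paste0(names(mu), "_mean")
    names(sdv) <- paste0(names(sdv), "_sd")
    df <- cbind(mu, sdv)
  } else if (is.data.frame(x)) {
    if (!nrow(x)) stop("empty metrics series")
    df <- x
  } else {
    stop("unsupported results object of class ", class(x)[1])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a results CSV
#'
#' @param path CSV file written by [write_results()].
#' @return data.frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  df <- utils::read.csv(path)
  if ("oxic" %in% names(df)) df$oxic <- as.logical(df$oxic)
  df
}
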