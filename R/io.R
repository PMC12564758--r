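# File formats ---------------------------------------------------------------
#
# Canonical spec format is JSON:
#   {"pools": [...], "u": [...], "B": [[...], ...],
#    "time_unit": "...", "mass_unit": "..."}
# The CSV convenience format is a d x (d+1) table: the d columns of B
# followed by a final column u; pool names are taken from the row names.

#' Read and write compartmental system specifications
#'
#' `read_system()` loads a system from a JSON spec (canonical) or a CSV
#' table (`d` columns of `B` plus a final `u` column); the format is chosen
#' by file extension.  `write_system()` writes the JSON form.  The loaded
#' system passes full validation, so malformed specs fail with the message
#' of the violated invariant.  Units are metadata only: no conversion is
#' performed.
#'
#' @param path file path ending in `.json` or `.csv`.
#' @param sys a [compartmental_system()].
#' @return `read_system()`: a [compartmental_system()];
#'   `write_system()`: `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_system(compartmental_system(c(1, 0), rbind(c(-1, 0), c(1, -1))), f)
#' read_system(f)
#' @export
read_system <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    spec <- jsonlite::fromJSON(path)
    for (field in c("u", "B")) {
      if (is.null(spec[[field]])) {
        stop(sprintf("system spec '%s' is missing required field '%s'",
                     path, field))
      }
    }
    compartmental_system(
      u = as.numeric(spec$u),
      B = matrix(as.numeric(as.matrix(spec$B)), nrow = length(spec$u)),
      pool_names = spec$pools,
      time_unit = if (is.null(spec$time_unit)) "time" else spec$time_unit,
      mass_unit = if (is.null(spec$mass_unit)) "mass" else spec$mass_unit)
  } else if (ext == "csv") {
    tab <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    d <- nrow(tab)
    if (ncol(tab) != d + 1L) {
      stop("CSV system spec must be a d x (d+1) table: d columns of B plus a final u column")
    }
    compartmental_system(u = as.numeric(tab[[d + 1L]]),
                         B = as.matrix(tab[, seq_len(d)]),
                         pool_names = rownames(tab))
  } else {
    stop("unsupported system spec format: .", ext)
  }
}

#' @rdname read_system
#' @export
write_system <- function(sys, path) {
  stopifnot(is.compartmental_system(sys))
  spec <- list(
    pools = if (is.null(sys$pool_names)) paste0("pool", seq_len(sys$d))
            else sys$pool_names,
    u = sys$u,
    B = unname(sys$B),
    time_unit = sys$time_unit,
    mass_unit = sys$mass_unit)
  jsonlite::write_json(spec, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Write an entropy report
#'
#' Serializes an [path_entropy()] report to JSON or a one-row CSV with
#' columns `H_path`, `H_beta`, `H_jump_part`, `H_sojourn_part`,
#' `theta_time`, `theta_jump`, `H_system`, `ET`, `EN`, `log_base`.
#'
#' @param report an `"entropy_report"` object.
#' @param path output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_entropy_report <- function(report, path) {
  stopifnot(inherits(report, "entropy_report"))
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(report)
  if (ext == "json") {
    jsonlite::write_json(as.list(df), path, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  } else if (ext == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    stop("unsupported report format: .", ext)
  }
  invisible(path)
}

#' Write Monte-Carlo estimates as JSON
#'
#' @param est an [mc_estimates()] object.
#' @param path output path ending in `.json`.
#' @return `path`, invisibly.
#' @export
write_mc_estimates <- function(est, path) {
  stopifnot(inherits(est, "mc_estimates"))
  jsonlite::write_json(unclass(est), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
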