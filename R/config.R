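## Flat key-value run configuration (TOML-compatible subset) and the
## provenance manifest written alongside every pipeline run.

#' Read a flat key = value configuration file
#'
#' Accepts the flat scalar subset of TOML: `key = value` lines, `#`
#' comments, quoted strings, booleans `true`/`false`, and numbers. No
#' tables or arrays.
#'
#' @param path file path.
#' @return Named list of scalars.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (k in seq_along(lines)) {
    m <- regmatches(lines[k], regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$",
                                      lines[k]))[[1]]
    if (length(m) != 3L)
      stop(sprintf("config parse error at '%s': expected key = value",
                   lines[k]))
    key <- m[2]
    val <- trimws(m[3])
    out[[key]] <-
      if (grepl('^".*"$', val)) sub('^"(.*)"$', "\\1", val)
      else if (val %in% c("true", "false")) val == "true"
      else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) stop(sprintf("config parse error: bad value for '%s'", key))
        num
      }
  }
  out
}

#' Write a provenance manifest
#'
#' Records the package version and all run parameters and seeds as JSON
#' next to the outputs. Deliberately excludes timestamps so reruns with
#' identical seeds produce byte-identical manifests.
#'
#' @param path output path.
#' @param params named list of parameters and seeds.
#' @param outputs named list/character of produced files.
#' @export
write_provenance <- function(path, params, outputs = NULL) {
  manifest <- list(
    tool = "pearlnecklace",
    version = as.character(utils::packageVersion("pearlnecklace")),
    parameters = params,
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
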