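#' Read a univariate series from CSV/TSV
#'
#' One numeric value per row; a single leading non-numeric line is treated
#' as a header and skipped. Parsing uses the C locale decimal point
#' regardless of the session locale.
#'
#' @param path File path.
#' @return Numeric vector.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) abort(sprintf("series file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("series file is empty: %s", path))
  start <- 1L
  first <- suppressWarnings(as.numeric(lines[1]))
  if (is.na(first)) start <- 2L  # header
  if (start > length(lines)) {
    abort(sprintf("series file has a header but no values: %s", path))
  }
  vals <- suppressWarnings(as.numeric(lines[start:length(lines)]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1] + start - 1L
    abort(sprintf("non-numeric value at line %d of %s: '%s'",
                  bad, path, lines[bad]))
  }
  vals
}

#' Read a cohort manifest
#'
#' CSV with columns `id`, `label`, `path` locating one series file per
#' patient. Ids must be unique, labels binary, and every path must exist
#' (relative paths are resolved against the manifest's directory).
#'
#' @param path Manifest file path.
#' @return Tibble with columns `id` (character), `label` (integer), `path`
#'   (resolved character paths).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "label", "path") %in% names(df))) {
    abort("manifest must have columns id, label, path")
  }
  if (anyDuplicated(df$id)) abort("manifest ids must be unique")
  if (!is_binary_label(as.numeric(df$label))) {
    abort("manifest labels must be binary (0/1)")
  }
  base <- dirname(path)
  resolved <- ifelse(file.exists(df$path), df$path,
                     file.path(base, df$path))
  missing <- !file.exists(resolved)
  if (any(missing)) {
    abort(sprintf("series files not found: %s",
                  paste(df$path[missing], collapse = ", ")))
  }
  tibble(id = as.character(df$id), label = as.integer(df$label),
         path = as.character(resolved))
}

#' Read all records listed in a manifest
#'
#' @param manifest Path to a manifest CSV, or a tibble as returned by
#'   [read_manifest()].
#' @return Tibble with columns `id`, `label` and list-column `values`,
#'   ready for [encode_records()].
#' @export
read_records <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  tibble(id = manifest$id, label = manifest$label,
         values = lapply(manifest$path, read_series))
}

#' Write records as CSV files plus a manifest
#'
#' Inverse of [read_records()]: one single-column CSV per record (header
#' `value`) and a `manifest.csv` with `id,label,path` rows, the format the
#' encoder consumes.
#'
#' @param records Tibble with columns `id`, `label`, `values`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_records <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_len(nrow(records)), function(i) {
    p <- file.path(dir, paste0(records$id[i], ".csv"))
    writeLines(c("value", format(records$values[[i]], digits = 10,
                                 trim = TRUE, scientific = FALSE)), p)
    p
  }, character(1))
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(
    data.frame(id = records$id, label = records$label,
               path = basename(paths)),
    mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Write labeled symbol strings
#'
#' One record per line in the format `<label><space><text>`, e.g.
#' `1 abbaccabcaba...`.
#'
#' @param strings Tibble with columns `label` and `text`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_symbol_strings <- function(strings, path) {
  stopifnot(all(c("label", "text") %in% names(strings)))
  writeLines(paste(strings$label, strings$text), path)
  invisible(path)
}

#' Read labeled symbol strings
#'
#' Parses the `<label><space><text>` line format; trailing whitespace is
#' tolerated. Malformed labels error with the offending line number.
#'
#' @param path Input path.
#' @return Tibble with columns `id` (line number as character), `label`
#'   (integer) and `text`.
#' @export
read_symbol_strings <- function(path) {
  if (!file.exists(path)) abort(sprintf("strings file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  m <- regmatches(lines, regexec("^([01])[ \t]+(\\S+)[ \t]*$", lines))
  bad <- which(vapply(m, length, integer(1)) != 3)
  if (length(bad) > 0) {
    abort(sprintf("malformed symbol-string line %d: '%s'",
                  which(keep)[bad[1]], lines[bad[1]]))
  }
  tibble(id = as.character(seq_along(lines)),
         label = as.integer(vapply(m, `[`, character(1), 2)),
         text = vapply(m, `[`, character(1), 3))
}

#' Serialize transducer parameters to JSON
#'
#' Fields in fixed order (`alphabet`, `ins`, `sub`, `del`, `gamma`), with
#' probabilities written at 17 significant digits so that a write/read
#' round trip reproduces the parameters bit-identically.
#'
#' @param params A [transducer_params()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_transducer_params <- function(params, path) {
  stopifnot(inherits(params, "transducer_params"))
  obj <- list(
    alphabet = paste(params$alphabet, collapse = ""),
    ins = unname(params$ins),
    sub = unname(params$sub),
    del = unname(params$del),
    gamma = params$gamma
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  writeLines(json, path)
  invisible(path)
}

#' Read transducer parameters from JSON
#'
#' @param path Path written by [write_transducer_params()].
#' @return A [transducer_params()] object.
#' @export
read_transducer_params <- function(path) {
  if (!file.exists(path)) abort(sprintf("params file not found: %s", path))
  obj <- jsonlite::fromJSON(path)
  transducer_params(str_chars(obj$alphabet), obj$ins, obj$sub, obj$del,
                    obj$gamma)
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized sections: `sax` (arguments of [sax_config()]), `em`
#' (`tol`, `max_iter`), `classify` (`pairs_scope`, `direction`) and
#' `seed`. Missing entries fall back to the package defaults, which match
#' the best-performing configuration (window 120, 24 symbols, 3 letters).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return List with elements `sax` (a [sax_config()]), `em`, `classify`
#'   and `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  sax_args <- raw$sax %||% list()
  sax <- do.call(sax_config, sax_args)
  em <- list(tol = raw$em$tol %||% 1e-6,
             max_iter = raw$em$max_iter %||% 100)
  classify <- list(pairs_scope = raw$classify$pairs_scope %||% "same_class",
                   direction = raw$classify$direction %||% "input_test")
  list(sax = sax, em = em, classify = classify, seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
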