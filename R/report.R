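# Report writers: deterministic TSV/JSON with 6 significant digits, each
# report stamped with the package version and a hash of the run config.

.signif_df <- function(df, digits = 6) {
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- signif(df[[nm]], digits)
  df
}

#' Stable hash of an R configuration object
#'
#' @param x any serialisable object.
#' @return md5 string.
#' @export
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # version-pinned serialisation keeps the hash stable across R versions
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Write a tabular report as TSV
#'
#' Numeric fields are printed with 6 significant digits; a comment header
#' carries the package version and config hash so identical runs produce
#' byte-identical files.
#'
#' @param df data.frame.
#' @param path output path.
#' @param config object hashed into the header (optional).
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, config = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# oleoflux %s",
                     as.character(utils::packageVersion("oleoflux"))), con)
  if (!is.null(config))
    writeLines(sprintf("# config %s", config_hash(config)), con)
  utils::write.table(.signif_df(as.data.frame(df)), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a report object as JSON
#'
#' @param x list or data.frame.
#' @param path output path.
#' @param config object hashed into the report (optional).
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path, config = NULL) {
  payload <- list(package = "oleoflux",
                  version = as.character(utils::packageVersion("oleoflux")),
                  config_hash = if (is.null(config)) NULL else
                    config_hash(config),
                  report = x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 6,
                       na = "null", pretty = TRUE)
  invisible(path)
}
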