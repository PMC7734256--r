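# Shared report writing.

#' Write a stage result to disk
#'
#' Data frames are written as CSV with a comment metadata header (package
#' version, timestamp, and the seed when supplied); list-like results
#' (goodness-of-fit results, decision records) are written as JSON with the
#' same metadata embedded.  Existing files are only replaced when
#' `overwrite = TRUE`.
#'
#' @param x A data frame, `gof_result`, `decision_record`, or plain list.
#' @param path Output path (`.csv` for tables, `.json` for lists).
#' @param seed Optional seed to record.
#' @param overwrite Replace an existing file (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, seed = NULL, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite ", path, " (use overwrite = TRUE)")
  if ((is.data.frame(x) || is.list(x)) && length(x) == 0)
    stop("refusing to write an empty result")
  meta <- list(package = "polyself",
               version = as.character(utils::packageVersion("polyself")),
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(seed)) meta$seed <- seed
  if (is.data.frame(x)) {
    if (nrow(x) == 0) stop("refusing to write an empty result")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", names(meta), ": ", unlist(meta)), con)
    utils::write.csv(x, con, row.names = FALSE)
  } else {
    payload <- list(metadata = meta, result = unclass(x))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
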