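# File plumbing: plain-text readers, wordlists, pair tables, report writers.

#' Read a plain text document
#'
#' Reads a UTF-8 `.txt` file into a [raw_text()]; CRLF line endings are
#' normalized so Windows and Unix files tokenize identically.
#'
#' @param path file path.
#' @param language ISO 639-1 code.
#' @return a `raw_text`.
#' @export
read_text <- function(path, language = "en") {
  if (!file.exists(path)) {
    cl_abort(sprintf("cannot read text file '%s'", path), "cl_file_format_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  raw_text(paste(lines, collapse = "\n"), language)
}

#' Read a wordlist file
#'
#' One lowercase word per line, UTF-8; blank lines and `#` comment lines are
#' skipped.
#' @param path file path.
#' @return character vector of words.
#' @export
read_wordlist <- function(path) {
  if (!file.exists(path)) cl_missing_resource(sprintf("wordlist '%s'", path))
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  tolower(x[nzchar(x) & !startsWith(x, "#")])
}

# Resolve a wordlist argument: character vector used as-is, a path is read,
# NULL loads the bundled default from inst/extdata.
as_wordlist <- function(x, default) {
  if (is.null(x)) {
    path <- system.file("extdata", default, package = "clinlang")
    if (!nzchar(path)) cl_missing_resource(default)
    return(read_wordlist(path))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    return(read_wordlist(x))
  }
  if (is.character(x)) return(tolower(x))
  cl_missing_resource("wordlist (expected character vector or path)")
}

#' Read a target/response pair table
#'
#' Accepts CSV, TSV, or XLSX. The table must contain the target and response
#' columns (names configurable); other columns are carried through.
#'
#' @param path file path (`.csv`, `.tsv`, or `.xlsx`).
#' @param target_col,response_col column names.
#' @return data.frame with at least `target` and `response` character columns.
#' @export
read_pairs_table <- function(path, target_col = "target",
                             response_col = "response") {
  if (!file.exists(path)) {
    cl_abort(sprintf("cannot read pairs file '%s'", path), "cl_file_format_error")
  }
  ext <- tolower(tools::file_ext(path))
  tab <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    tsv = utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    xlsx = as.data.frame(readxl::read_excel(path)),
    cl_abort(sprintf("unsupported pairs file format '.%s'", ext),
      "cl_file_format_error")
  )
  for (col in c(target_col, response_col)) {
    if (!col %in% names(tab)) {
      cl_abort(sprintf("pairs table is missing required column '%s'", col),
        "cl_schema_error")
    }
  }
  names(tab)[match(c(target_col, response_col), names(tab))] <-
    c("target", "response")
  tab$target <- as.character(tab$target)
  tab$response <- as.character(tab$response)
  tab
}

#' Write a report table
#'
#' Writes a data.frame as CSV (RFC 4180), TSV, or JSON (records orientation),
#' chosen by file extension or `format`.
#'
#' @param x data.frame.
#' @param path output path.
#' @param format `"csv"`, `"tsv"`, or `"json"`; default inferred from `path`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(format,
    csv = utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8"),
    tsv = utils::write.table(x, path, sep = "\t", row.names = FALSE,
      qmethod = "double", fileEncoding = "UTF-8"),
    json = jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
      digits = NA, na = "null"),
    cl_abort(sprintf("unsupported report format '%s'", format),
      "cl_file_format_error")
  )
  invisible(path)
}
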