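## io: plain-CSV round-tripping of trial tables and JSON/CSV reports.
## Missing cells are encoded as empty fields; decimal separator ".".

#' Write a trial table to CSV
#'
#' One header row; missing values as empty fields; UTF-8; "." decimals.
#'
#' @param table trial data frame; `path` output file.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Empty fields become missing values (never zero). Arm labels are
#' validated against the known set, naming the offending row; outcome
#' columns that fail to parse as numbers raise an error naming the column.
#'
#' @param path CSV file written by [write_trial_csv()] or matching its
#'   schema.
#' @return a validated trial data frame.
#' @export
read_trial_csv <- function(path) {
  tab <- read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8")
  assert_cols(tab, c("id", "arm", "sex", "t2d"), where = path)
  bad <- which(!is.na(tab$arm) & !tab$arm %in% ARM_LEVELS)
  if (length(bad))
    stop_config("unknown arm label '%s' at row %d of %s",
                tab$arm[bad[1]], bad[1], path)
  numish <- grep("_m0$|_m6$|_m12$|^weight_change$|^age$|^height$",
                 names(tab), value = TRUE)
  for (cl in setdiff(numish, "nafld_m0")) {
    if (is.character(tab[[cl]])) {
      v <- suppressWarnings(as.numeric(tab[[cl]]))
      if (any(is.na(v) & !is.na(tab[[cl]])))
        stop_config("non-numeric value in column '%s' of %s", cl, path)
      tab[[cl]] <- v
    }
  }
  if ("t2d" %in% names(tab) && !is.logical(tab$t2d))
    tab$t2d <- as.logical(tab$t2d)
  if ("nafld_m0" %in% names(tab) && !is.logical(tab$nafld_m0))
    tab$nafld_m0 <- as.logical(tab$nafld_m0)
  validate_trial(tab)
  tab
}

## stable hash of a configuration list (md5 of its canonical JSON)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                           digits = NA, force = TRUE)), f)
  unname(tools::md5sum(f))
}

#' Write an analysis report as JSON (and a CSV contrast summary)
#'
#' @param results a report list from [run_primary_analysis()] and friends.
#' @param path JSON output path; a sibling `<path>.csv` holds the flat
#'   contrast table when contrasts are present.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, na = "null")
  rows <- list()
  for (oc in names(results$outcomes %||% list())) {
    ct <- results$outcomes[[oc]]$contrasts
    if (is.data.frame(ct) && nrow(ct))
      rows[[oc]] <- cbind(outcome = oc, ct)
  }
  if (length(rows))
    write.csv(do.call(rbind, rows), paste0(path, ".csv"),
              row.names = FALSE)
  invisible(path)
}
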