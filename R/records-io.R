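# Tabular artifacts: the master per-spore record table, manual-override
# tables and the flat-key run configuration file.

.RECORD_COLS <- c("spore_id", "origin", "condition", "fate",
                  "centroid_y", "centroid_x",
                  "t_start_min", "germ_duration_min", "t_germ_end_min",
                  "t_division_min", "division_source",
                  "outgrowth_time_min", "generation_time_min", "fit_r",
                  "burst_times_min", "censored_at_min", "censor_reason")

.FATES <- c("outgrow", "germinate_only", "dormant", "pre_germinated",
            "excluded", "vegetative")

#' An empty spore record table
#'
#' One row per spore; columns cover every reported metric (start of
#' germination, germination time, outgrowth time, generation time), the fate
#' class, burst times and censoring.
#' @return zero-row data.frame with the record column contract.
#' @export
emptyRecords <- function() {
  df <- data.frame(
    spore_id = integer(0), origin = character(0), condition = character(0),
    fate = character(0), centroid_y = numeric(0), centroid_x = numeric(0),
    t_start_min = numeric(0), germ_duration_min = numeric(0),
    t_germ_end_min = numeric(0), t_division_min = numeric(0),
    division_source = character(0), outgrowth_time_min = numeric(0),
    generation_time_min = numeric(0), fit_r = numeric(0),
    burst_times_min = character(0), censored_at_min = numeric(0),
    censor_reason = character(0), stringsAsFactors = FALSE)
  df
}

.format_full <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v)
      if (is.na(v)) "" else sprintf("%.17g", v), character(1))
    out
  } else {
    ifelse(is.na(x), "", as.character(x))
  }
}

#' Write spore records to CSV
#'
#' Numeric columns are written with 17 significant digits so that
#' [readRecords()] restores them to full double precision
#' (`readRecords(writeRecords(x)) == x`). An empty record list yields a
#' header-only file.
#'
#' @param records data.frame with the columns of [emptyRecords()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRecords <- function(records, path) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(.RECORD_COLS, names(records))
  if (length(miss))
    stop("records missing columns: ", paste(miss, collapse = ", "))
  records <- records[, .RECORD_COLS, drop = FALSE]
  out <- as.data.frame(lapply(records, .format_full),
                       stringsAsFactors = FALSE, optional = TRUE)
  names(out) <- .RECORD_COLS
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write records to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a spore record CSV written by writeRecords
#'
#' @param path CSV path.
#' @return data.frame with the record column contract; numeric columns
#'   restored at full precision.
#' @export
readRecords <- function(path) {
  if (!file.exists(path)) stop("cannot read records file: ", path)
  tmpl <- emptyRecords()
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = setNames(
                   ifelse(vapply(tmpl, is.numeric, logical(1)),
                          "character", "character"), names(tmpl)))
  miss <- setdiff(.RECORD_COLS, names(df))
  if (length(miss))
    stop("record file missing columns: ", paste(miss, collapse = ", "))
  for (cn in .RECORD_COLS) {
    if (is.numeric(tmpl[[cn]])) {
      v <- df[[cn]]
      v[v == ""] <- NA
      df[[cn]] <- as.numeric(v)
      if (is.integer(tmpl[[cn]])) df[[cn]] <- as.integer(df[[cn]])
    } else {
      v <- as.character(df[[cn]])
      v[v == ""] <- NA
      df[[cn]] <- v
    }
  }
  df[, .RECORD_COLS, drop = FALSE]
}

#' Read a flat key-value configuration file into a RunConfig
#'
#' The accepted format is the flat-mapping subset of YAML: one `key: value`
#' per line, `#` comments and blank lines ignored. Keys are the arguments of
#' [runConfig()] (snake_case also accepted, e.g. `dark_threshold`).
#'
#' @param path configuration file.
#' @return A [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("cannot read config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE))
      stop("config line is not 'key: value': ", ln)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    # snake_case -> camelCase
    key <- gsub("_(\\w)", "\\U\\1", key, perl = TRUE)
    args[[key]] <- suppressWarnings(as.numeric(val))
    if (is.na(args[[key]]) && !val %in% c("NA", "na", ""))
      stop("config value for '", key, "' is not numeric: ", val)
  }
  unknown <- setdiff(names(args), names(formals(runConfig)))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(runConfig, args)
}

#' Read a one-id-per-line exclusion table
#'
#' @param path plain-text file with one spore id per line (`#` comments
#'   allowed).
#' @return integer vector of spore ids.
#' @export
readExclusions <- function(path) {
  if (!file.exists(path)) stop("cannot read exclusion table: ", path)
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  ids <- suppressWarnings(as.integer(lines))
  if (anyNA(ids)) stop("non-integer spore id in exclusion table: ", path)
  ids
}

#' Read a manual override table
#'
#' Used for manual first-division times (`spore_id, t_division_min`) and
#' manual fit windows (`spore_id, start_min, end_min`).
#'
#' @param path CSV with a header row.
#' @param columns required column names.
#' @return data.frame with the requested columns.
#' @export
readManualTable <- function(path, columns = c("spore_id", "t_division_min")) {
  if (!file.exists(path)) stop("cannot read manual table: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(columns, names(df))
  if (length(miss))
    stop("manual table missing columns: ", paste(miss, collapse = ", "))
  df[, columns, drop = FALSE]
}
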