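#' Read a per-cell CSV table exported from a segmentation tool
#'
#' Expects comma-separated UTF-8 with a header row. Header names are
#' normalized by trimming surrounding whitespace; unknown columns are
#' preserved untouched. Required columns: `participant_id`, `core_id`,
#' `x_um`, `y_um`, `intensity_hoechst`, `intensity_ck`, `intensity_cd8`,
#' `intensity_foxp3`. Malformed numeric cells are reported with their row
#' and column.
#'
#' @param path CSV file path.
#' @return data.frame of cell records.
#' @export
read_cell_table <- function(path) {
  df <- read_checked_csv(path,
    required = c("participant_id", "core_id", "x_um", "y_um",
                 "intensity_hoechst", "intensity_ck", "intensity_cd8",
                 "intensity_foxp3"),
    numeric_cols = c("x_um", "y_um", "intensity_hoechst", "intensity_ck",
                     "intensity_cd8", "intensity_foxp3"))
  df$participant_id <- as.character(df$participant_id)
  df$core_id <- as.character(df$core_id)
  df
}

#' Read a per-participant survival CSV (`participant_id`, `time`, `event`)
#' @param path CSV file path.
#' @return data.frame of survival records.
#' @export
read_survival_table <- function(path) {
  df <- read_checked_csv(path,
    required = c("participant_id", "time", "event"),
    numeric_cols = c("time", "event"))
  df$participant_id <- as.character(df$participant_id)
  check_survival_frame(df)
  df
}

#' Read a per-participant label CSV (`participant_id`, `label`)
#' @param path CSV file path.
#' @return data.frame of label records.
#' @export
read_labels_table <- function(path) {
  df <- read_checked_csv(path, required = c("participant_id", "label"),
                         numeric_cols = character(0))
  df$participant_id <- as.character(df$participant_id)
  df$label <- as.character(df$label)
  df
}

read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- trimws(names(df))
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("'", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in numeric_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & trimws(v) != "")
      if (length(bad)) {
        stop("non-numeric value in column '", col, "' of '", path,
             "' at data row(s) ", paste(head(bad, 5), collapse = ", "))
      }
      df[[col]] <- num
    }
    bad_na <- which(is.na(df[[col]]))
    if (length(bad_na)) {
      stop("missing value in column '", col, "' of '", path,
           "' at data row(s) ", paste(head(bad_na, 5), collapse = ", "))
    }
  }
  df
}

write_output_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}
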