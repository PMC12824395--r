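#' Write and read a registry directory of CSV tables
#'
#' Tables are written as plain CSV with one header row and ISO-8601 dates.
#' Reading validates row-level invariants (parseable dates, positive supply,
#' discharge >= admit) and fails with messages naming the file, row and
#' column of each violation.
#'
#' @param tables Named list of data frames as returned by
#'   [generate_cohort()]; any subset of `persons`, `dispensings`,
#'   `hospital_stays`, `diagnoses`, `truth`.
#' @param directory Output/input directory.
#' @return `write_registry` returns the file paths invisibly;
#'   `read_registry` returns the named list of tables.
#' @export
write_registry <- function(tables, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    path <- file.path(directory, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], path, row.names = FALSE, na = "")
    path
  }, character(1))
  invisible(paths)
}

.date_cols <- c("birth_date", "diagnosis_date", "death_date",
                "residency_start", "residency_end", "dispense_date",
                "admit_date", "discharge_date", "date")

#' @rdname write_registry
#' @export
read_registry <- function(directory) {
  files <- list.files(directory, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no CSV tables found in ", directory)
  tables <- lapply(files, function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    for (col in intersect(names(df), .date_cols)) {
      raw <- df[[col]]
      parsed <- as.Date(raw, format = "%Y-%m-%d")
      bad <- which(!is.na(raw) & nzchar(raw) & is.na(parsed))
      if (length(bad))
        stop("malformed date in ", basename(path), ", column '", col,
             "', row(s) ", paste(utils::head(bad, 5), collapse = ", "))
      df[[col]] <- parsed
    }
    if ("days_supply" %in% names(df)) {
      df$days_supply <- as.integer(df$days_supply)
      bad <- which(is.na(df$days_supply) | df$days_supply < 1)
      if (length(bad))
        stop("days_supply must be a positive integer in ", basename(path),
             ", row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    }
    if (all(c("admit_date", "discharge_date") %in% names(df))) {
      bad <- which(df$discharge_date < df$admit_date)
      if (length(bad))
        stop("discharge_date earlier than admit_date in ", basename(path),
             ", row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    }
    if (all(c("death_date", "diagnosis_date") %in% names(df))) {
      bad <- which(!is.na(df$death_date) &
                     df$death_date < df$diagnosis_date)
      if (length(bad))
        stop("death_date earlier than diagnosis_date in ", basename(path),
             ", row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    }
    for (col in intersect(names(df), c("weight"))) {
      df[[col]] <- as.numeric(df[[col]])
    }
    for (col in intersect(names(df),
                          c("living_with_partner", "prior_depression",
                            "adhd", "substance_use", "neurotic",
                            "obesity_diabetes", "prior_sickness_absence",
                            "disability_pension"))) {
      df[[col]] <- as.integer(df[[col]])
    }
    df
  })
  names(tables) <- sub("\\.csv$", "", basename(files))
  tables
}
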