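#' Twelve-period follow-up grid
#'
#' Follow-up is divided into twelve consecutive 91-day periods starting at
#' the diagnosis date (day 0), spanning 1092 days in total. Intervals are
#' half-open in days: period k covers days `[91*(k-1), 91*k)` from diagnosis.
#'
#' @param diagnosis_date Date of incident diagnosis.
#' @param n_periods,period_days Grid dimensions; defaults 12 x 91 days.
#' @return Data frame with `period`, `start` (Date, inclusive) and
#'   `end` (Date, exclusive).
#' @export
build_period_grid <- function(diagnosis_date, n_periods = 12,
                              period_days = 91) {
  stopifnot(inherits(diagnosis_date, "Date"), length(diagnosis_date) == 1,
            !is.na(diagnosis_date))
  k <- seq_len(n_periods)
  data.frame(period = k,
             start = diagnosis_date + period_days * (k - 1),
             end = diagnosis_date + period_days * k)
}

#' Binarize one follow-up period into four medication indicators
#'
#' Inpatient days are subtracted from the period denominator (hospital
#' medication is not captured by dispensing data). With `D` non-hospital days
#' in the 91-day period, a class indicator is positive when the class's use
#' periods cover at least 50% of those `D` days. A period with >= 50% of its
#' days (>= 46 of 91) spent in hospital is not assessable (`valid = FALSE`).
#'
#' @param use_periods Use periods for one person (see [build_use_periods()]).
#' @param period One row of [build_period_grid()] (fields `start`, `end`).
#' @param hospital_stays Data frame with `admit_date`, `discharge_date`
#'   (inclusive) for the same person; may be empty.
#' @return List with `indicators` (named 0/1 vector over the four classes),
#'   `valid` flag, and `inpatient_days`.
#' @export
binarize_period <- function(use_periods, period, hospital_stays = NULL) {
  p1 <- as.numeric(period$start)
  p2 <- as.numeric(period$end)
  len <- p2 - p1
  # union of inpatient days within the period
  hosp_days <- rep(FALSE, len)
  if (!is.null(hospital_stays) && nrow(hospital_stays)) {
    for (i in seq_len(nrow(hospital_stays))) {
      a <- max(p1, as.numeric(hospital_stays$admit_date[i]))
      b <- min(p2 - 1, as.numeric(hospital_stays$discharge_date[i]))
      if (b >= a) hosp_days[(a - p1 + 1):(b - p1 + 1)] <- TRUE
    }
  }
  n_hosp <- sum(hosp_days)
  if (n_hosp >= ceiling(len / 2)) {
    ind <- setNames(rep(NA_real_, length(medseq_classes)), medseq_classes)
    return(list(indicators = ind, valid = FALSE, inpatient_days = n_hosp))
  }
  D <- len - n_hosp
  ind <- setNames(numeric(length(medseq_classes)), medseq_classes)
  if (!is.null(use_periods) && nrow(use_periods)) {
    for (cl in medseq_classes) {
      up <- use_periods[use_periods$drug_class == cl, , drop = FALSE]
      if (!nrow(up)) next
      cov_days <- rep(FALSE, len)
      for (i in seq_len(nrow(up))) {
        a <- max(p1, as.numeric(up$start_date[i]))
        b <- min(p2 - 1, as.numeric(up$end_date[i]))
        if (b >= a) cov_days[(a - p1 + 1):(b - p1 + 1)] <- TRUE
      }
      ind[cl] <- as.numeric(sum(cov_days & !hosp_days) >= 0.5 * D)
    }
  }
  list(indicators = ind, valid = TRUE, inpatient_days = n_hosp)
}

#' Build a person's 12-period treatment-state sequence
#'
#' Applies, in order: per-period binarization and the state decision tree;
#' death censoring (every period from the period containing the death date
#' onward becomes `CENSORED`); substitution of non-assessable periods by the
#' following period's resolved state (right-to-left, so chains resolve; a
#' non-assessable period 12 takes period 11's resolved state; a successor of
#' `CENSORED` makes the period `CENSORED`). Two or more *consecutive*
#' non-assessable periods, or censoring already at period 1, exclude the
#' person.
#'
#' @param person One-row data frame with `person_id`, `diagnosis_date` and
#'   optional `death_date` (NA if alive).
#' @param use_periods,hospital_stays Tables for this person.
#' @return List with `states` (length-12 character vector) and `exclusion`
#'   (`NA`, `"consecutive_inpatient"` or `"censored_first_period"`); when an
#'   exclusion applies `states` is `NULL`.
#' @export
build_sequence <- function(person, use_periods, hospital_stays = NULL) {
  grid <- build_period_grid(person$diagnosis_date)
  n <- nrow(grid)
  raw <- character(n)
  valid <- logical(n)
  for (k in seq_len(n)) {
    b <- binarize_period(use_periods, grid[k, ], hospital_stays)
    valid[k] <- b$valid
    raw[k] <- if (b$valid)
      assign_state(b$indicators["antidepressant"],
                   b$indicators["anticonvulsant_ms"],
                   b$indicators["antipsychotic"],
                   b$indicators["lithium"])
    else NA_character_
  }
  # death censoring from the period containing the death date
  death <- person$death_date
  if (!is.null(death) && length(death) == 1 && !is.na(death)) {
    dd <- as.numeric(death) - as.numeric(person$diagnosis_date)
    if (dd < 1092) {
      k0 <- max(1L, dd %/% 91 + 1L)
      raw[k0:n] <- "CENSORED"
      valid[k0:n] <- TRUE
    }
  }
  if (any(diff(which(!valid)) == 1))
    return(list(states = NULL, exclusion = "consecutive_inpatient"))
  # right-to-left substitution of non-assessable periods
  states <- raw
  if (!valid[n]) {
    states[n] <- states[n - 1]
    if (is.na(states[n]))  # periods 11 and 12 both invalid: caught above
      stop("unresolvable trailing non-assessable period")
  }
  for (k in rev(seq_len(n - 1))) {
    if (!valid[k]) states[k] <- states[k + 1]
  }
  if (states[1] == "CENSORED")
    return(list(states = NULL, exclusion = "censored_first_period"))
  list(states = states, exclusion = NA_character_)
}

#' Build state sequences for a cohort
#'
#' Vectorized driver over persons; emits the sequence table and a log of
#' sequence-stage exclusions.
#'
#' @param persons Data frame with `person_id`, `diagnosis_date`,
#'   optional `death_date`.
#' @param use_periods Output of [build_use_periods()] (all persons).
#' @param hospital_stays Hospital stay table (all persons); may be `NULL`.
#' @return List with `sequences` (data frame: `person_id`, `s1`..`s12`,
#'   `weight`) and `exclusions` (data frame: `person_id`, `reason`).
#' @export
build_sequences <- function(persons, use_periods, hospital_stays = NULL) {
  up_split <- if (nrow(use_periods))
    split(use_periods, use_periods$person_id) else list()
  hs_split <- if (!is.null(hospital_stays) && nrow(hospital_stays))
    split(hospital_stays, hospital_stays$person_id) else list()
  none_up <- data.frame(person_id = character(), drug_class = character(),
                        start_date = as.Date(character()),
                        end_date = as.Date(character()))
  seqs <- vector("list", nrow(persons))
  excl <- character(nrow(persons))
  for (i in seq_len(nrow(persons))) {
    pid <- persons$person_id[i]
    res <- build_sequence(persons[i, , drop = FALSE],
                          up_split[[pid]] %||% none_up,
                          hs_split[[pid]])
    seqs[[i]] <- res$states
    excl[i] <- res$exclusion
  }
  keep <- is.na(excl)
  states <- do.call(rbind, seqs[keep])
  sequences <- data.frame(person_id = persons$person_id[keep],
                          stringsAsFactors = FALSE)
  if (!is.null(states)) {
    colnames(states) <- paste0("s", seq_len(ncol(states)))
    sequences <- cbind(sequences, as.data.frame(states,
                                                stringsAsFactors = FALSE))
  }
  sequences$weight <- 1
  list(sequences = sequences,
       exclusions = data.frame(person_id = persons$person_id[!keep],
                               reason = excl[!keep],
                               stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the state matrix from a sequence table
#' @param sequences Data frame with columns `s1`..`s12`.
#' @return Character matrix, one row per sequence.
#' @export
sequence_matrix <- function(sequences) {
  cols <- grep("^s[0-9]+$", names(sequences), value = TRUE)
  m <- as.matrix(sequences[, cols, drop = FALSE])
  rownames(m) <- sequences$person_id
  m
}
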