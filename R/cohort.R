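#' Apply cohort eligibility rules
#'
#' Evaluates, per person, the incidence and data-quality filters in a fixed
#' order, recording every triggered reason (not just the first):
#'
#' 1. `prior_bd` — any F30/F31 diagnosis in the 3 years (1095 days) before
#'    the index date (exclusive).
#' 2. `washout_medication` — any antipsychotic, anticonvulsant
#'    mood-stabilizer or lithium use period overlapping the window from 455
#'    to 91 days before diagnosis (i.e. 15 until 3 months). Antidepressant
#'    use does not trigger washout.
#' 3. `psychosis_dementia` — any F2x, F00–F03 or G30 code from 3 years
#'    before diagnosis through the end of follow-up (1092 days, or death).
#' 4. `residency` — residency interval not covering the 3 years before
#'    diagnosis through the full follow-up (or until death).
#' 5. `age` — age at diagnosis outside 16–65 (completed years).
#'
#' Sequence-stage exclusions (`censored_first_period`,
#' `consecutive_inpatient`) are appended later by [build_sequences()] /
#' [run_pipeline()].
#'
#' @param persons Data frame with `person_id`, `birth_date`,
#'   `diagnosis_date`, optional `death_date`, `residency_start`,
#'   `residency_end`.
#' @param diagnoses Data frame with `person_id`, `icd10_code`, `date`. The
#'   index diagnosis itself (on the diagnosis date) does not count as a
#'   prior diagnosis.
#' @param use_periods Output of [build_use_periods()].
#' @return Data frame with `person_id`, `included`, and `exclusion_reasons`
#'   (`;`-separated, `""` when included).
#' @export
apply_eligibility <- function(persons, diagnoses, use_periods) {
  if (anyNA(persons$diagnosis_date))
    stop("missing diagnosis_date for person(s): ",
         paste(utils::head(persons$person_id[is.na(persons$diagnosis_date)],
                           5), collapse = ", "))
  n <- nrow(persons)
  dx <- as.numeric(persons$diagnosis_date)
  death <- if ("death_date" %in% names(persons))
    as.numeric(persons$death_date) else rep(NA_real_, n)
  fu_end <- ifelse(is.na(death), dx + 1092, pmin(dx + 1092, death))

  dg_split <- if (nrow(diagnoses)) split(diagnoses, diagnoses$person_id)
              else list()
  washout_classes <- c("antipsychotic", "anticonvulsant_ms", "lithium")
  up <- use_periods[use_periods$drug_class %in% washout_classes, ,
                    drop = FALSE]
  up_split <- if (nrow(up)) split(up, up$person_id) else list()

  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- persons$person_id[i]
    r <- character(0)
    dg <- dg_split[[pid]]
    if (!is.null(dg)) {
      dgd <- as.numeric(dg$date)
      bd <- grepl("^F3[01]", dg$icd10_code) &
        dgd >= dx[i] - 1095 & dgd < dx[i]
      if (any(bd)) r <- c(r, "prior_bd")
    }
    u <- up_split[[pid]]
    if (!is.null(u)) {
      w1 <- dx[i] - 455; w2 <- dx[i] - 91
      hit <- as.numeric(u$start_date) <= w2 & as.numeric(u$end_date) >= w1
      if (any(hit)) r <- c(r, "washout_medication")
    }
    if (!is.null(dg)) {
      dgd <- as.numeric(dg$date)
      psy <- grepl("^(F2|F0[0-3]|G30)", dg$icd10_code) &
        dgd >= dx[i] - 1095 & dgd <= fu_end[i]
      if (any(psy)) r <- c(r, "psychosis_dementia")
    }
    rs <- persons$residency_start[i]
    re <- persons$residency_end[i]
    if (is.na(rs) || is.na(re) ||
        as.numeric(rs) > dx[i] - 1095 || as.numeric(re) < fu_end[i])
      r <- c(r, "residency")
    age <- floor((dx[i] - as.numeric(persons$birth_date[i])) / 365.25)
    if (is.na(age) || age < 16 || age > 65) r <- c(r, "age")
    reasons[[i]] <- r
  }
  data.frame(person_id = persons$person_id,
             included = lengths(reasons) == 0,
             exclusion_reasons = vapply(reasons, paste, character(1),
                                        collapse = ";"),
             stringsAsFactors = FALSE)
}
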