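#' Dichotomize a state sequence into treatment / no treatment
#'
#' `LACK` maps to 0, any of the six treatment states to 1, and `CENSORED`
#' to `NA`, ending the evaluable window.
#'
#' @param sequence Character vector of states.
#' @return Integer vector of 0/1 with `NA` for censored periods.
#' @export
dichotomize <- function(sequence) {
  out <- ifelse(sequence == "CENSORED", NA_integer_,
                as.integer(sequence != "LACK"))
  out
}

#' Classify treatment initiation timing
#'
#' The first treated period determines the class: period 1 is early
#' initiation (within 3 months of diagnosis); periods 2–4 delayed initiation
#' within 4–12 months; periods 5–12 delayed by a year or more; no treated
#' period means never initiated. Antidepressant monotherapy already ongoing
#' at diagnosis and continuing into period 1 also counts as early.
#'
#' @param binary_seq Output of [dichotomize()].
#' @param pre_dx_ad_monotherapy Flag: antidepressant monotherapy overlapping
#'   the diagnosis date and continuing (period 1 treated).
#' @return One of `"early_0_3m"`, `"delayed_4_12m"`, `"delayed_ge12m"`,
#'   `"never"`.
#' @export
classify_initiation <- function(binary_seq, pre_dx_ad_monotherapy = FALSE) {
  ev <- binary_seq[!is.na(binary_seq)]
  t <- which(ev == 1)[1]
  if (isTRUE(pre_dx_ad_monotherapy) && length(ev) >= 1 && ev[1] == 1)
    return("early_0_3m")
  if (is.na(t)) return("never")
  if (t == 1) "early_0_3m"
  else if (t <= 4) "delayed_4_12m"
  else "delayed_ge12m"
}

#' Classify time to treatment discontinuation
#'
#' Discontinuation is the first transition from treatment to lack of
#' treatment after initiation. With initiation at period `t` and the first
#' post-initiation untreated period at `u`, the gap `g = u - t` is binned:
#' `g <= 2` within 6 months, `g` of 3–4 within 1 year, 5–8 within 2 years,
#' `>= 9` after 2 years. No such transition (or never initiated) is
#' `"none"`.
#'
#' @param binary_seq Output of [dichotomize()].
#' @return One of `"none"`, `"within_6m"`, `"within_1y"`, `"within_2y"`,
#'   `"after_2y"`.
#' @export
classify_discontinuation <- function(binary_seq) {
  ev <- binary_seq[!is.na(binary_seq)]
  t <- which(ev == 1)[1]
  if (is.na(t)) return("none")
  after <- ev[-seq_len(t)]
  u_rel <- which(after == 0)[1]
  if (is.na(u_rel)) return("none")
  g <- u_rel  # u - t
  if (g <= 2) "within_6m"
  else if (g <= 4) "within_1y"
  else if (g <= 8) "within_2y"
  else "after_2y"
}

#' Classify the overall treatment trajectory
#'
#' Cross of initiation timing (early vs delayed, pooling both delayed
#' classes) and discontinuation (any vs none), plus continuous lack of
#' treatment for never-initiators.
#'
#' @param initiation_class From [classify_initiation()].
#' @param discontinuation_class From [classify_discontinuation()].
#' @return One of `"early_no_disc"`, `"early_disc"`, `"delayed_no_disc"`,
#'   `"delayed_disc"`, `"continuous_lack"`.
#' @export
classify_trajectory <- function(initiation_class, discontinuation_class) {
  if (initiation_class == "never") return("continuous_lack")
  early <- initiation_class == "early_0_3m"
  disc <- discontinuation_class != "none"
  if (early && !disc) "early_no_disc"
  else if (early && disc) "early_disc"
  else if (!early && !disc) "delayed_no_disc"
  else "delayed_disc"
}

#' Build per-person trajectory records
#'
#' @param sequences Sequence table (`person_id`, `s1..s12`).
#' @param pre_dx_ad_mono Logical vector (or named by person_id) flagging
#'   pre-diagnosis antidepressant monotherapy continuing into follow-up;
#'   default all `FALSE`.
#' @return Data frame with `person_id`, `initiated`, `initiation_class`,
#'   `discontinued`, `discontinuation_class`, `trajectory`.
#' @export
classify_trajectories <- function(sequences, pre_dx_ad_mono = NULL) {
  m <- sequence_matrix(sequences)
  n <- nrow(m)
  if (is.null(pre_dx_ad_mono)) pre_dx_ad_mono <- rep(FALSE, n)
  init <- character(n); disc <- character(n); traj <- character(n)
  for (i in seq_len(n)) {
    b <- dichotomize(m[i, ])
    init[i] <- classify_initiation(b, pre_dx_ad_mono[i])
    disc[i] <- classify_discontinuation(b)
    traj[i] <- classify_trajectory(init[i], disc[i])
  }
  data.frame(person_id = sequences$person_id,
             initiated = init != "never",
             initiation_class = init,
             discontinued = disc != "none",
             discontinuation_class = disc,
             trajectory = traj,
             stringsAsFactors = FALSE)
}

#' Flag pre-diagnosis antidepressant monotherapy
#'
#' True when an antidepressant use period overlaps the diagnosis date while
#' no adequate-treatment class (mood-stabilizer, antipsychotic, lithium)
#' does.
#'
#' @param persons Persons table with `person_id`, `diagnosis_date`.
#' @param use_periods Output of [build_use_periods()].
#' @return Logical vector aligned with `persons`.
#' @export
pre_diagnosis_ad_monotherapy <- function(persons, use_periods) {
  vapply(seq_len(nrow(persons)), function(i) {
    dxd <- persons$diagnosis_date[i]
    u <- use_periods[use_periods$person_id == persons$person_id[i] &
                       use_periods$start_date <= dxd &
                       use_periods$end_date >= dxd, , drop = FALSE]
    any(u$drug_class == "antidepressant") &&
      !any(u$drug_class %in% c("anticonvulsant_ms", "antipsychotic",
                               "lithium"))
  }, logical(1))
}

#' Summarize trajectories into the descriptive table layout
#'
#' Produces the initiation/discontinuation summary by population group:
#' initiation yes/no over all persons; time to initiation among initiators;
#' discontinuation yes/no among persons initiating within one year
#' (initiation classes early and delayed 4–12 months); time to
#' discontinuation among those who discontinue; and the five-trajectory
#' cross over all persons. Percentages are computed per group against each
#' section's denominator and rounded half-up to one decimal.
#'
#' @param records Output of [classify_trajectories()].
#' @param groups Population-group label per record.
#' @return Data frame with `section`, `row`, `group`, `n`, `denominator`,
#'   `percent`.
#' @export
summarize_trajectories <- function(records, groups) {
  groups <- as.character(groups)
  glev <- unique(groups)
  rows <- list()
  add <- function(section, row, mask, denom_mask) {
    for (g in glev) {
      den <- sum(denom_mask & groups == g)
      cnt <- sum(mask & groups == g)
      rows[[length(rows) + 1L]] <<- data.frame(
        section = section, row = row, group = g, n = cnt,
        denominator = den,
        percent = if (den > 0) round_half_up(100 * cnt / den, 1)
                  else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  all_mask <- rep(TRUE, nrow(records))
  add("initiation", "yes", records$initiated, all_mask)
  add("initiation", "no", !records$initiated, all_mask)
  for (cl in c("early_0_3m", "delayed_4_12m", "delayed_ge12m"))
    add("time_to_initiation", cl, records$initiation_class == cl,
        records$initiated)
  within1y <- records$initiation_class %in% c("early_0_3m", "delayed_4_12m")
  add("discontinuation", "no", within1y & !records$discontinued, within1y)
  add("discontinuation", "yes", within1y & records$discontinued, within1y)
  disc1y <- within1y & records$discontinued
  for (cl in c("within_6m", "within_1y", "within_2y", "after_2y"))
    add("time_to_discontinuation", cl,
        disc1y & records$discontinuation_class == cl, disc1y)
  for (tr in c("early_no_disc", "early_disc", "delayed_no_disc",
               "delayed_disc", "continuous_lack"))
    add("trajectory", tr, records$trajectory == tr, all_mask)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round half away from zero
#'
#' Matches the conventional table style where e.g. 0.25 rounds to 0.3 at one
#' decimal (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
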