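#' Default typology archetype sequences
#'
#' Seven reference 12-period sequences, one per typology: *treatment
#' failure* is two periods of mood-stabilizers followed by ten periods
#' without treatment (initiation then discontinuation); the six others are
#' constant sequences of their defining state.
#'
#' @return 7 x 12 character matrix with typology names as row names.
#' @export
default_archetypes <- function() {
  a <- rbind(
    treatment_failure = c(rep("MOOD_STAB", 2), rep("LACK", 10)),
    persistent_ad_mono = rep("AD_MONO", 12),
    persistent_mood_stab = rep("MOOD_STAB", 12),
    persistent_antipsych = rep("ANTIPSYCH", 12),
    persistent_lithium = rep("LITHIUM", 12),
    persistent_augment = rep("AUGMENT", 12),
    persistent_li_augment = rep("LI_AUGMENT", 12)
  )
  colnames(a) <- paste0("s", 1:12)
  a
}

#' Default covariate -> typology log-odds shifts
#'
#' Named list mapping factor levels to length-7 log-odds vectors over the
#' typologies (order of [default_archetypes()]); reference levels carry zero
#' vectors and are omitted. Defaults qualitatively emulate the study system:
#' immigrant groups (especially refugees) shifted toward treatment failure
#' and away from mood-stabilizers/lithium; low education toward treatment
#' failure; high education, partner and prior depression toward
#' mood-stabilizers/lithium; ADHD and substance use toward treatment
#' failure; neurotic disorders and disability pension toward antidepressant
#' monotherapy; obesity/diabetes toward mood-stabilizers.
#'
#' @return Named list of 7-vectors.
#' @export
default_typology_coefficients <- function() {
  v <- function(...) {
    x <- c(...)
    stopifnot(length(x) == 7)
    x
  }
  # order: tf, ad_mono, mood_stab, antipsych, lithium, augment, li_augment
  list(
    "population_group=second_gen"  = v(0.45, 0, 0, 0, 0, 0, 0),
    "population_group=non_refugee" = v(0.50, 0.1, -0.2, 0, 0, 0, 0),
    "population_group=refugee"     = v(0.85, 0.1, -0.6, 0, -0.3, 0, 0),
    "education=low"                = v(0.40, 0, -0.1, 0, -0.2, 0, 0),
    "education=high"               = v(-0.30, 0, 0.15, 0, 0.25, 0, 0),
    "living_with_partner=1"        = v(-0.25, 0, 0.10, 0, 0.20, 0, 0),
    "prior_depression=1"           = v(-0.15, 0.25, 0.10, 0, 0.10, 0, 0),
    "adhd=1"                       = v(0.35, 0.1, 0, 0, 0, 0, 0),
    "substance_use=1"              = v(0.30, 0, 0, 0.15, 0, 0, 0),
    "neurotic=1"                   = v(0.10, 0.35, 0, 0, 0, 0, 0),
    "obesity_diabetes=1"           = v(0, 0.15, 0.30, 0, 0, 0, 0),
    "disability_pension=1"         = v(0, 0.40, 0, 0.1, 0, 0, 0)
  )
}

#' Generator configuration
#'
#' Bundles all knobs of the synthetic registry generator. Defaults emulate
#' the structure of a national incident-bipolar-disorder register cohort:
#' four population groups at proportions 82.8 / 7.6 / 5.9 / 3.6%,
#' seven latent medication-use typologies whose membership depends on
#' covariates through a multinomial logit, per-period state noise, and
#' hospitalization/death events exercising the censoring rules.
#'
#' @param n_persons Cohort size.
#' @param group_proportions Length-4 simplex over
#'   `swedish_born, second_gen, non_refugee, refugee`.
#' @param archetypes 7 x 12 state matrix; see [default_archetypes()].
#' @param typology_intercepts Baseline log-odds (length 7); default zero.
#' @param typology_coefficients Named list of factor-level log-odds shifts;
#'   see [default_typology_coefficients()].
#' @param state_noise_prob Per-period probability that the latent state is
#'   replaced by a uniformly random different treatment state.
#' @param hospitalization_rate Probability that a person has one inpatient
#'   stay during follow-up.
#' @param death_rate Probability of death, uniform over follow-up.
#' @param seed Integer RNG seed.
#' @return Object of class `medseq_genconfig`.
#' @export
generator_config <- function(n_persons,
                             group_proportions = c(swedish_born = 20361,
                                                   second_gen = 1867,
                                                   non_refugee = 1462,
                                                   refugee = 888) / 24578,
                             archetypes = default_archetypes(),
                             typology_intercepts = rep(0, 7),
                             typology_coefficients =
                               default_typology_coefficients(),
                             state_noise_prob = 0.05,
                             hospitalization_rate = 0.05,
                             death_rate = 0.01,
                             seed = 1L) {
  if (n_persons < 1) stop("n_persons must be >= 1")
  if (abs(sum(group_proportions) - 1) > 1e-9)
    stop("group_proportions must sum to 1")
  if (length(group_proportions) != 4)
    stop("group_proportions must have 4 entries")
  stopifnot(nrow(archetypes) == 7, ncol(archetypes) == 12,
            all(archetypes %in% medseq_states),
            state_noise_prob >= 0, state_noise_prob <= 1,
            hospitalization_rate >= 0, hospitalization_rate <= 1,
            death_rate >= 0, death_rate <= 1)
  structure(list(n_persons = as.integer(n_persons),
                 group_proportions = group_proportions,
                 archetypes = archetypes,
                 typology_intercepts = typology_intercepts,
                 typology_coefficients = typology_coefficients,
                 state_noise_prob = state_noise_prob,
                 hospitalization_rate = hospitalization_rate,
                 death_rate = death_rate,
                 seed = as.integer(seed)),
            class = "medseq_genconfig")
}

.population_groups <- c("swedish_born", "second_gen", "non_refugee",
                        "refugee")

# ATC codes used when emitting dispensings, one representative per class
.emit_atc <- c(antidepressant = "N06AB04", anticonvulsant_ms = "N03AX09",
               lithium = "N05AN01", antipsychotic = "N05AH04")

# classes a state implies (what must be dispensed to reproduce it)
.state_classes <- list(
  LACK = character(0),
  AD_MONO = "antidepressant",
  MOOD_STAB = "anticonvulsant_ms",
  ANTIPSYCH = "antipsychotic",
  LITHIUM = "lithium",
  AUGMENT = c("anticonvulsant_ms", "antipsychotic"),
  LI_AUGMENT = c("lithium", "anticonvulsant_ms")
)

#' Generate a synthetic registry cohort
#'
#' Draws persons (population group, covariates, diagnosis date within
#' 2006-07-01..2015-12-31, age 16-65), assigns each a latent typology from a
#' multinomial logit over their covariates, perturbs the typology's
#' archetype sequence with per-period noise, and emits dispensing records
#' that reconstruct the latent sequence through the exposure and sequence
#' modules (each use period receives a dispensing of a class-appropriate ATC
#' code covering the full 91 days). Hospital stays and deaths are injected
#' at the configured rates. A diagnosis table carrying the incident ICD-10
#' code is emitted for the eligibility stage.
#'
#' @param config A `medseq_genconfig` from [generator_config()].
#' @return List of data frames: `persons`, `dispensings`, `hospital_stays`,
#'   `diagnoses`, `truth` (person level latent typology and sequence).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "medseq_genconfig"))
  set.seed(config$seed)
  n <- config$n_persons
  pid <- sprintf("P%06d", seq_len(n))
  group <- sample(.population_groups, n, replace = TRUE,
                  prob = config$group_proportions)
  dx <- as.Date("2006-07-01") +
    sample.int(as.integer(as.Date("2015-12-31") - as.Date("2006-07-01")) + 1L,
               n, replace = TRUE) - 1L
  age <- sample(16:65, n, replace = TRUE)
  birth <- dx - round(age * 365.25)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  education <- sample(c("low", "medium", "high"), n, replace = TRUE,
                      prob = c(0.25, 0.45, 0.30))
  bin <- function(p) as.integer(stats::runif(n) < p)
  covars <- data.frame(
    education = education,
    living_with_partner = bin(0.50),
    prior_depression = bin(0.55),
    adhd = bin(0.10),
    substance_use = bin(0.15),
    neurotic = bin(0.20),
    obesity_diabetes = bin(0.10),
    prior_sickness_absence = bin(0.30),
    disability_pension = bin(0.10),
    stringsAsFactors = FALSE
  )

  # latent typology via multinomial logit over covariates
  eta <- matrix(rep(config$typology_intercepts, each = n), nrow = n)
  level_of <- function(spec) {
    parts <- strsplit(spec, "=", fixed = TRUE)[[1]]
    var <- parts[1]; lev <- parts[2]
    vals <- if (var == "population_group") group else covars[[var]]
    if (is.null(vals)) stop("unknown factor in coefficients: ", var)
    as.character(vals) == lev
  }
  for (spec in names(config$typology_coefficients)) {
    hit <- level_of(spec)
    if (!any(hit)) next
    eta[hit, ] <- eta[hit, , drop = FALSE] +
      matrix(rep(config$typology_coefficients[[spec]], each = sum(hit)),
             nrow = sum(hit))
  }
  pr <- exp(eta - apply(eta, 1, max))
  pr <- pr / rowSums(pr)
  typology <- vapply(seq_len(n), function(i)
    sample.int(7L, 1L, prob = pr[i, ]), integer(1))

  # latent sequence: archetype + per-period noise
  states <- config$archetypes[typology, , drop = FALSE]
  if (config$state_noise_prob > 0) {
    flip <- matrix(stats::runif(n * 12) < config$state_noise_prob, n, 12)
    if (any(flip)) {
      idx <- which(flip)
      cur <- states[idx]
      states[idx] <- vapply(cur, function(s)
        sample(setdiff(medseq_states, s), 1L), character(1))
    }
  }
  rownames(states) <- NULL

  # deaths: uniform over follow-up
  death <- as.Date(rep(NA, n))
  dies <- stats::runif(n) < config$death_rate
  death[dies] <- dx[dies] + sample.int(1092L, sum(dies), replace = TRUE) - 1L

  # hospital stays: one stay of 10-70 days starting uniformly in follow-up
  stays_at <- which(stats::runif(n) < config$hospitalization_rate)
  hospital_stays <- if (length(stays_at)) {
    start <- dx[stays_at] + sample.int(1092L, length(stays_at),
                                       replace = TRUE) - 1L
    dur <- sample(10:70, length(stays_at), replace = TRUE)
    data.frame(person_id = pid[stays_at], admit_date = start,
               discharge_date = start + dur - 1,
               stringsAsFactors = FALSE)
  } else {
    data.frame(person_id = character(), admit_date = as.Date(character()),
               discharge_date = as.Date(character()))
  }

  # dispensings reproducing the latent sequence: for every use period, one
  # dispensing per implied class at the period start, 91-day supply
  disp <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- list()
    for (k in 1:12) {
      classes <- .state_classes[[states[i, k]]]
      for (cl in classes) {
        rows[[length(rows) + 1L]] <-
          data.frame(person_id = pid[i], atc_code = unname(.emit_atc[cl]),
                     dispense_date = dx[i] + 91L * (k - 1L),
                     days_supply = 91L, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) disp[[i]] <- do.call(rbind, rows)
  }
  dispensings <- do.call(rbind, disp[!vapply(disp, is.null, logical(1))])
  if (is.null(dispensings))
    dispensings <- data.frame(person_id = character(),
                              atc_code = character(),
                              dispense_date = as.Date(character()),
                              days_supply = integer())
  rownames(dispensings) <- NULL

  persons <- data.frame(person_id = pid, birth_date = birth, sex = sex,
                        population_group = group,
                        diagnosis_date = dx, death_date = death,
                        residency_start = dx - 1095L,
                        residency_end = ifelse(is.na(death), dx + 1092L,
                                               pmin(dx + 1092L, death)),
                        stringsAsFactors = FALSE)
  persons$residency_end <- as.Date(persons$residency_end,
                                   origin = "1970-01-01")
  persons <- cbind(persons, covars)

  diagnoses <- data.frame(person_id = pid, icd10_code = "F31",
                          date = dx, setting = "specialized",
                          stringsAsFactors = FALSE)

  truth <- data.frame(person_id = pid,
                      typology = rownames(config$archetypes)[typology],
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(states, stringsAsFactors = FALSE))
  names(truth)[-(1:2)] <- paste0("s", 1:12)

  list(persons = persons, dispensings = dispensings,
       hospital_stays = hospital_stays, diagnoses = diagnoses,
       truth = truth)
}
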