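#' Pipeline configuration
#'
#' @param input Either a `medseq_genconfig` (synthetic cohort is generated)
#'   or a directory of registry CSV files for [read_registry()].
#' @param out_dir Output directory for CSV artifacts (`NULL` = don't write).
#' @param atc_map ATC class map.
#' @param grace_days,window Exposure-model parameters.
#' @param cval,indel Substitution/indel cost parameters.
#' @param k_range Candidate cluster counts.
#' @param methods Clustering methods to fit.
#' @param entropy_norm_size Alphabet size for entropy normalization.
#' @param adjusted Fit the covariate-adjusted multinomial model in addition
#'   to the univariate population-group model.
#' @return Object of class `medseq_config`.
#' @export
pipeline_config <- function(input, out_dir = NULL,
                            atc_map = default_atc_map(),
                            grace_days = 30, window = 3,
                            cval = 2, indel = cval / 2,
                            k_range = 2:15,
                            methods = c("pam", "ward_then_pam", "ward"),
                            entropy_norm_size = length(medseq_alphabet),
                            adjusted = TRUE) {
  validate_atc_map(atc_map)
  stopifnot(grace_days >= 0, window >= 1, cval > 0, indel > 0,
            all(k_range >= 2))
  structure(as.list(environment()), class = "medseq_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate/ingest, exposure modelling, eligibility,
#' sequence construction, sequence statistics (transition rates, entropies,
#' mean time in state), dissimilarity + clustering with silhouette-based
#' selection, trajectory classification, and multinomial association
#' models. When `config$out_dir` is set, every stage's table is persisted
#' as CSV together with a JSON manifest (package version, config hash,
#' seed).
#'
#' @param config A `medseq_config` from [pipeline_config()].
#' @return List with all stage outputs (see details in the vignette).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "medseq_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tables <- stage("ingest", {
    if (inherits(config$input, "medseq_genconfig")) {
      generate_cohort(config$input)
    } else {
      read_registry(config$input)
    }
  })
  for (nm in c("persons", "dispensings"))
    if (is.null(tables[[nm]]))
      stop("pipeline stage 'ingest' failed: missing table '", nm, "'")

  use_periods <- stage("exposure",
    build_use_periods(tables$dispensings, config$atc_map,
                      grace_days = config$grace_days,
                      window = config$window))

  eligibility <- stage("cohort",
    apply_eligibility(tables$persons, tables$diagnoses %||%
                        data.frame(person_id = character(),
                                   icd10_code = character(),
                                   date = as.Date(character())),
                      use_periods))
  persons <- tables$persons[eligibility$included, , drop = FALSE]

  seq_res <- stage("sequences",
    build_sequences(persons, use_periods, tables$hospital_stays))
  sequences <- seq_res$sequences
  persons <- persons[match(sequences$person_id, persons$person_id), ,
                     drop = FALSE]
  groups <- persons$population_group

  ssa <- stage("ssa", {
    rates <- transition_rates(sequences)
    list(rates = rates,
         costs = trate_costs(rates, cval = config$cval,
                             indel = config$indel),
         transversal_entropy =
           transversal_entropy(sequences,
                               norm_size = config$entropy_norm_size),
         longitudinal_entropy =
           apply(sequence_matrix(sequences), 1L, longitudinal_entropy,
                 norm_size = config$entropy_norm_size),
         complexity = apply(sequence_matrix(sequences), 1L,
                            complexity_index,
                            norm_size = config$entropy_norm_size),
         mean_time = mean_time_in_states(sequences, groups))
  })

  clust <- stage("cluster", {
    diss <- dissimilarity_matrix(sequences, ssa$costs)
    sel <- select_typologies(diss, k_range = config$k_range,
                             methods = config$methods)
    labels <- person_labels(sel$best, diss)
    names <- name_typologies(sel$best, diss)
    list(diss = diss, selection = sel, best = sel$best,
         person_labels = labels, typology_names = names[labels],
         cluster_names = names)
  })

  trajectories <- stage("trajectories", {
    pre_ad <- pre_diagnosis_ad_monotherapy(persons, use_periods)
    rec <- classify_trajectories(sequences, pre_ad)
    list(records = rec, summary = summarize_trajectories(rec, groups))
  })

  assoc <- stage("associate", {
    typ <- clust$typology_names
    out <- list()
    if (length(unique(typ)) >= 2 && length(unique(groups)) >= 2) {
      ref_levels <- list(population_group = "swedish_born")
      uni <- fit_multinomial(typ,
                             data.frame(population_group = groups),
                             reference_levels = ref_levels)
      out$univariate <- uni
      out$univariate_or <- odds_ratios(uni)
      out$univariate_probs <-
        fitted_probabilities(uni, "population_group")
      if (config$adjusted) {
        covs <- intersect(c("education", "living_with_partner",
                            "prior_depression", "adhd", "substance_use",
                            "neurotic", "obesity_diabetes",
                            "prior_sickness_absence", "disability_pension",
                            "sex"),
                          names(persons))
        design <- cbind(data.frame(population_group = groups),
                        persons[, covs, drop = FALSE])
        adj <- fit_multinomial(typ, design, reference_levels = ref_levels)
        out$adjusted <- adj
        out$adjusted_or <- odds_ratios(adj)
        out$adjusted_probs <- fitted_probabilities(adj, "population_group")
      }
    }
    out
  })

  report <- stage("report",
    table_one(groups, trajectories$records, clust$typology_names))

  result <- list(config = config, tables = tables,
                 use_periods = use_periods, eligibility = eligibility,
                 sequences = sequences,
                 sequence_exclusions = seq_res$exclusions,
                 groups = groups, ssa = ssa, clustering = clust,
                 trajectories = trajectories, association = assoc,
                 table_one = report)
  if (!is.null(config$out_dir)) write_artifacts(result, config$out_dir)
  result
}

#' Descriptive medication-use pattern table by population group
#'
#' Builds the three-section descriptive table: (A) treatment initiation and
#' discontinuation with times to event, (B) the five-trajectory cross, and
#' (C) typology membership, each as counts with percentages (rounded
#' half-up to one decimal) against the section's denominator.
#'
#' @param groups Population-group label per person.
#' @param trajectory_records Output of [classify_trajectories()].
#' @param typology_names Typology name per person (or `NULL` to omit
#'   section C).
#' @return Data frame with `section`, `row`, `group`, `n`, `denominator`,
#'   `percent`.
#' @export
table_one <- function(groups, trajectory_records, typology_names = NULL) {
  out <- summarize_trajectories(trajectory_records, groups)
  out$section <- paste0("A_", out$section)
  out$section[out$section == "A_trajectory"] <- "B_trajectory"
  if (!is.null(typology_names)) {
    groups <- as.character(groups)
    rows <- list()
    for (tn in unique(typology_names)) {
      for (g in unique(groups)) {
        den <- sum(groups == g)
        cnt <- sum(typology_names == tn & groups == g)
        rows[[length(rows) + 1L]] <- data.frame(
          section = "C_typology", row = tn, group = g, n = cnt,
          denominator = den,
          percent = round_half_up(100 * cnt / den, 1),
          stringsAsFactors = FALSE)
      }
    }
    out <- rbind(out, do.call(rbind, rows))
  }
  rownames(out) <- NULL
  check_table_percentages(out)
  out
}

#' Self-check that every printed percentage matches its count ratio
#' @param tab A table as produced by [table_one()].
#' @return `TRUE` invisibly; error on mismatch.
#' @export
check_table_percentages <- function(tab) {
  ok <- is.na(tab$percent) |
    abs(tab$percent - round_half_up(100 * tab$n / tab$denominator, 1)) <
      1e-9
  if (!all(ok)) stop("table percentages inconsistent with counts at row(s) ",
                     paste(utils::head(which(!ok), 5), collapse = ", "))
  invisible(TRUE)
}

write_artifacts <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  wr(result$use_periods, "use_periods")
  wr(result$eligibility, "eligibility")
  wr(result$sequences, "sequences")
  wr(result$sequence_exclusions, "sequence_exclusions")
  wr(result$trajectories$records, "trajectories")
  wr(result$trajectories$summary, "trajectory_summary")
  wr(result$clustering$selection$asw_table, "asw_table")
  wr(data.frame(person_id = result$sequences$person_id,
                cluster = result$clustering$person_labels,
                typology_name = result$clustering$typology_names),
     "labels")
  wr(result$ssa$mean_time, "mean_time_in_state")
  wr(as.data.frame(result$ssa$rates$probs), "transition_rates")
  wr(result$table_one, "table_one")
  diss <- result$clustering$diss
  utils::write.csv(diss$d, file.path(out_dir, "dissimilarity.csv"))
  wr(data.frame(sequence = rownames(diss$d), weight = diss$weights),
     "dissimilarity_weights")
  if (!is.null(result$association$univariate_or))
    wr(result$association$univariate_or, "effects_univariate")
  if (!is.null(result$association$adjusted_or))
    wr(result$association$adjusted_or, "effects_adjusted")
  cfg <- result$config
  cfg_json <- jsonlite::toJSON(
    cfg[setdiff(names(cfg), "input")], auto_unbox = TRUE, digits = NA,
    force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(
    package = "medseq",
    version = as.character(utils::packageVersion("medseq")),
    config_hash = unname(tools::md5sum(tf)),
    seed = if (inherits(cfg$input, "medseq_genconfig")) cfg$input$seed
           else NA,
    n_sequences = nrow(result$sequences),
    selected_method = result$clustering$best$method,
    selected_k = result$clustering$best$k,
    best_asw = result$clustering$best$asw)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(out_dir, "manifest.json"))
  unlink(tf)
  invisible(out_dir)
}
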