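#' Multinomial logistic regression of typology membership
#'
#' Maximum-likelihood softmax regression of the typology outcome on a table
#' of categorical predictors, with the outcome reference set to the largest
#' category by default (so effects read as odds of each typology versus the
#' majority pattern). The fit is deterministic (zero initialization) and
#' standard errors come from the observed information.
#'
#' @param outcome Factor (or character) of typology labels.
#' @param design Data frame of categorical predictors.
#' @param reference_outcome Reference outcome category; default the most
#'   frequent.
#' @param reference_levels Named list of reference levels per predictor;
#'   default each factor's first level.
#' @param weights Optional case weights.
#' @return Object of class `medseq_multinom`: list with the `nnet::multinom`
#'   `fit`, `outcome_levels`, `reference_outcome`, `n`.
#' @export
fit_multinomial <- function(outcome, design, reference_outcome = NULL,
                            reference_levels = NULL, weights = NULL) {
  outcome <- as.factor(outcome)
  if (nlevels(outcome) < 2) stop("need >= 2 outcome categories")
  if (is.null(reference_outcome))
    reference_outcome <- names(sort(table(outcome), decreasing = TRUE))[1]
  outcome <- stats::relevel(outcome, ref = reference_outcome)
  design <- as.data.frame(design)
  for (nm in names(design)) {
    design[[nm]] <- as.factor(design[[nm]])
    if (nlevels(design[[nm]]) < 2) {
      message("dropping constant predictor '", nm, "'")
      design[[nm]] <- NULL
      next
    }
    if (!is.null(reference_levels[[nm]]))
      design[[nm]] <- stats::relevel(design[[nm]],
                                     ref = reference_levels[[nm]])
  }
  dat <- cbind(.outcome = outcome, design)
  form <- stats::as.formula(paste(".outcome ~",
                                  if (ncol(design)) paste(names(design),
                                                          collapse = " + ")
                                  else "1"))
  if (is.null(weights)) weights <- rep(1, nrow(dat))
  fit <- nnet::multinom(form, data = dat, weights = weights,
                        trace = FALSE, maxit = 500, reltol = 1e-12,
                        Hess = TRUE)
  if (fit$convergence != 0)
    stop("multinomial fit did not converge")
  structure(list(fit = fit, outcome_levels = levels(outcome),
                 reference_outcome = reference_outcome,
                 design_names = names(design),
                 data = dat, n = nrow(dat)),
            class = "medseq_multinom")
}

#' Odds ratios with Wald confidence intervals
#'
#' `OR = exp(coef)` with 95% CI `exp(coef +/- 1.959964 * se)` per
#' (typology, predictor-level) pair; the reference outcome's coefficients
#' are identically zero and are not listed.
#'
#' @param result A `medseq_multinom` from [fit_multinomial()].
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with `typology`, `term`, `estimate` (log-odds), `or`,
#'   `ci_low`, `ci_high`, `p_value`.
#' @export
odds_ratios <- function(result, conf_level = 0.95) {
  stopifnot(inherits(result, "medseq_multinom"))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  cf <- stats::coef(result$fit)
  if (is.null(dim(cf))) {  # two-category outcome: coerce to matrix
    cf <- matrix(cf, nrow = 1,
                 dimnames = list(result$outcome_levels[2], names(cf)))
  }
  vc <- stats::vcov(result$fit)
  se <- matrix(sqrt(diag(vc)), nrow = nrow(cf), byrow = TRUE,
               dimnames = dimnames(cf))
  out <- expand.grid(typology = rownames(cf), term = colnames(cf),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- cbind(match(out$typology, rownames(cf)),
               match(out$term, colnames(cf)))
  out$estimate <- cf[idx]
  out$se <- se[idx]
  out$or <- exp(out$estimate)
  out$ci_low <- exp(out$estimate - z * out$se)
  out$ci_high <- exp(out$estimate + z * out$se)
  out$p_value <- 2 * stats::pnorm(-abs(out$estimate / out$se))
  out
}

#' Marginally standardized fitted probabilities
#'
#' For each level of `factor_name`, sets every person's value of that factor
#' to the level, averages the model-predicted typology probabilities over
#' the sample (g-computation), optionally within strata of `stratify_by`.
#' With `factor_name = NULL` the observed-covariate average probabilities
#' are returned.
#'
#' @param result A `medseq_multinom`.
#' @param factor_name Predictor to standardize over (or `NULL`).
#' @param stratify_by Optional vector of stratum labels (length `n`).
#' @return Data frame with `stratum`, `factor`, `level`, `typology`,
#'   `probability`; probabilities sum to 1 within each (stratum, level).
#' @export
fitted_probabilities <- function(result, factor_name = NULL,
                                 stratify_by = NULL) {
  stopifnot(inherits(result, "medseq_multinom"))
  dat <- result$data
  strata <- if (is.null(stratify_by)) rep("all", nrow(dat))
            else as.character(stratify_by)
  predict_mean <- function(d, rows) {
    pr <- stats::predict(result$fit, newdata = d[rows, , drop = FALSE],
                         type = "probs")
    if (is.null(dim(pr)))
      pr <- matrix(pr, ncol = length(result$outcome_levels),
                   dimnames = list(NULL, result$outcome_levels))
    colMeans(pr)
  }
  rows_out <- list()
  for (s in unique(strata)) {
    rows <- which(strata == s)
    if (is.null(factor_name)) {
      p <- predict_mean(dat, rows)
      rows_out[[length(rows_out) + 1L]] <-
        data.frame(stratum = s, factor = NA_character_,
                   level = NA_character_, typology = names(p),
                   probability = unname(p), stringsAsFactors = FALSE)
    } else {
      stopifnot(factor_name %in% result$design_names)
      for (lev in levels(dat[[factor_name]])) {
        d2 <- dat
        d2[[factor_name]] <- factor(lev, levels = levels(dat[[factor_name]]))
        p <- predict_mean(d2, rows)
        rows_out[[length(rows_out) + 1L]] <-
          data.frame(stratum = s, factor = factor_name, level = lev,
                     typology = names(p), probability = unname(p),
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows_out)
  rownames(out) <- NULL
  out
}
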