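#' Weighted transition rates between states
#'
#' Pools weighted first-order transition counts over positions 1..(L-1) of
#' all sequences. Row `i` of `probs` gives `p(i -> j)`, the probability of
#' being in state `j` at `t+1` given state `i` at `t`. States never observed
#' as an origin get an all-zero row and are listed in `empty_origins` rather
#' than propagating `NaN`.
#'
#' @param states Character matrix (rows = sequences, cols = periods) or a
#'   sequence table with `s1..s12` columns.
#' @param weights Sequence multiplicities; default 1.
#' @param alphabet Symbol set defining rows/columns.
#' @return Object of class `medseq_trate`: list with `counts`, `probs`,
#'   `leave` (1 - p(i->i)), `empty_origins`.
#' @examples
#' m <- rbind(c("A", "A", "A", "B"))
#' transition_rates(m, alphabet = c("A", "B"))$probs
#' @export
transition_rates <- function(states, weights = NULL,
                             alphabet = medseq_alphabet) {
  if (is.data.frame(states)) {
    weights <- weights %||% states$weight
    states <- sequence_matrix(states)
  }
  stopifnot(is.matrix(states), nrow(states) >= 1, ncol(states) >= 2)
  weights <- weights %||% rep(1, nrow(states))
  s <- length(alphabet)
  codes <- encode_states(states, alphabet)
  counts <- matrix(0, s, s, dimnames = list(alphabet, alphabet))
  L <- ncol(codes)
  for (t in seq_len(L - 1)) {
    idx <- cbind(codes[, t], codes[, t + 1])
    for (r in seq_len(nrow(idx)))
      counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] + weights[r]
  }
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, 1)
  probs[rs == 0, ] <- 0
  structure(list(counts = counts, probs = probs,
                 leave = ifelse(rs > 0, 1 - diag(probs), NA_real_),
                 empty_origins = alphabet[rs == 0]),
            class = "medseq_trate")
}

#' Transition-rate (TRATE) substitution costs
#'
#' Substitution cost between distinct states `i`, `j` is
#' `cval - p(i->j) - p(j->i)`, floored at zero, so frequently interchanged
#' states are cheap to substitute; the diagonal is zero. The indel cost
#' defaults to `cval / 2`.
#'
#' @param rates A `medseq_trate` object from [transition_rates()].
#' @param cval Maximal substitution cost (default 2).
#' @param indel Insertion/deletion cost; default `cval / 2`.
#' @return Object of class `medseq_costs`: list with symmetric `sub` matrix
#'   and scalar `indel`.
#' @export
trate_costs <- function(rates, cval = 2, indel = cval / 2) {
  stopifnot(inherits(rates, "medseq_trate"), cval > 0, indel > 0)
  p <- rates$probs
  sub <- pmax(cval - p - t(p), 0)
  diag(sub) <- 0
  structure(list(sub = sub, indel = indel, cval = cval,
                 alphabet = rownames(p)),
            class = "medseq_costs")
}

#' Constant substitution costs
#'
#' @param alphabet Symbol set.
#' @param cval Off-diagonal substitution cost.
#' @param indel Indel cost.
#' @return A `medseq_costs` object.
#' @export
constant_costs <- function(alphabet = medseq_alphabet, cval = 2,
                           indel = cval / 2) {
  sub <- matrix(cval, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(sub) <- 0
  structure(list(sub = sub, indel = indel, cval = cval, alphabet = alphabet),
            class = "medseq_costs")
}

#' Optimal-matching distance between two state sequences
#'
#' Minimal total cost of transforming `a` into `b` with substitutions (priced
#' by the cost matrix) and insertions/deletions (priced by the indel cost),
#' computed by dynamic programming. Symmetric when the cost matrix is.
#'
#' @param a,b Character vectors of states.
#' @param costs A `medseq_costs` object.
#' @return Non-negative edit distance.
#' @export
om_distance <- function(a, b, costs) {
  stopifnot(inherits(costs, "medseq_costs"))
  ca <- encode_states(a, costs$alphabet)
  cb <- encode_states(b, costs$alphabet)
  .om_dist_pair(ca, cb, costs$sub, costs$indel)
}

#' Pairwise optimal-matching dissimilarity over unique sequences
#'
#' Identical sequences are collapsed into unique rows with multiplicity
#' weights (summing the input weights) before the quadratic distance
#' computation; unique rows are ordered lexicographically by their state
#' strings so the result does not depend on input order.
#'
#' @param states Character matrix or sequence table (`s1..s12` + `weight`).
#' @param costs A `medseq_costs` object.
#' @param weights Per-sequence weights; default 1 (or the table's `weight`).
#' @return Object of class `medseq_diss`: list with `d` (symmetric matrix
#'   over unique sequences), `weights`, `unique_states` (matrix), and `index`
#'   mapping each input row to its unique row.
#' @export
dissimilarity_matrix <- function(states, costs, weights = NULL) {
  if (is.data.frame(states)) {
    weights <- weights %||% states$weight
    states <- sequence_matrix(states)
  }
  stopifnot(is.matrix(states), nrow(states) >= 1)
  weights <- weights %||% rep(1, nrow(states))
  keys <- sequence_key(states)
  ord_levels <- sort(unique(keys))
  idx <- match(keys, ord_levels)
  uniq <- states[match(ord_levels, keys), , drop = FALSE]
  rownames(uniq) <- NULL
  w <- as.vector(tapply(weights, idx, sum))
  codes <- encode_states(uniq, costs$alphabet)
  d <- .om_dist_matrix(codes, costs$sub, costs$indel)
  dimnames(d) <- list(ord_levels, ord_levels)
  structure(list(d = d, weights = w, unique_states = uniq, index = idx,
                 costs = costs),
            class = "medseq_diss")
}

#' Transversal (cross-sectional) entropy per period
#'
#' Shannon entropy of the weighted state distribution at each period,
#' normalized by `log(norm_size)` so values lie in `[0, 1]`.
#'
#' @param states Character matrix or sequence table.
#' @param weights Sequence weights.
#' @param alphabet Symbol set.
#' @param norm_size Alphabet size used for normalization; defaults to the
#'   full alphabet length (censoring counts as a state).
#' @return Numeric vector, one entry per period.
#' @export
transversal_entropy <- function(states, weights = NULL,
                                alphabet = medseq_alphabet,
                                norm_size = length(alphabet)) {
  if (is.data.frame(states)) {
    weights <- weights %||% states$weight
    states <- sequence_matrix(states)
  }
  weights <- weights %||% rep(1, nrow(states))
  apply(states, 2L, function(col) {
    p <- tapply(weights, factor(col, levels = alphabet), sum)
    p[is.na(p)] <- 0
    p <- p / sum(p)
    .entropy(p) / log(norm_size)
  })
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Longitudinal (within-sequence) entropy
#'
#' Shannon entropy of the distribution of states within one sequence,
#' normalized by `log(norm_size)`.
#'
#' @param sequence Character vector of states.
#' @inheritParams transversal_entropy
#' @return Scalar in `[0, 1]`.
#' @export
longitudinal_entropy <- function(sequence, alphabet = medseq_alphabet,
                                 norm_size = length(alphabet)) {
  p <- table(factor(sequence, levels = alphabet))
  .entropy(p / sum(p)) / log(norm_size)
}

#' Sequence complexity index
#'
#' Geometric mean of the normalized transition count and the normalized
#' longitudinal entropy:
#' `sqrt((n_transitions / (L - 1)) * longitudinal_entropy)`. Zero for
#' constant sequences; bounded by 1.
#'
#' @inheritParams longitudinal_entropy
#' @export
complexity_index <- function(sequence, alphabet = medseq_alphabet,
                             norm_size = length(alphabet)) {
  L <- length(sequence)
  ntrans <- sum(sequence[-1] != sequence[-L])
  sqrt((ntrans / (L - 1)) *
         longitudinal_entropy(sequence, alphabet, norm_size))
}

#' Mean time spent in each state, by group
#'
#' For each group and state, the mean number of periods spent in the state
#' and the mean proportion of follow-up, where each person's proportion
#' denominator is their number of non-censored periods (the censored share is
#' reported separately as state `CENSORED` over all 12 periods).
#'
#' @param states Character matrix or sequence table.
#' @param groups Group label per sequence.
#' @param weights Sequence weights.
#' @return Data frame with `group`, `state`, `mean_periods`,
#'   `mean_proportion`.
#' @export
mean_time_in_states <- function(states, groups, weights = NULL) {
  if (is.data.frame(states)) {
    weights <- weights %||% states$weight
    states <- sequence_matrix(states)
  }
  weights <- weights %||% rep(1, nrow(states))
  L <- ncol(states)
  counts <- sapply(medseq_alphabet, function(st) rowSums(states == st))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL,
                                                             medseq_alphabet))
  noncens <- L - counts[, "CENSORED"]
  out <- do.call(rbind, lapply(split(seq_len(nrow(states)), groups),
                               function(ii) {
    w <- weights[ii]
    data.frame(
      group = groups[ii[1]],
      state = medseq_alphabet,
      mean_periods = colSums(counts[ii, , drop = FALSE] * w) / sum(w),
      mean_proportion = vapply(medseq_alphabet, function(st) {
        if (st == "CENSORED")
          return(sum(counts[ii, st] / L * w) / sum(w))
        ok <- noncens[ii] > 0
        sum((counts[ii, st][ok] / noncens[ii][ok]) * w[ok]) / sum(w[ok])
      }, numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Group contrasts of time in state by log-linear count regression
#'
#' For each state, fits a Poisson log-link regression of per-person period
#' counts on group indicators with an offset for the number of observed
#' (non-censored) periods, yielding rate ratios vs the reference group.
#'
#' @param states Character matrix or sequence table.
#' @param groups Factor of group labels (first level = reference).
#' @param weights Optional weights.
#' @param robust Use HC0 sandwich standard errors (default `TRUE`).
#' @param states_tested States to contrast; default the 7 treatment states.
#' @return Data frame with `state`, `group`, `rate_ratio`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
time_in_state_contrast <- function(states, groups, weights = NULL,
                                   robust = TRUE,
                                   states_tested = medseq_states) {
  if (is.data.frame(states)) {
    weights <- weights %||% states$weight
    states <- sequence_matrix(states)
  }
  weights <- weights %||% rep(1, nrow(states))
  groups <- as.factor(groups)
  L <- ncol(states)
  cens <- rowSums(states == "CENSORED")
  offset_periods <- L - cens
  keep <- offset_periods > 0
  out <- lapply(states_tested, function(st) {
    y <- rowSums(states == st)[keep]
    dat <- data.frame(y = y, group = groups[keep],
                      off = log(offset_periods[keep]))
    fit <- stats::glm(y ~ group + offset(off), family = stats::poisson(),
                      data = dat, weights = weights[keep])
    cf <- stats::coef(fit)
    if (robust) {
      vc <- sandwich::vcovHC(fit, type = "HC0")
      ct <- lmtest::coeftest(fit, vcov. = vc)
      se <- ct[, "Std. Error"]; pv <- ct[, 4]
    } else {
      se <- sqrt(diag(stats::vcov(fit)))
      pv <- summary(fit)$coefficients[, 4]
    }
    term <- grep("^group", names(cf), value = TRUE)
    data.frame(state = st,
               group = sub("^group", "", term),
               rate_ratio = exp(cf[term]),
               ci_low = exp(cf[term] - 1.959964 * se[term]),
               ci_high = exp(cf[term] + 1.959964 * se[term]),
               p_value = pv[term],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
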