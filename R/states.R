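#' Treatment-state alphabet
#'
#' Seven mutually exclusive treatment states plus an absorbing censoring
#' state. Each 91-day period of follow-up is mapped to exactly one symbol:
#'
#' * `LACK` — no medication group used on >= 50% of assessable days.
#' * `AD_MONO` — antidepressants only (guideline-discordant monotherapy).
#' * `MOOD_STAB` — anticonvulsant mood-stabilizers, no antipsychotics/lithium.
#' * `ANTIPSYCH` — antipsychotics, no mood-stabilizers/lithium.
#' * `LITHIUM` — lithium, no mood-stabilizers/antipsychotics.
#' * `AUGMENT` — mood-stabilizers and antipsychotics combined, no lithium.
#' * `LI_AUGMENT` — lithium plus mood-stabilizers and/or antipsychotics.
#' * `CENSORED` — period at or after death; absorbing until end of follow-up.
#'
#' Concomitant antidepressant use is allowed (ignored) in all standard and
#' augmentation states.
#'
#' @format Character vector of length 8 (`medseq_alphabet`), or 7 treatment
#'   states only (`medseq_states`).
#' @export
medseq_alphabet <- c("LACK", "AD_MONO", "MOOD_STAB", "ANTIPSYCH",
                     "LITHIUM", "AUGMENT", "LI_AUGMENT", "CENSORED")

#' @rdname medseq_alphabet
#' @export
medseq_states <- medseq_alphabet[1:7]

#' @rdname medseq_alphabet
#' @export
medseq_classes <- c("antidepressant", "anticonvulsant_ms", "lithium",
                    "antipsychotic")

#' Human-readable typology names keyed by dominant state
#' @keywords internal
.typology_names <- c(
  LACK       = "treatment failure",
  AD_MONO    = "persistent antidepressant-monotherapy",
  MOOD_STAB  = "persistent mood-stabilizers",
  ANTIPSYCH  = "persistent antipsychotics",
  LITHIUM    = "persistent lithium",
  AUGMENT    = "persistent augmentation",
  LI_AUGMENT = "persistent lithium with augmentation"
)

#' Assign a treatment state from four binary medication indicators
#'
#' Implements the state decision tree. The adequate-treatment classes
#' (mood-stabilizers, antipsychotics, lithium) dominate: the antidepressant
#' indicator only matters when all three are negative.
#'
#' @param ad,ms,ap,li Binary indicators (0/1 or logical) for antidepressants,
#'   anticonvulsant mood-stabilizers, antipsychotics and lithium. Vectorized.
#' @return Character vector of states from [medseq_states].
#' @examples
#' assign_state(ad = 1, ms = 0, ap = 0, li = 0)  # "AD_MONO"
#' assign_state(ad = 1, ms = 1, ap = 0, li = 0)  # "MOOD_STAB"
#' @export
assign_state <- function(ad, ms, ap, li) {
  ad <- as.logical(ad); ms <- as.logical(ms)
  ap <- as.logical(ap); li <- as.logical(li)
  n <- max(length(ad), length(ms), length(ap), length(li))
  ad <- rep_len(ad, n); ms <- rep_len(ms, n)
  ap <- rep_len(ap, n); li <- rep_len(li, n)
  if (anyNA(ad) || anyNA(ms) || anyNA(ap) || anyNA(li))
    stop("indicators must be non-missing 0/1 values")
  out <- rep("LACK", n)
  out[ad] <- "AD_MONO"
  out[ms] <- "MOOD_STAB"
  out[ap] <- "ANTIPSYCH"
  out[ms & ap] <- "AUGMENT"
  out[li] <- "LITHIUM"
  out[li & (ms | ap)] <- "LI_AUGMENT"
  out
}

#' Encode/decode state sequences between character and integer codes
#'
#' @param x Character matrix/vector of states, or integer codes.
#' @param alphabet Symbol set; defaults to the full 8-state alphabet.
#' @return Integer codes (1-based) or character symbols.
#' @keywords internal
encode_states <- function(x, alphabet = medseq_alphabet) {
  codes <- match(x, alphabet)
  if (anyNA(codes) && !anyNA(x))
    stop("symbol outside alphabet: ",
         paste(unique(x[is.na(codes)]), collapse = ", "))
  if (is.matrix(x)) dim(codes) <- dim(x)
  codes
}

#' @rdname encode_states
#' @keywords internal
decode_states <- function(x, alphabet = medseq_alphabet) {
  out <- alphabet[x]
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Collapse a state matrix to one string per sequence
#' @param states Character matrix (rows = persons, cols = periods).
#' @keywords internal
sequence_key <- function(states) {
  apply(states, 1L, paste, collapse = "-")
}
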