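#' Default ATC-prefix to medication-class map
#'
#' Ordered longest-prefix rules mapping WHO ATC codes to the four medication
#' classes used throughout the pipeline. The lithium rule (`N05AN`) shadows
#' the general antipsychotic rule (`N05A`) via longest-prefix matching.
#'
#' These defaults cover the class definitions (N06A antidepressants, N03A
#' anticonvulsant mood-stabilizers, N05AN lithium, N05A antipsychotics) but
#' are not an authoritative reproduction of any register-specific code list;
#' supply your own map (e.g. from YAML, see [read_atc_map()]) to override.
#'
#' @return Data frame with columns `atc_prefix`, `class`.
#' @export
default_atc_map <- function() {
  data.frame(
    atc_prefix = c("N06A", "N03A", "N05AN", "N05A"),
    class = c("antidepressant", "anticonvulsant_ms", "lithium",
              "antipsychotic"),
    stringsAsFactors = FALSE
  )
}

#' Read an ATC class map from a YAML file
#'
#' The YAML file holds a mapping of ATC prefix to class name, e.g.
#' `N06A: antidepressant`.
#'
#' @param path YAML file path.
#' @export
read_atc_map <- function(path) {
  raw <- yaml::read_yaml(path)
  map <- data.frame(atc_prefix = names(raw),
                    class = unname(unlist(raw)),
                    stringsAsFactors = FALSE)
  validate_atc_map(map)
  map
}

validate_atc_map <- function(map) {
  stopifnot(is.data.frame(map), all(c("atc_prefix", "class") %in% names(map)))
  bad <- setdiff(unique(map$class), medseq_classes)
  if (length(bad))
    stop("unknown medication class in ATC map: ", paste(bad, collapse = ", "))
  if (anyDuplicated(map$atc_prefix))
    stop("duplicate ATC prefixes in map")
  invisible(map)
}

#' Classify an ATC code into a medication class
#'
#' Longest matching prefix wins; codes matching no rule return `NA`.
#'
#' @param atc_code Character vector of ATC codes.
#' @param map Prefix rules as from [default_atc_map()].
#' @return Character vector of classes (`NA` where unclassified).
#' @examples
#' classify_atc("N05AN01")  # lithium
#' classify_atc("N05AH03")  # antipsychotic
#' @export
classify_atc <- function(atc_code, map = default_atc_map()) {
  validate_atc_map(map)
  if (any(!nzchar(atc_code) | is.na(atc_code)))
    stop("ATC codes must be non-empty")
  # order rules by decreasing prefix length so the first hit is the longest
  map <- map[order(-nchar(map$atc_prefix)), , drop = FALSE]
  out <- rep(NA_character_, length(atc_code))
  for (r in seq_len(nrow(map))) {
    hit <- is.na(out) & startsWith(atc_code, map$atc_prefix[r])
    out[hit] <- map$class[r]
  }
  out
}

#' Build continuous drug-use periods from dispensing records
#'
#' A simplified continuous-exposure model: each dispensing covers
#' `[dispense_date, dispense_date + supply - 1]` where `supply` is the
#' sliding mean of `days_supply` over the person's last `window` dispensings
#' of the same class (smoothing out stockpiling), and per-class coverage
#' intervals separated by at most `grace_days` are merged into one maximal
#' use period. This follows the sliding-average principle of dose-based
#' exposure modelling; it is not a reimplementation of any specific published
#' exposure algorithm.
#'
#' @param dispensings Data frame with `person_id`, `atc_code`, `dispense_date`
#'   (Date), `days_supply` (positive integer).
#' @param map ATC class map; see [default_atc_map()].
#' @param grace_days Maximal gap (days) bridged when merging intervals.
#' @param window Sliding-mean window (number of dispensings).
#' @param strict If `TRUE`, an unclassifiable ATC code is an error;
#'   otherwise such records are dropped with a message.
#' @return Data frame of use periods: `person_id`, `drug_class`,
#'   `start_date`, `end_date` (inclusive), sorted, maximal, non-overlapping
#'   within person and class.
#' @export
build_use_periods <- function(dispensings, map = default_atc_map(),
                              grace_days = 30, window = 3, strict = FALSE) {
  stopifnot(grace_days >= 0, window >= 1)
  empty <- data.frame(person_id = character(), drug_class = character(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      stringsAsFactors = FALSE)
  if (nrow(dispensings) == 0) return(empty)
  if (any(dispensings$days_supply < 1))
    stop("days_supply must be >= 1")
  cls <- classify_atc(dispensings$atc_code, map)
  if (anyNA(cls)) {
    if (strict)
      stop("unclassifiable ATC code(s): ",
           paste(unique(dispensings$atc_code[is.na(cls)]), collapse = ", "))
    message(sum(is.na(cls)), " dispensing record(s) with unclassifiable ATC ",
            "code skipped")
  }
  d <- dispensings[!is.na(cls), , drop = FALSE]
  d$drug_class <- cls[!is.na(cls)]
  if (nrow(d) == 0) return(empty)
  d <- d[order(d$person_id, d$drug_class, d$dispense_date), , drop = FALSE]

  out <- lapply(split(d, list(d$person_id, d$drug_class), drop = TRUE),
                function(g) {
    # sliding mean of supply over the last `window` dispensings (incl. current)
    n <- nrow(g)
    supply <- vapply(seq_len(n), function(i) {
      lo <- max(1L, i - window + 1L)
      round(mean(g$days_supply[lo:i]))
    }, numeric(1))
    supply <- pmax(1, supply)
    start <- as.numeric(g$dispense_date)
    end <- start + supply - 1
    # merge intervals whose gap (days between end and next start) <= grace
    ms <- start[1]; me <- end[1]
    rs <- numeric(0); re <- numeric(0)
    for (i in seq_len(n)[-1]) {
      if (start[i] - me - 1 <= grace_days) {
        me <- max(me, end[i])
      } else {
        rs <- c(rs, ms); re <- c(re, me)
        ms <- start[i]; me <- end[i]
      }
    }
    rs <- c(rs, ms); re <- c(re, me)
    data.frame(person_id = g$person_id[1], drug_class = g$drug_class[1],
               start_date = as.Date(rs, origin = "1970-01-01"),
               end_date = as.Date(re, origin = "1970-01-01"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[order(out$person_id, out$drug_class, out$start_date), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
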