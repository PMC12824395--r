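# Independent oracles used to verify the package's algorithms.

# Brute-force edit distance by plain recursion over substitute /
# delete / insert moves (no dynamic programming), for tiny sequences.
bf_edit_distance <- function(a, b, sub, indel) {
  if (!length(a)) return(length(b) * indel)
  if (!length(b)) return(length(a) * indel)
  min(bf_edit_distance(a[-1], b[-1], sub, indel) + sub[a[1], b[1]],
      bf_edit_distance(a[-1], b, sub, indel) + indel,
      bf_edit_distance(a, b[-1], sub, indel) + indel)
}

# Exhaustive weighted k-medoids: minimal objective over all medoid subsets.
bf_pam_objective <- function(d, w, k) {
  m <- nrow(d)
  best <- Inf
  for (set in utils::combn(m, k, simplify = FALSE)) {
    obj <- sum(apply(d[, set, drop = FALSE], 1, min) * w)
    if (obj < best) best <- obj
  }
  best
}

# Wrap an arbitrary dissimilarity matrix as a medseq_diss object.
make_diss <- function(d, w = rep(1, nrow(d)), states = NULL) {
  structure(list(d = d, weights = w, unique_states = states,
                 index = seq_len(nrow(d))),
            class = "medseq_diss")
}

# All sequences of length 1..max_len over an alphabet, as list of vectors.
all_sequences <- function(alphabet, max_len) {
  out <- list()
  for (L in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), L),
                      list(stringsAsFactors = FALSE)))
    out <- c(out, lapply(seq_len(nrow(grid)), function(i)
      unlist(grid[i, ], use.names = FALSE)))
  }
  out
}

# Tiny helper: sequence table from a character matrix.
as_seq_table <- function(m, ids = NULL, weight = 1) {
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- paste0("s", seq_len(ncol(m)))
  df <- cbind(person_id = ids %||% sprintf("P%03d", seq_len(nrow(m))), df)
  df$weight <- weight
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
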