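#' Ward hierarchical clustering of weighted unique sequences
#'
#' Agglomerative clustering of the unique-sequence dissimilarity matrix with
#' the Ward criterion (Lance–Williams update on squared dissimilarities,
#' "ward.D2"), treating each unique sequence as a pre-formed group of
#' `weight` identical objects via the `members` mechanism, then cutting the
#' tree at `k` clusters.
#'
#' `hclust` interprets its input as the dissimilarity *between the initial
#' clusters*, so for weighted units the raw distances are first rescaled to
#' the Ward merge distance between groups of identical objects
#' (`sqrt(2 w_i w_j / (w_i + w_j)) * d_ij` for `ward.D2`, the squared
#' analogue for `ward.D`); the result then matches clustering the fully
#' expanded multiset.
#'
#' @param diss A `medseq_diss` object from [dissimilarity_matrix()].
#' @param k Number of clusters (2..number of unique sequences).
#' @param variant `"ward.D2"` (default) or `"ward.D"`.
#' @return A `medseq_clust` object; see [pam_cluster()].
#' @export
ward_cluster <- function(diss, k, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  m <- nrow(diss$d)
  stopifnot(k >= 1, k <= m)
  w <- diss$weights
  scale2 <- 2 * outer(w, w) / outer(w, w, "+")
  d0 <- if (variant == "ward.D2") diss$d * sqrt(scale2)
        else diss$d * scale2
  hc <- stats::hclust(stats::as.dist(d0), method = variant, members = w)
  labels <- unname(stats::cutree(hc, k = k))
  medoids <- cluster_medoids(diss, labels)
  sil <- silhouette_width(diss, labels)
  structure(list(method = "ward", k = k, labels = labels, medoids = medoids,
                 silhouettes = sil$widths, asw = sil$asw,
                 objective = pam_objective(diss, medoids)),
            class = "medseq_clust")
}

#' Weighted medoid of each cluster
#'
#' The medoid of a cluster is the member minimizing the weighted sum of
#' dissimilarities to all cluster members; ties break to the lowest index.
#'
#' @param diss A `medseq_diss` object.
#' @param labels Cluster label per unique sequence.
#' @return Integer vector of medoid indices, one per cluster id (sorted).
#' @export
cluster_medoids <- function(diss, labels) {
  vapply(sort(unique(labels)), function(cl) {
    ii <- which(labels == cl)
    costs <- colSums(diss$d[ii, ii, drop = FALSE] * diss$weights[ii])
    ii[which.min(costs)]
  }, integer(1))
}

pam_objective <- function(diss, medoids) {
  dm <- diss$d[, medoids, drop = FALSE]
  sum(apply(dm, 1L, min) * diss$weights)
}

#' Partitioning around medoids on weighted unique sequences
#'
#' Classic PAM adapted to multiplicity weights: BUILD greedily seeds `k`
#' medoids minimizing the weighted total distance to the nearest medoid;
#' SWAP repeatedly applies the single (medoid, non-medoid) exchange with the
#' steepest weighted-cost descent until no exchange improves. Entirely
#' deterministic (ties break to the lowest index). If `init` labels are
#' given (hybrid clustering), BUILD is replaced by per-cluster medoid
#' extraction from `init`.
#'
#' Because steepest-descent SWAP can stop in a local optimum (the classical
#' algorithm carries no global guarantee), small instances — where the
#' number of candidate medoid subsets `choose(m, k)` is at most
#' `exact_limit` — are instead solved exactly by enumerating all subsets.
#'
#' @param diss A `medseq_diss` object.
#' @param k Number of clusters.
#' @param init Optional initial labels (e.g. a Ward cut) for the hybrid
#'   Ward-then-PAM method (always uses SWAP, never enumeration).
#' @param max_iter Safety cap on SWAP iterations.
#' @param exact_limit Maximal number of medoid subsets enumerated for the
#'   exact small-instance solve; set to 0 to force BUILD+SWAP.
#' @return A `medseq_clust` object: `method`, `k`, `labels`, `medoids`,
#'   `silhouettes`, `asw`, `objective` (weighted sum of distances to the
#'   nearest medoid), `iterations`.
#' @export
pam_cluster <- function(diss, k, init = NULL, max_iter = 200,
                        exact_limit = 5000) {
  d <- diss$d
  w <- diss$weights
  m <- nrow(d)
  if (k > m) stop("k = ", k, " exceeds the number of unique sequences (", m,
                  ")")
  stopifnot(k >= 1)
  if (is.null(init) && choose(m, k) <= exact_limit) {
    # exact k-medoids by subset enumeration; first-in-order subset wins ties
    best <- Inf; medoids <- NULL
    sets <- utils::combn(m, k, simplify = FALSE)
    for (set in sets) {
      obj <- sum(apply(d[, set, drop = FALSE], 1L, min) * w)
      if (obj < best - 1e-12) {
        best <- obj; medoids <- set
      }
    }
    dm <- d[, medoids, drop = FALSE]
    labels <- apply(dm, 1L, which.min)
    sil <- silhouette_width(diss, labels)
    return(structure(list(method = "pam", k = k, labels = labels,
                          medoids = medoids, silhouettes = sil$widths,
                          asw = sil$asw, objective = best,
                          iterations = 0L),
                     class = "medseq_clust"))
  }
  if (is.null(init)) {
    # BUILD: first medoid minimizes weighted total distance; then greedily
    # add the point yielding the largest cost reduction
    medoids <- integer(0)
    dn <- rep(Inf, m)
    for (step in seq_len(k)) {
      gain <- vapply(seq_len(m), function(h) {
        if (h %in% medoids) return(-Inf)
        sum(w * pmin(d[, h], dn)) * -1
      }, numeric(1))
      h <- which.max(gain)
      medoids <- c(medoids, h)
      dn <- pmin(dn, d[, h])
    }
  } else {
    stopifnot(length(init) == m, length(unique(init)) == k)
    medoids <- cluster_medoids(diss, init)
  }
  method <- if (is.null(init)) "pam" else "ward_then_pam"

  iter <- 0L
  repeat {
    iter <- iter + 1L
    dm <- d[, medoids, drop = FALSE]
    near <- apply(dm, 1L, which.min)          # index into medoids
    dn <- dm[cbind(seq_len(m), near)]          # nearest-medoid distance
    ds <- if (k >= 2) {
      apply(dm, 1L, function(r) sort(r, partial = 2)[2])
    } else rep(Inf, m)
    cand <- setdiff(seq_len(m), medoids)
    if (!length(cand)) break
    best_delta <- 0; best_i <- NA; best_h <- NA
    for (ii in seq_len(k)) {
      assigned <- near == ii
      # cost change for each object if medoid ii is replaced by candidate h
      M <- pmin(d[, cand, drop = FALSE] - dn, 0)           # not assigned
      if (any(assigned))
        M[assigned, ] <- pmin(d[assigned, cand, drop = FALSE],
                              ds[assigned]) - dn[assigned]
      delta <- colSums(M * w)
      j <- which.min(delta)
      if (delta[j] < best_delta - 1e-12) {
        best_delta <- delta[j]; best_i <- ii; best_h <- cand[j]
      }
    }
    if (is.na(best_i) || iter > max_iter) break
    medoids[best_i] <- best_h
  }
  medoids <- sort(medoids)
  dm <- d[, medoids, drop = FALSE]
  labels <- apply(dm, 1L, which.min)
  sil <- silhouette_width(diss, labels)
  structure(list(method = method, k = k, labels = labels, medoids = medoids,
                 silhouettes = sil$widths, asw = sil$asw,
                 objective = pam_objective(diss, medoids),
                 iterations = iter),
            class = "medseq_clust")
}

#' Weighted silhouette widths
#'
#' Silhouette of object `i`: `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where
#' `a(i)` is the mean dissimilarity to the other objects of its own cluster
#' and `b(i)` the smallest mean dissimilarity to another cluster. With
#' multiplicity weights the `w_i - 1` zero-distance duplicates of `i` count
#' as own-cluster neighbours, so results match clustering the fully expanded
#' data. Conventions: objects alone in their cluster and degenerate cases
#' (`a = b = 0`) get `s = 0`.
#'
#' @param diss A `medseq_diss` object.
#' @param labels Cluster labels per unique sequence.
#' @return List with `widths` (per unique sequence) and `asw` (weighted
#'   mean).
#' @export
silhouette_width <- function(diss, labels) {
  d <- diss$d
  w <- diss$weights
  m <- nrow(d)
  cl_ids <- sort(unique(labels))
  if (length(cl_ids) == 1) {
    return(list(widths = rep(0, m), asw = 0))
  }
  # weighted total distance from each object to each cluster
  tot <- sapply(cl_ids, function(cl) {
    ii <- labels == cl
    as.vector(d[, ii, drop = FALSE] %*% w[ii])
  })
  W <- vapply(cl_ids, function(cl) sum(w[labels == cl]), numeric(1))
  widths <- numeric(m)
  for (i in seq_len(m)) {
    own <- match(labels[i], cl_ids)
    denom <- W[own] - 1        # expansion view: own weight minus object i
    a <- if (denom > 0) tot[i, own] / denom else NA_real_
    b <- min(tot[i, -own] / W[-own])
    widths[i] <- if (is.na(a) || (a == 0 && b == 0)) 0
                 else (b - a) / max(a, b)
  }
  list(widths = widths, asw = sum(widths * w) / sum(w))
}

#' Fit all clustering methods over a range of k and select by ASW
#'
#' Fits Ward, PAM, and Ward-then-PAM for every `k` in `k_range`, computes the
#' weighted average silhouette width (ASW) of each solution, and returns the
#' solution with maximal ASW. Ties break toward smaller `k`, then by method
#' order `pam` > `ward_then_pam` > `ward`.
#'
#' @param diss A `medseq_diss` object.
#' @param k_range Candidate cluster counts (default 2:15, clamped to the
#'   number of unique sequences).
#' @param methods Subset of `c("pam", "ward_then_pam", "ward")`.
#' @return List with `best` (a `medseq_clust`), `asw_table` (data frame
#'   `method`, `k`, `asw`) and `solutions` (all fitted `medseq_clust`).
#' @export
select_typologies <- function(diss, k_range = 2:15,
                              methods = c("pam", "ward_then_pam", "ward")) {
  methods <- match.arg(methods, several.ok = TRUE)
  m <- nrow(diss$d)
  k_range <- k_range[k_range >= 2 & k_range <= m]
  if (!length(k_range)) stop("no admissible k in k_range")
  solutions <- list()
  rows <- list()
  for (k in k_range) {
    ward_fit <- NULL
    for (method in methods) {
      fit <- switch(method,
        ward = {
          ward_fit <- ward_fit %||% ward_cluster(diss, k)
          ward_fit
        },
        pam = pam_cluster(diss, k),
        ward_then_pam = {
          ward_fit <- ward_fit %||% ward_cluster(diss, k)
          pam_cluster(diss, k, init = ward_fit$labels)
        })
      solutions[[paste(method, k, sep = "_")]] <- fit
      rows[[paste(method, k, sep = "_")]] <-
        data.frame(method = method, k = k, asw = fit$asw,
                   stringsAsFactors = FALSE)
    }
  }
  asw_table <- do.call(rbind, rows)
  rownames(asw_table) <- NULL
  pref <- match(asw_table$method, c("pam", "ward_then_pam", "ward"))
  ord <- order(-asw_table$asw, asw_table$k, pref)
  pick <- asw_table[ord[1], ]
  best <- solutions[[paste(pick$method, pick$k, sep = "_")]]
  no_structure <- max(asw_table$asw) < 0.25
  if (no_structure)
    warning("all ASW values below 0.25: little evidence of cluster structure")
  list(best = best, asw_table = asw_table, solutions = solutions,
       no_structure = no_structure)
}

#' Name typologies from their medoid sequences
#'
#' Assigns the seven conventional typology names by the dominant
#' (modal) state of each cluster's medoid sequence, censored periods
#' excluded: a LACK-dominated medoid is "treatment failure", an AD_MONO
#' medoid "persistent antidepressant-monotherapy", and so on. A medoid with
#' a tied mode is labelled `"unclassified"` with a warning.
#'
#' @param solution A `medseq_clust` object.
#' @param diss The `medseq_diss` object it was fitted on.
#' @return Character vector of names, one per cluster id.
#' @export
name_typologies <- function(solution, diss) {
  vapply(seq_len(solution$k), function(cl) {
    med <- diss$unique_states[solution$medoids[cl], ]
    med <- med[med != "CENSORED"]
    if (!length(med)) return("unclassified")
    tab <- sort(table(med), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) {
      warning("cluster ", cl, " has a bimodal medoid; labelled unclassified")
      return("unclassified")
    }
    unname(.typology_names[names(tab)[1]])
  }, character(1))
}

#' Expand unique-sequence cluster labels back to persons
#'
#' @param solution A `medseq_clust` object.
#' @param diss The `medseq_diss` it was fitted on.
#' @return Integer labels, one per original input sequence.
#' @export
person_labels <- function(solution, diss) {
  solution$labels[diss$index]
}
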