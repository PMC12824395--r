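# two tight groups of sequences far apart, for separable-case tests
separable_diss <- function() {
  m <- rbind(matrix(rep(c(rep("LACK", 12)), 3), 3, 12, byrow = TRUE),
             matrix(rep(c(rep("LITHIUM", 12)), 3), 3, 12, byrow = TRUE))
  m[2, 12] <- "AD_MONO"; m[3, 11] <- "AD_MONO"
  m[5, 12] <- "AUGMENT"; m[6, 11] <- "AUGMENT"
  dissimilarity_matrix(m, constant_costs())
}

test_that("Ward clustering splits separable data and handles boundaries", {
  diss <- separable_diss()
  w2 <- ward_cluster(diss, 2)
  expect_equal(length(unique(w2$labels)), 2)
  lacks <- grepl("^LACK", rownames(diss$d))
  expect_equal(length(unique(w2$labels[lacks])), 1)
  expect_equal(length(unique(w2$labels[!lacks])), 1)
  # k = n: singletons
  wn <- ward_cluster(diss, nrow(diss$d))
  expect_equal(sort(unique(wn$labels)), seq_len(nrow(diss$d)))
})

test_that("PAM matches exhaustive medoid-subset search on small instances", {
  set.seed(14)
  for (rep in 1:6) {
    n <- sample(5:8, 1)
    pts <- matrix(rnorm(n * 2), n, 2)
    d <- as.matrix(dist(pts))
    w <- sample(1:3, n, replace = TRUE)
    diss <- make_diss(d, w)
    for (k in 1:3) {
      fit <- pam_cluster(diss, k)
      expect_equal(fit$objective, bf_pam_objective(d, w, k),
                   tolerance = 1e-10, info = paste("n", n, "k", k))
    }
  }
})

test_that("PAM agrees with cluster::pam on unweighted data", {
  skip_if_not_installed("cluster")
  set.seed(15)
  pts <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 4), 10, 2),
               matrix(rnorm(20, 8), 10, 2))
  d <- as.matrix(dist(pts))
  fit <- pam_cluster(make_diss(d), 3)
  ref <- cluster::pam(as.dist(d), 3)
  # cluster::pam reports the average distance to the medoid
  expect_equal(fit$objective, ref$objective[["swap"]] * nrow(d),
               tolerance = 1e-8)
  expect_equal(mclust::adjustedRandIndex(fit$labels, ref$clustering), 1)
})

test_that("weighted PAM picks a most-duplicated central sequence as medoid", {
  # line of points; heavy weight at index 2 pulls the medoid there
  d <- as.matrix(dist(c(0, 1, 2, 10)))
  fit <- pam_cluster(make_diss(d, w = c(1, 5, 1, 1)), 1)
  expect_equal(fit$medoids, 2L)
})

test_that("PAM from a perfect initial partition is a fixed point", {
  diss <- separable_diss()
  init <- c(1, 1, 1, 2, 2, 2)
  fit <- pam_cluster(diss, 2, init = init)
  expect_equal(fit$method, "ward_then_pam")
  expect_equal(mclust::adjustedRandIndex(fit$labels, init), 1)
})

test_that("silhouette matches a hand-computed four-point example", {
  d <- matrix(c(0, 1, 5, 5,
                1, 0, 5, 5,
                5, 5, 0, 1,
                5, 5, 1, 0), 4, 4)
  s <- silhouette_width(make_diss(d), c(1, 1, 2, 2))
  # a(i) = 1, b(i) = 5 for every i: s = (5-1)/5 = 0.8
  expect_equal(s$widths, rep(0.8, 4))
  expect_equal(s$asw, 0.8)
  # weighted version, manual arithmetic (weight 2 on point 1)
  sw <- silhouette_width(make_diss(d, w = c(2, 1, 1, 1)), c(1, 1, 2, 2))
  expect_equal(sw$widths, c(0.9, 0.8, 0.8, 0.8))
  expect_equal(sw$asw, (2 * 0.9 + 0.8 + 0.8 + 0.8) / 5)
})

test_that("silhouette agrees with cluster::silhouette on unweighted data", {
  skip_if_not_installed("cluster")
  set.seed(16)
  d <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  labels <- rep(1:3, each = 4)
  s <- silhouette_width(make_diss(d), labels)
  ref <- cluster::silhouette(labels, dmatrix = d)
  expect_equal(s$widths, ref[, "sil_width"], tolerance = 1e-12)
  expect_equal(s$asw, mean(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("degenerate silhouettes follow the zero conventions", {
  # all points identical, forced 2-way split: a = b = 0 -> s = 0
  d <- matrix(0, 4, 4)
  s <- silhouette_width(make_diss(d), c(1, 1, 2, 2))
  expect_equal(s$widths, rep(0, 4))
  # singleton cluster of an unweighted point -> s = 0
  d2 <- as.matrix(dist(c(0, 1, 10)))
  s2 <- silhouette_width(make_diss(d2), c(1, 1, 2))
  expect_equal(s2$widths[3], 0)
  # one cluster only -> all zero
  s3 <- silhouette_width(make_diss(d2), rep(1, 3))
  expect_equal(s3$asw, 0)
})

test_that("weighted clustering equals clustering the expanded multiset", {
  set.seed(17)
  base <- rbind(matrix(rnorm(10, 0), 5, 2), matrix(rnorm(10, 6), 5, 2))
  w <- sample(1:3, 10, replace = TRUE)
  dw <- as.matrix(dist(base))
  expanded <- base[rep(seq_len(10), w), ]
  de <- as.matrix(dist(expanded))
  orig <- rep(seq_len(10), w)
  for (k in 2:3) {
    fw <- pam_cluster(make_diss(dw, w), k)
    fe <- pam_cluster(make_diss(de), k)
    expect_equal(fw$objective, fe$objective, tolerance = 1e-10)
    expect_equal(mclust::adjustedRandIndex(fw$labels, fe$labels[match(
      seq_len(10), orig)]), 1)
    # silhouette ASW matches between weighted and expanded views
    sw <- silhouette_width(make_diss(dw, w), fw$labels)
    se <- silhouette_width(make_diss(de), fw$labels[orig])
    expect_equal(sw$asw, se$asw, tolerance = 1e-10)
    # Ward partitions of the distinct points agree too
    ww <- ward_cluster(make_diss(dw, w), k)
    we <- ward_cluster(make_diss(de), k)
    expect_equal(mclust::adjustedRandIndex(ww$labels, we$labels[match(
      seq_len(10), orig)]), 1)
  }
})

test_that("ASW selection returns the table maximum with documented ties", {
  diss <- separable_diss()
  sel <- select_typologies(diss, k_range = 2:5)
  expect_equal(sel$best$asw, max(sel$asw_table$asw))
  expect_equal(sel$best$k, 2)
  # single-archetype data (equidistant perturbations): flagged structureless
  m <- matrix("LACK", 8, 12)
  m[cbind(1:8, 1:8)] <- "AD_MONO"
  d1 <- dissimilarity_matrix(m, constant_costs())
  expect_warning(sel2 <- select_typologies(d1, k_range = 2:4),
                 "structure")
  expect_true(sel2$no_structure)
})

test_that("typology naming keys on the medoid's dominant state", {
  m <- rbind(matrix(rep(rep("LACK", 12), 3), 3, 12, byrow = TRUE),
             matrix(rep(rep("LITHIUM", 12), 3), 3, 12, byrow = TRUE))
  m[2, 1] <- "MOOD_STAB"; m[5, 1] <- "AUGMENT"
  diss <- dissimilarity_matrix(m, constant_costs())
  fit <- pam_cluster(diss, 2)
  names <- name_typologies(fit, diss)
  expect_setequal(names, c("treatment failure", "persistent lithium"))
  # a bimodal medoid cannot be named
  m2 <- rbind(c(rep("LACK", 6), rep("LITHIUM", 6)),
              c(rep("LACK", 6), rep("LITHIUM", 6)),
              rep("AD_MONO", 12))
  d2 <- dissimilarity_matrix(m2, constant_costs())
  fit2 <- pam_cluster(d2, 2)
  expect_warning(n2 <- name_typologies(fit2, d2), "bimodal")
  expect_true("unclassified" %in% n2)
})
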