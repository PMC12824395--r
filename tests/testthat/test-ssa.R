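ab <- c("A", "B", "C")

test_that("transition rates match count enumeration", {
  tr <- transition_rates(rbind(c("A", "A", "A", "B")), alphabet = ab)
  expect_equal(tr$probs["A", "A"], 2 / 3)
  expect_equal(tr$probs["A", "B"], 1 / 3)
  expect_equal(tr$counts["A", "A"], 2)
  expect_identical(tr$empty_origins, c("B", "C"))
  # constant sequence: self-transition probability 1, leave probability 0
  tr2 <- transition_rates(rbind(rep("A", 5)), alphabet = ab)
  expect_equal(tr2$probs["A", "A"], 1)
  expect_equal(unname(tr2$leave["A"]), 0)
  # pooled counts over two sequences
  tr3 <- transition_rates(rbind(c("A", "B"), c("B", "A")), alphabet = ab)
  expect_equal(tr3$probs["A", "B"], 1)
  expect_equal(tr3$probs["B", "A"], 1)
  # weights scale counts
  tr4 <- transition_rates(rbind(c("A", "B"), c("A", "A")),
                          weights = c(3, 1), alphabet = ab)
  expect_equal(tr4$probs["A", "B"], 3 / 4)
  # rows are stochastic or flagged empty
  rs <- rowSums(tr4$probs)
  expect_true(all(abs(rs[!rownames(tr4$probs) %in% tr4$empty_origins] - 1)
                  < 1e-12))
})

test_that("TRATE costs follow cval - p(i,j) - p(j,i) with zero diagonal", {
  tr <- transition_rates(rbind(c("A", "B"), c("A", "A"), c("B", "A"),
                               c("B", "B"), c("B", "B"), c("B", "B")),
                         alphabet = ab)
  # p(A->B) = 1/2, p(B->A) = 1/4
  co <- trate_costs(tr, cval = 2)
  expect_equal(co$sub["A", "B"], 2 - 0.5 - 0.25)
  expect_equal(co$sub["B", "A"], co$sub["A", "B"])
  expect_equal(unname(diag(co$sub)), rep(0, 3))
  # never-interchanged states cost the full cval
  expect_equal(co$sub["A", "C"], 2)
  expect_equal(co$indel, 1)
  # costs are floored at zero and bounded by cval
  expect_true(all(co$sub >= 0 & co$sub <= 2))
})

test_that("OM distance equals hand-checked examples", {
  co <- constant_costs(ab, cval = 2, indel = 1)
  expect_equal(om_distance(c("A", "A"), c("A", "A"), co), 0)
  expect_equal(om_distance(c("A", "A"), c("A", "B"), co), 2)
  # delete+insert (cost 2) beats two substitutions (cost 4)
  expect_equal(om_distance(c("A", "B"), c("B", "A"), co), 2)
  expect_error(om_distance(c("A", "Z"), c("A", "A"), co),
               "outside alphabet")
})

test_that("OM equals the brute-force edit-script oracle on short sequences", {
  sub <- matrix(c(0, 1.5, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
                dimnames = list(ab, ab))
  co <- structure(list(sub = sub, indel = 0.8, alphabet = ab),
                  class = "medseq_costs")
  seqs <- all_sequences(ab, 3)
  set.seed(1)
  pick <- sample(length(seqs))
  for (i in pick[1:40]) for (j in pick[1:15]) {
    a <- seqs[[i]]; b <- seqs[[j]]
    expect_equal(om_distance(a, b, co),
                 bf_edit_distance(a, b, sub, 0.8),
                 info = paste(paste(a, collapse = ""),
                              paste(b, collapse = "")))
  }
})

test_that("OM with metric costs is a pseudo-metric on random instances", {
  co <- constant_costs(medseq_alphabet, cval = 2, indel = 1)
  set.seed(5)
  m <- matrix(sample(medseq_alphabet, 15 * 12, replace = TRUE), 15, 12)
  diss <- dissimilarity_matrix(m, co)
  d <- diss$d
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("dissimilarity aggregation collapses duplicates with weights", {
  co <- constant_costs(ab, cval = 2, indel = 1)
  m <- rbind(c("A", "A"), c("A", "B"), c("A", "A"), c("A", "A"))
  diss <- dissimilarity_matrix(m, co)
  expect_equal(dim(diss$d), c(2, 2))
  expect_equal(sort(diss$weights, decreasing = TRUE), c(3, 1))
  expect_equal(sum(diss$weights), 4)
  expect_equal(diss$d[1, 2], om_distance(c("A", "A"), c("A", "B"), co))
  # identical sequences only: 1x1 zero matrix with full weight
  d1 <- dissimilarity_matrix(rbind(c("A", "A"), c("A", "A")), co)
  expect_equal(unname(d1$d), matrix(0, 1, 1))
  expect_equal(d1$weights, 2)
  # permutation invariance (canonical lexicographic order)
  d2 <- dissimilarity_matrix(m[c(2, 4, 1, 3), ], co)
  expect_equal(d2$d, diss$d)
  expect_equal(d2$weights, diss$weights)
})

test_that("entropies match closed forms and bounds", {
  # all sequences share the state at t = 1 -> 0
  m <- rbind(c("A", "A"), c("A", "B"))
  e <- transversal_entropy(m, alphabet = ab, norm_size = 3)
  expect_equal(e[1], 0)
  # 50/50 over two states with 8-state normalization
  m8 <- rbind(rep("LACK", 2), rep("AD_MONO", 2))
  e8 <- transversal_entropy(m8)
  expect_equal(e8[1], log(2) / log(8))
  # uniform over the full alphabet -> 1
  eu <- transversal_entropy(cbind(medseq_alphabet))
  expect_equal(unname(eu[1]), 1)
  # longitudinal entropy and complexity
  expect_equal(longitudinal_entropy(rep("LACK", 12)), 0)
  expect_equal(complexity_index(rep("LACK", 12)), 0)
  alt <- rep(c("LACK", "AD_MONO"), 6)
  expect_equal(longitudinal_entropy(alt), log(2) / log(8))
  expect_equal(complexity_index(alt), sqrt(log(2) / log(8)))
  set.seed(2)
  for (i in 1:20) {
    s <- sample(medseq_alphabet, 12, replace = TRUE)
    le <- longitudinal_entropy(s)
    ci <- complexity_index(s)
    expect_true(le >= 0 && le <= 1)
    expect_true(ci >= 0 && ci <= 1)
  }
})

test_that("mean time in state respects censoring denominators", {
  m <- rbind(c(rep("LACK", 6), rep("LITHIUM", 6)),
             c(rep("LITHIUM", 6), rep("CENSORED", 6)))
  mt <- mean_time_in_states(m, groups = c("g1", "g1"))
  lack <- mt[mt$state == "LACK", ]
  expect_equal(lack$mean_periods, 3)        # (6 + 0) / 2
  expect_equal(lack$mean_proportion, 0.25)  # (6/12 + 0/6) / 2
  li <- mt[mt$state == "LITHIUM", ]
  expect_equal(li$mean_proportion, 0.75)    # (6/12 + 6/6) / 2
  cens <- mt[mt$state == "CENSORED", ]
  expect_equal(cens$mean_proportion, 0.25)  # (0 + 6/12) / 2
})

test_that("time-in-state contrasts recover simulated rate ratios", {
  # two groups with identical sequences: all rate ratios 1
  m <- rbind(c(rep("LACK", 6), rep("LITHIUM", 6)),
             c(rep("LACK", 6), rep("LITHIUM", 6)))
  ct <- time_in_state_contrast(m, groups = factor(c("a", "b")),
                               states_tested = "LACK", robust = FALSE)
  expect_equal(ct$rate_ratio, 1, tolerance = 1e-8)
  # simulated 2x difference in LITHIUM time
  set.seed(8)
  n <- 300
  g <- rep(c("a", "b"), each = n)
  mk <- function(p) t(replicate(n, sample(c("LITHIUM", "LACK"), 12,
                                          replace = TRUE,
                                          prob = c(p, 1 - p))))
  m2 <- rbind(mk(0.3), mk(0.6))
  ct2 <- time_in_state_contrast(m2, groups = factor(g),
                                states_tested = "LITHIUM")
  expect_equal(ct2$rate_ratio, 2, tolerance = 0.15)
  expect_lt(ct2$p_value, 0.001)
})
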