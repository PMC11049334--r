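# exhaustive-enumeration oracle for the hypergeometric upper tail
enumUpperTail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

test_that("hypergeometric upper tail matches exhaustive enumeration (full grid N <= 12)", {
  for (N in 2:12) for (K in 1:N) for (n in 1:N) {
    for (k in 0:min(n, K)) {
      expect_equal(hypergeomUpperTail(k, n, K, N),
                   enumUpperTail(k, n, K, N), tolerance = 1e-12)
    }
  }
  # the worked example: 55/210
  expect_equal(hypergeomUpperTail(3, 4, 5, 10), 55 / 210,
               tolerance = 1e-15)
  expect_equal(hypergeomUpperTail(0, 4, 5, 10), 1)
  # full-universe draw is forced to overlap in K
  expect_equal(hypergeomUpperTail(3, 10, 3, 10), 1)
  expect_error(hypergeomUpperTail(4, 10, 3, 10), "min")
})

test_that("overlap tests count intersections within the universe", {
  universe <- sprintf("P%02d", 1:20)
  dis <- diseaseSignature("d", sprintf("P%02d", 1:5))
  # disjoint sets: k = 0, p = 1
  t0 <- overlapTest(sprintf("P%02d", 10:13), dis, universe)
  expect_identical(t0@k, 0L)
  expect_equal(t0@pValue, 1)
  # targets a subset of the disease proteins: k = n, minimal p for that n
  t1 <- overlapTest(sprintf("P%02d", 1:3), dis, universe)
  expect_identical(t1@k, t1@n)
  expect_equal(t1@pValue, enumUpperTail(3, 3, 5, 20), tolerance = 1e-12)
  expect_error(overlapTest("P01", dis, character()), "empty universe")
})

test_that("overlap p-values are super-uniform under permuted disease sets", {
  set.seed(123)
  universe <- sprintf("P%03d", 1:60)
  targets <- sample(universe, 8)
  p <- replicate(1000, overlapTest(targets,
                                   sample(universe, 10), universe)@pValue)
  # upper-tail discrete p-values: P(p <= t) <= t for every t
  for (t in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(p <= t), t + 3 * sqrt(t * (1 - t) / 1000))
  }
})

test_that("gene-set enrichment applies BH across the collection", {
  universe <- sprintf("g%02d", 1:30)
  targets <- universe[1:6]
  sets <- list(exact = targets,            # minimal attainable p
               half = universe[4:9],
               none = universe[25:30],
               outside = c("x1", "x2"))    # skipped with a warning
  expect_warning(res <- enrichGeneSets(targets, sets, universe),
                 "outside")
  expect_identical(res$set_name[1], "exact")
  expect_equal(res$p_value[1], enumUpperTail(6, 6, 6, 30),
               tolerance = 1e-12)
  expect_true(all(res$p_adjust >= res$p_value))
  expect_equal(res$p_adjust,
               stats::p.adjust(res$p_value, method = "BH"))
  # hand-computed BH step-up on (0.01, 0.02, 0.03): all become 0.03
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"),
               rep(0.03, 3))
  # disjoint targets: every p is 1
  res1 <- enrichGeneSets(universe[25:26], sets[c("exact", "half")],
                         universe)
  expect_true(all(res1$overlap == 0))
  expect_true(all(res1$p_value == 1))
})

# independent pairwise-concordance oracle for AUROC
pairwiseAuroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# independent per-rank average precision oracle (tie blocks joint)
rankwiseAupr <- function(scores, labels) {
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  ap <- 0; tp <- 0; n <- 0; i <- 1
  while (i <= length(s)) {
    j <- i
    while (j < length(s) && s[j + 1] == s[i]) j <- j + 1
    tp <- tp + sum(y[i:j]); n <- j
    ap <- ap + sum(y[i:j]) * tp / n
    i <- j + 1
  }
  ap / sum(y)
}

test_that("AUROC and AUPR reproduce the toy cases exactly", {
  s <- c(0.9, 0.8, 0.7, 0.6); y <- c(1, 0, 1, 0)
  expect_equal(aurocScore(s, y), 0.75)
  expect_equal(auprScore(s, y), 5 / 6)
  # perfectly separated
  expect_equal(aurocScore(c(3, 2, 1, 0), c(1, 1, 0, 0)), 1)
  expect_equal(auprScore(c(3, 2, 1, 0), c(1, 1, 0, 0)), 1)
  # all scores tied
  expect_equal(aurocScore(rep(1, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_error(aurocScore(1:3, c(1, 1, 1)), "positive and one negative")
  expect_error(auprScore(1:3, c(0, 0, 0)), "positive and one negative")
})

test_that("AUROC/AUPR match independent oracles on random instances, ties included", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    scores <- if (i %% 3 == 0) sample(1:5, n, replace = TRUE) / 5
              else stats::runif(n)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (sum(labels) == 0) labels[1] <- 1
    if (sum(labels) == n) labels[1] <- 0
    expect_equal(aurocScore(scores, labels), pairwiseAuroc(scores, labels),
                 tolerance = 1e-9)
    expect_equal(auprScore(scores, labels), rankwiseAupr(scores, labels),
                 tolerance = 1e-9)
  }
})

test_that("AUROC matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:100) {
    n <- sample(10:50, 1)
    scores <- stats::runif(n)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (sum(labels) == 0) labels[1] <- 1
    if (sum(labels) == n) labels[1] <- 0
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(aurocScore(scores, labels), ref, tolerance = 1e-9)
  }
})

test_that("AUROC is invariant under monotone transforms and flips under negation", {
  set.seed(5)
  scores <- stats::runif(25)
  labels <- c(rep(1, 8), rep(0, 17))
  a <- aurocScore(scores, labels)
  expect_equal(aurocScore(exp(4 * scores), labels), a, tolerance = 1e-12)
  expect_equal(aurocScore(rank(scores), labels), a, tolerance = 1e-12)
  expect_equal(aurocScore(-scores, labels), 1 - a, tolerance = 1e-12)
})

test_that("random scores give AUROC 0.5 and AUPR at its exact permutation baseline", {
  set.seed(99)
  n <- 50; P <- 10
  labels <- c(rep(1, P), rep(0, n - P))
  auc <- replicate(1000, aurocScore(stats::runif(n), labels))
  ap <- replicate(1000, auprScore(stats::runif(n), labels))
  expect_equal(mean(auc), 0.5, tolerance = 0.02)
  # exact E[AP] under uniform random ranking: the i-th positive sits at
  # rank R_i, the i-th order statistic of a uniform P-subset of 1..n,
  # so E[AP] = (1/P) sum_i E[i / R_i] -- slightly above the prevalence
  # P/n at finite n (0.257 vs 0.2 here)
  exactEAP <- local({
    tot <- 0
    for (i in 1:P) {
      r <- i:(n - P + i)
      pr <- exp(lchoose(r - 1, i - 1) + lchoose(n - r, P - i) -
                  lchoose(n, P))
      tot <- tot + sum(pr * i / r)
    }
    tot / P
  })
  expect_equal(mean(ap), exactEAP, tolerance = 0.03)
  expect_gt(exactEAP, P / n)
})

test_that("evaluateKnownPositives labels the table and returns curves", {
  sc <- data.frame(compound_id = sprintf("c%02d", 1:10),
                   name = sprintf("c%02d", 1:10),
                   n_targets_in_network = 5L,
                   score = seq(0.9, 0, length.out = 10),
                   rank = 1:10, stringsAsFactors = FALSE)
  st <- new("ScoreTable", scores = sc,
            metadata = list(disease = "d", alpha = 0.85, epsilon = 1e-6,
                            weights = edgeWeightScheme(), min_targets = 3L,
                            excluded = data.frame()))
  # positives occupy the top ranks: AUROC 1
  ev <- evaluateKnownPositives(st, c("c01", "c02", "c03"))
  expect_equal(ev@auroc, 1)
  expect_equal(ev@aupr, 1)
  expect_identical(ev@nPositive, 3L)
  expect_equal(utils::tail(ev@rocPoints, 1)$tpr, 1)
  expect_equal(utils::tail(ev@rocPoints, 1)$fpr, 1)
  expect_error(evaluateKnownPositives(st, "zzz"), "no known positive")
  # random placement: mean AUROC near 0.5 over permutations
  set.seed(13)
  m <- replicate(500, {
    pos <- sample(sc$compound_id, 3)
    evaluateKnownPositives(st, pos)@auroc
  })
  expect_equal(mean(m), 0.5, tolerance = 0.03)
})
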