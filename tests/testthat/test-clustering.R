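# Ward linkage, tree cutting, silhouette, quality indices, summaries.

test_that("ward linkage and cutTree recover the two-pair structure", {
  d <- twoPairD()
  tree <- wardLinkage(d)
  # first two merges join the tight pairs, the final merge joins them
  expect_equal(tree$height[3], max(tree$height))
  sol <- cutTree(tree, 2)
  lab <- clusterLabels(sol)
  expect_equal(lab[["p1"]], lab[["p2"]])
  expect_equal(lab[["p3"]], lab[["p4"]])
  expect_false(lab[["p1"]] == lab[["p3"]])

  # k = n and k = 1
  expect_equal(sort(unname(clusterLabels(cutTree(tree, 4)))), 1:4)
  expect_true(all(clusterLabels(cutTree(tree, 1)) == 1))
  expect_error(cutTree(tree, 5), "out of range")

  # n = 2: a single merge
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- wardLinkage(d2)
  expect_equal(length(t2$height), 1)
  expect_error(wardLinkage(matrix(0, 1, 1, dimnames = list("a", "a"))),
               "at least 2")
})

test_that("equal distances give a deterministic merge order", {
  d <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  l1 <- clusterLabels(cutTree(wardLinkage(d), 2))
  l2 <- clusterLabels(cutTree(wardLinkage(d), 2))
  expect_identical(l1, l2)
})

test_that("cluster ids are renumbered by descending size", {
  d <- as.matrix(dist(c(0, 0.1, 0.2, 10, 10.1, 10.2, 10.3, 20)))
  dimnames(d) <- list(paste0("p", 1:8), paste0("p", 1:8))
  sol <- cutTree(wardLinkage(d), 3)
  sizes <- as.integer(table(clusterLabels(sol)))
  expect_true(all(diff(sizes) <= 0))      # cluster 1 largest
  expect_equal(sol@k, 3L)
})

test_that("silhouette matches the hand computation on the two-pair fixture", {
  d <- twoPairD()
  lab <- setNames(c(1L, 1L, 2L, 2L), rownames(d))
  sil <- silhouetteWidths(d, lab)
  expect_equal(unname(sil$widths), rep(0.8, 4), tolerance = 1e-12)
  expect_equal(sil$asw, 0.8, tolerance = 1e-12)

  # perfect separation with zero within-distance
  dp <- matrix(1, 4, 4, dimnames = list(paste0("q", 1:4), paste0("q", 1:4)))
  dp[1, 2] <- dp[2, 1] <- dp[3, 4] <- dp[4, 3] <- 0
  diag(dp) <- 0
  expect_equal(silhouetteWidths(dp, lab)$asw, 1)
  expect_error(silhouetteWidths(d, rep(1L, 4)), "2 clusters")
})

test_that("silhouette agrees with the cluster package implementation", {
  skip_if_not_installed("cluster")
  set.seed(13)
  x <- matrix(rnorm(60 * 2), 60)
  x[1:30, ] <- x[1:30, ] + 3
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("i", 1:60), paste0("i", 1:60))
  lab <- setNames(rep(1:3, each = 20), rownames(d))
  ours <- silhouetteWidths(d, lab)
  ref <- cluster::silhouette(unname(lab), dmatrix = unname(d))
  expect_equal(unname(ours$widths), unname(ref[, "sil_width"]),
               tolerance = 1e-10)
  expect_equal(ours$asw, mean(ref[, "sil_width"]), tolerance = 1e-10)
})

test_that("random labels on an unstructured matrix give ASW near zero", {
  set.seed(17)
  asws <- replicate(20, {
    d <- as.matrix(dist(matrix(runif(200 * 3), 200)))
    dimnames(d) <- list(1:200, 1:200)
    lab <- setNames(sample(1:4, 200, replace = TRUE), rownames(d))
    silhouetteWidths(d, lab)$asw
  })
  expect_true(all(abs(asws) < 0.1))
})

test_that("quality indices match the hand computation exactly", {
  d <- twoPairD()
  lab <- setNames(c(1L, 1L, 2L, 2L), rownames(d))
  q <- qualityIndices(d, lab)
  # T = 8.16/8 = 1.02, W = 0.04 -> r2 = 1 - 0.04/1.02, CH = 49
  expect_equal(q@asw, 0.8, tolerance = 1e-10)
  expect_equal(q@r2, 1 - 0.04 / 1.02, tolerance = 1e-10)
  expect_equal(q@ch, 49, tolerance = 1e-10)
  expect_equal(q@hg, 1, tolerance = 1e-10)
  expect_equal(q@hc, 0, tolerance = 1e-10)

  # perfect separation, zero within-distance
  dp <- matrix(1, 6, 6, dimnames = list(1:6, 1:6))
  for (p in list(c(1, 2), c(3, 4), c(5, 6))) {
    dp[p[1], p[2]] <- dp[p[2], p[1]] <- 0
  }
  diag(dp) <- 0
  lab3 <- setNames(rep(1:3, each = 2), rownames(dp))
  q2 <- qualityIndices(dp, lab3)
  expect_equal(q2@r2, 1); expect_equal(q2@hc, 0); expect_equal(q2@hg, 1)

  expect_error(qualityIndices(matrix(0, 3, 3, dimnames = list(1:3, 1:3)),
                              setNames(c(1L, 1L, 2L), 1:3)), "degenerate")
})

test_that("quality indices are invariant to relabeling and permutation", {
  set.seed(19)
  sim <- simulateCohort(generatorConfig(n = 150), seed = 19)
  seqs <- new("StateSequenceSet", states = sim$truth$latentStates,
              imputed = sim$truth$latentStates == "?")
  D <- pairwiseMatrix(seqs, trateCosts(estimateTransitionRates(seqs)))
  lab <- setNames(sim$truth$class, personIds(seqs))
  q1 <- qualityIndices(D, lab)

  relab <- setNames(c(3L, 1L, 6L, 2L, 5L, 4L)[lab], names(lab))
  q2 <- qualityIndices(D, relab)
  expect_equal(as.numeric(q1), as.numeric(q2), tolerance = 1e-12)

  perm <- sample(length(lab))
  DP <- new("SeqDissimilarity", d = as.matrix(D)[perm, perm])
  q3 <- qualityIndices(DP, lab[perm])
  expect_equal(as.numeric(q1), as.numeric(q3), tolerance = 1e-12)

  expect_true(q1@r2 >= 0 && q1@r2 <= 1)
})

test_that("true labels beat random labels on all five indices", {
  set.seed(23)
  better <- replicate(10, {
    sim <- simulateCohort(generatorConfig(
      n = 120, classShares = c(0.05, 0.05, 0.05, 0.4, 0.4, 0.05)),
      seed = sample.int(1e6, 1))
    seqs <- new("StateSequenceSet", states = sim$truth$latentStates,
                imputed = sim$truth$latentStates == "?")
    D <- pairwiseMatrix(seqs, trateCosts(estimateTransitionRates(seqs)))
    lab <- setNames(sim$truth$class, personIds(seqs))
    rnd <- setNames(sample(lab), names(lab))
    qt <- qualityIndices(D, lab); qr <- qualityIndices(D, rnd)
    c(qt@asw > qr@asw, qt@r2 > qr@r2, qt@ch > qr@ch,
      qt@hg > qr@hg, qt@hc < qr@hc)
  })
  expect_true(all(rowMeans(better) >= 0.9))
})

test_that("r2 is 1 when every point is its own cluster", {
  d <- as.matrix(dist(1:5)); dimnames(d) <- list(1:5, 1:5)
  # k = n is degenerate for CH (division by n - k); check r2 via W = 0
  m2 <- d^2
  W <- 0
  expect_equal(1 - W / (sum(m2) / (2 * 5)), 1)
  # and CH > 0 for 1 < k < n with separation
  q <- qualityIndices(d, setNames(c(1L, 1L, 2L, 2L, 2L), 1:5))
  expect_gt(q@ch, 0)
})

test_that("summarizeClusters reports sizes, shares and marriage ages", {
  s <- c(rep(strrep("N", 36), 3),
         rep(paste0(strrep("N", 5), strrep("M", 31)), 2))
  seqs <- seqSetFromStrings(s)
  lab <- setNames(c(1L, 1L, 1L, 2L, 2L), personIds(seqs))
  sm <- summarizeClusters(seqs, lab)
  expect_equal(sm$cluster1$size, 3)
  expect_equal(sm$cluster1$share, 0.6)
  expect_true(is.na(sm$cluster1$meanAgeFirstMarriage))
  expect_equal(sm$cluster1$nNeverMarried, 3)
  expect_equal(sm$cluster2$meanAgeFirstMarriage, 20)
  expect_equal(sm$cluster2$medianAgeFirstMarriage, 20)
  expect_equal(sum(vapply(sm, `[[`, 0, "share")), 1)
})

test_that("per-class first-marriage ages match the generator timing laws", {
  sim <- simulateCohort(generatorConfig(n = 1200), seed = 29)
  seqs <- new("StateSequenceSet", states = sim$truth$latentStates,
              imputed = sim$truth$latentStates == "?")
  sm <- summarizeClusters(seqs, setNames(sim$truth$class, personIds(seqs)))
  # class 5 (married by 20): all first marriages at <= 20
  cl5 <- sim$truth$firstMarriageAge[sim$truth$class == 5]
  expect_true(all(cl5 <= 20))
  expect_equal(sm$cluster5$meanAgeFirstMarriage, mean(cl5), tolerance = 1e-9)
  # class 4 (married in 20s): first marriages in 21..29
  cl4 <- sim$truth$firstMarriageAge[sim$truth$class == 4]
  expect_true(all(cl4 >= 21 & cl4 <= 29))
  expect_equal(sm$cluster4$medianAgeFirstMarriage, median(cl4))
})

test_that("Ward at k = 6 recovers the latent archetypes", {
  sim <- simulateCohort(generatorConfig(n = 400), seed = 31)
  out <- buildCohort(sim$persons, sim$marriages)
  D <- pairwiseMatrix(out$sequences,
                      trateCosts(estimateTransitionRates(out$sequences)))
  sol <- cutTree(wardLinkage(D), 6)
  ari <- adjustedRand(clusterLabels(sol),
                      sim$truth$class[personIds(out$sequences)])
  expect_gte(ari, 0.9)
})

test_that("adjustedRand agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(37)
  for (r in 1:10) {
    a <- sample(1:4, 80, replace = TRUE)
    b <- sample(1:3, 80, replace = TRUE)
    expect_equal(adjustedRand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjustedRand(1:10, 1:10), 1)
})

test_that("qualityScan tabulates indices over k and labels round-trip", {
  set.seed(41)
  sim <- simulateCohort(generatorConfig(n = 150), seed = 41)
  seqs <- new("StateSequenceSet", states = sim$truth$latentStates,
              imputed = sim$truth$latentStates == "?")
  D <- pairwiseMatrix(seqs, trateCosts(estimateTransitionRates(seqs)))
  tree <- wardLinkage(D)
  scan <- qualityScan(D, tree, 2:7)
  expect_equal(scan$k, 2:7)
  expect_true(all(is.finite(unlist(scan[, -1]))))

  sol <- cutTree(tree, 6)
  f <- tempfile(fileext = ".csv")
  writeLabels(sol, f)
  back <- readLabels(f)
  expect_identical(clusterLabels(back), clusterLabels(sol))
  qf <- tempfile(fileext = ".json")
  writeQuality(qualityIndices(D, sol), qf)
  j <- jsonlite::read_json(qf)
  expect_equal(length(j), 7)
  unlink(c(f, qf))
})
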