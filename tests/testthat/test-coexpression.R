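test_that("spearmanDistance matches hand-computed rank correlations", {
  m <- toyMatrix(c(1, 2, 3, 4,
                   1, 3, 2, 4,
                   4, 3, 2, 1), c("x", "y", "z"), paste0("s", 1:4))
  d <- spearmanDistance(m)
  expect_equal(d["x", "y"], 1 - 0.8)       # hand rank computation
  expect_equal(d["x", "z"], 2)             # exactly reversed ordering
  expect_equal(diag(d), c(x = 0, y = 0, z = 0))
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0 & d <= 2))

  # identical ordering -> distance 0
  m2 <- toyMatrix(c(1, 2, 3, 10, 20, 30), c("a", "b"), paste0("s", 1:3))
  expect_equal(spearmanDistance(m2)["a", "b"], 0)

  # constant gene rejected by name
  m3 <- toyMatrix(c(1, 1, 1, 1, 2, 3), c("flat", "ok"), paste0("s", 1:3))
  expect_error(spearmanDistance(m3), "flat")
})

test_that("spearmanDistance is invariant under strictly monotone transforms", {
  set.seed(4)
  m <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  d0 <- spearmanDistance(m)
  m2 <- exp(m)            # strictly increasing per-gene transform
  m2[2, ] <- m[2, ]^3
  expect_equal(spearmanDistance(m2), d0)
})

test_that("wardCluster recovers planted blocks and ignores input order", {
  set.seed(7)
  # 40 samples keep the rank-correlation grid fine enough that merge
  # heights are effectively tie-free, so trees are order-invariant
  f1 <- rnorm(40); f2 <- rnorm(40)
  m <- rbind(t(replicate(10, 2 * f1 + rnorm(40, sd = 0.5))),
             t(replicate(10, 2 * f2 + rnorm(40, sd = 0.5))))
  dimnames(m) <- list(paste0("g", 1:20), paste0("s", 1:40))
  d <- spearmanDistance(m)
  tree <- wardCluster(d)
  expect_true(all(diff(tree$height) >= -1e-12))   # monotone merges
  part <- cutree(tree, 2)
  expect_equal(length(unique(part[1:10])), 1L)
  expect_equal(length(unique(part[11:20])), 1L)
  expect_true(part[1] != part[11])

  # permuting gene order leaves K = 2..5 partitions invariant up to labels
  perm <- sample(20)
  tree2 <- wardCluster(d[perm, perm])
  for (k in 2:5) {
    a <- cutree(tree, k); b <- cutree(tree2, k)[names(a)]
    expect_equal(length(unique(paste(a, b))), k)
  }

  expect_error(wardCluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  # 2 genes -> a single merge
  expect_equal(nrow(wardCluster(d[1:2, 1:2])$merge), 1L)
})

test_that("partition scores satisfy the sum-of-squares identity and bounds", {
  # two-block toy distances: within 0.1, between 1.5
  n <- 10
  d <- matrix(1.5, n, n); d[1:5, 1:5] <- 0.1; d[6:10, 6:10] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(paste0("g", 1:n), paste0("g", 1:n))
  tree <- wardCluster(d)
  sc <- scanPartitions(tree, d, 2, n)

  # brute-force oracle at K = 2: explicit double loop over all pairs
  part <- cutree(tree, 2)
  wssBrute <- 0
  for (cl in unique(part)) {
    idx <- which(part == cl)
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + d[i, j]^2
    wssBrute <- wssBrute + s / length(idx)
  }
  tssBrute <- 0
  for (i in 1:n) for (j in 1:n) if (i < j) tssBrute <- tssBrute + d[i, j]^2
  tssBrute <- tssBrute / n
  expect_equal(sc$WSS[sc$K == 2], wssBrute, tolerance = 1e-12)
  expect_equal(sc$R2[sc$K == 2], (tssBrute - wssBrute) / tssBrute,
               tolerance = 1e-12)

  # BSS + WSS = TSS at every K; R2 monotone along nested cuts; singletons
  expect_true(all(abs(sc$BSS + sc$WSS - (sc$BSS[1] + sc$WSS[1])) <
                    1e-9 * (sc$BSS[1] + sc$WSS[1])))
  expect_true(all(diff(sc$R2) >= -1e-12))
  expect_equal(sc$WSS[sc$K == n], 0)
  expect_equal(sc$R2[sc$K == n], 1)
  expect_error(scanPartitions(tree, d, 2, n + 1), "exceeds")
})

test_that("distance-identity WSS equals centroid WSS on a Euclidean embedding", {
  set.seed(21)
  x <- matrix(rnorm(16 * 3), 16, 3)          # points in R^3
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("p", 1:16), paste0("p", 1:16))
  tree <- wardCluster(d)
  sc <- scanPartitions(tree, d, 2, 5)
  for (k in 2:5) {
    part <- cutree(tree, k)
    centroidWSS <- sum(vapply(unique(part), function(cl) {
      idx <- which(part == cl)
      ctr <- colMeans(x[idx, , drop = FALSE])
      sum(sweep(x[idx, , drop = FALSE], 2, ctr)^2)
    }, 0))
    expect_equal(sc$WSS[sc$K == k], centroidWSS, tolerance = 1e-9)
  }
})

test_that("selectK finds the plateau and flags degenerate structure", {
  # planted 6 modules, strong loadings: both criteria agree on K = 6
  cfg <- simulationConfig(nGenes = 240, nCase = 40, nControl = 10,
    moduleSpecs = data.frame(size = rep(40, 6), lambdaCase = 0.9,
      lambdaControl = 0.9, traitEffect = 0, deFraction = 0,
      deDirection = "over"), noiseSd = 0.5, seed = 31)
  sim <- simulateExpression(cfg)
  d <- spearmanDistance(sim$case)
  sc <- scanPartitions(wardCluster(d), d, 2, 12)
  k <- selectK(sc, "consensus")
  expect_equal(as.integer(k), 6L)
  expect_equal(unname(attr(k, "candidates")), c(6, 6))

  # featureless cloud: no R2 plateau, so the elbow runs to the scan
  # boundary, the criteria disagree, and consensus refuses to pick a K
  set.seed(5)
  m <- matrix(rnorm(60 * 30), 60, 30,
              dimnames = list(paste0("g", 1:60), paste0("s", 1:30)))
  d0 <- spearmanDistance(m)
  sc0 <- scanPartitions(wardCluster(d0), d0, 2, 10)
  expect_error(selectK(sc0, "consensus"), "disagree")
  expect_warning(kN <- selectK(sc0, "elbow"), "boundary")
  expect_equal(as.integer(kN), 10L)

  # single-K score set returns it with a degenerate-range warning
  expect_warning(k1 <- selectK(sc[sc$K == 2, , drop = FALSE]), "degenerate")
  expect_equal(as.integer(k1), 2L)
})

test_that("moduleEigengene matches an independent PCA and orients its sign", {
  set.seed(12)
  # module of noisy copies of one profile
  base <- rnorm(10)
  m <- t(replicate(5, base))
  m <- m + matrix(rnorm(50, sd = 1e-6), 5)
  dimnames(m) <- list(paste0("g", 1:5), paste0("s", 1:10))
  e <- moduleEigengene(m, rownames(m))
  zb <- (base - mean(base)) / sd(base)
  expect_equal(abs(cor(e$values, zb)), 1, tolerance = 1e-6)
  expect_equal(e$varianceExplained, 1, tolerance = 1e-6)
  expect_equal(mean(e$values), 0, tolerance = 1e-12)
  # orientation: positively correlated with the mean standardized profile
  expect_gte(cor(e$values, zb), 0)

  # negating the data leaves any association through the eigengene intact
  # in absolute value (orientation is relative to the module's own mean)
  e2 <- moduleEigengene(-m, rownames(m))
  expect_equal(abs(cor(e2$values, e$values)), 1, tolerance = 1e-6)

  # SVD oracle on random modules (prcomp as the independent route)
  for (s in 1:10) {
    set.seed(100 + s)
    x <- matrix(rnorm(8 * 12), 8, 12,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:12)))
    eg <- moduleEigengene(x, rownames(x))
    z <- t(scale(t(x)))
    pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
    ref <- pc$x[, 1] / sqrt(sum(pc$x[, 1]^2))
    expect_equal(abs(sum(eg$values * ref)), 1, tolerance = 1e-8)
    expect_equal(eg$varianceExplained,
                 pc$sdev[1]^2 / sum(pc$sdev^2), tolerance = 1e-8)
    expect_gte(cor(eg$values, colMeans(z)), 0)
  }

  expect_error(moduleEigengene(m, c("g1", "nope")), "nope")
  mc <- m; mc[1, ] <- 7
  expect_error(moduleEigengene(mc, rownames(mc)), "constant")
})
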