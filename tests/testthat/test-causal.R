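test_that("sign composition follows the rule table in both modes", {
  # uncontested rows hold in both modes
  for (mode in c("multiplicative", "as_printed")) {
    expect_equal(composeSigns("act", "act", mode), "act")
    expect_equal(composeSigns("act", "inh", mode), "inh")
    expect_equal(composeSigns("inh", "inh", mode), "act")
  }
  # the contested (inh, act) row differs between modes
  expect_equal(composeSigns("inh", "act"), "inh")
  expect_equal(composeSigns("inh", "act", mode = "as_printed"), "act")
  # unknown absorbs
  expect_equal(composeSigns("unk", "act"), "unk")
  expect_equal(composeSigns("act", "unk"), "unk")
  # full multiplicative 3x3 table: sign group with unk absorbing
  s <- c("act", "inh", "unk")
  tab <- outer(s, s, composeSigns)
  expect_equal(tab, rbind(c("act", "inh", "unk"),
                          c("inh", "act", "unk"),
                          c("unk", "unk", "unk")))
  # associativity over all triples; act is the identity
  for (a in s) for (b in s) for (c_ in s)
    expect_equal(composeSigns(composeSigns(a, b), c_),
                 composeSigns(a, composeSigns(b, c_)))
  for (a in s) expect_equal(composeSigns("act", a), a)
  expect_error(composeSigns("act", "activates"), "invalid sign")
})

test_that("receptorTargetSets composes two-hop paths with conflicts kept", {
  reg <- Regulome(
    data.frame(source = "R", target = c("T1", "T2"), sign = c("act", "inh")),
    data.frame(source = c("T1", "T1", "T2"), target = c("g1", "g2", "g1"),
               sign = c("act", "inh", "act")))
  ts <- receptorTargetSets(reg, "R")
  # R -act-> T1 -act-> g1 gives activation; R -inh-> T2 -act-> g1 inhibition
  expect_equal(ts$activated, "g1")
  expect_equal(ts$inhibited, c("g1", "g2"))
  expect_length(ts$unknown, 0)
  expect_error(receptorTargetSets(reg, "nope"), "not present")

  # brute-force path oracle on random regulomes, both sign modes
  for (s in 1:15) {
    rr <- randomRegulome(nR = 4, nT = 6, nG = 25, nEdges = 50, seed = s)
    for (mode in c("multiplicative", "as_printed")) {
      for (r in receptors(rr)) {
        got <- receptorTargetSets(rr, r, mode = mode)
        want <- enumTargetSets(rr, r, mode = mode)
        expect_equal(got[c("activated", "inhibited", "unknown")], want)
      }
    }
  }
})

test_that("filterToExpressed prunes edges and reports entity counts", {
  reg <- Regulome(
    data.frame(source = c("R1", "R2"), target = c("T1", "T2"), sign = "act"),
    data.frame(source = c("T1", "T2"), target = c("g1", "g2"), sign = "act"))
  # everything expressed: identity
  all <- c("R1", "R2", "T1", "T2", "g1", "g2")
  f <- filterToExpressed(reg, all)
  expect_equal(receptors(f), c("R1", "R2"))
  # unexpressed receptor loses its layer-1 edges; TF survives via its own edges
  f2 <- filterToExpressed(reg, setdiff(all, "R2"))
  expect_equal(receptors(f2), "R1")
  expect_true("T2" %in% transcriptionFactors(f2))
  rep2 <- attr(f2, "report")
  expect_equal(unname(rep2["receptors_before"]), 2)
  expect_equal(unname(rep2["receptors_after"]), 1)
  expect_warning(e <- filterToExpressed(reg, character()), "no regulome edges")
  expect_length(receptors(e), 0)
})

test_that("buildSubmodules partitions modules by DE direction", {
  de <- data.frame(gene_id = paste0("g", 1:10),
                   direction = c(rep("over", 4), rep("under", 3), rep("none", 3)),
                   q = c(rep(0.01, 7), rep(0.9, 3)))
  part <- list(M1 = paste0("g", 1:10))
  sub <- buildSubmodules(part, de)
  expect_equal(sub$submodule, c("M1_o", "M1_u"))
  expect_equal(unname(lengths(sub$genes)), c(4L, 3L))
  # a module with no DE genes yields no sub-modules
  sub2 <- buildSubmodules(list(M2 = paste0("g", 8:10)), de)
  expect_equal(nrow(sub2), 0)
  # genes missing from the DE table count as "none"
  sub3 <- buildSubmodules(list(M3 = c("g1", "zz")), de)
  expect_equal(unlist(sub3$genes), "g1", ignore_attr = TRUE)
})

test_that("effectEnrichment gives closed-form and enumerated p-values", {
  u <- paste0("g", 1:20)
  ts <- list(regulator = "R", activated = u[1:5], inhibited = character(),
             unknown = character())
  # activated set identical to the sub-module: p = 1/C(20,5) = 1/15504
  r <- effectEnrichment(ts, u[1:5], u)
  expect_equal(nrow(r), 1)           # empty inhibited set is untested
  expect_equal(r$effect_sign, "positive")
  expect_equal(r$p, 1 / 15504, tolerance = 1e-12)
  # disjoint activated set with positive expectation: p = 1
  r0 <- effectEnrichment(ts, u[6:10], u)
  expect_equal(r0$p, 1)
  # enumeration oracle across all configurations with N <= 12
  for (N in c(5, 8, 12)) {
    uu <- paste0("x", 1:N)
    for (K in 1:min(4, N)) for (n in 1:min(4, N)) for (k in 0:min(K, n)) {
      if (n - k > N - K) next
      tset <- c(uu[seq_len(k)], if (n > k) rev(uu)[seq_len(n - k)])
      sub <- uu[seq_len(K)]
      if (length(intersect(tset, sub)) != k) next
      ts2 <- list(regulator = "R", activated = tset, inhibited = character(),
                  unknown = character())
      expect_equal(effectEnrichment(ts2, sub, uu)$p,
                   enumHyperUpper(k, K, N, n), tolerance = 1e-12)
    }
  }
  expect_error(effectEnrichment(ts, u[1:5], character()), "universe")
})

test_that("classifyRegulator applies the FDR direction rules", {
  expect_equal(classifyRegulator(0.01, 0.50), "act")
  expect_equal(classifyRegulator(0.50, 0.01), "inh")
  expect_equal(classifyRegulator(0.01, 0.01), "uns")
  expect_equal(classifyRegulator(0.20, 0.20), "ns")
  expect_equal(classifyRegulator(0.01, NA), "act")     # untested negative
  expect_equal(classifyRegulator(NA, NA), "ns")
})

test_that("therapeutic direction follows signature-reversion logic", {
  expect_equal(therapeuticDirection("act", "o"), "blockade")
  expect_equal(therapeuticDirection("inh", "o"), "activation")
  expect_equal(therapeuticDirection("act", "u"), "activation")
  expect_equal(therapeuticDirection("inh", "u"), "blockade")
  expect_true(is.na(therapeuticDirection("uns", "o")))
  expect_true(is.na(therapeuticDirection("ns", "u")))
})

test_that("absoluteRanking prioritizes defined effects then rank sums", {
  # an act regulator outranks an uns one despite smaller metrics
  calls <- data.frame(regulator = c("A", "B"),
                      class = c("act", "uns"),
                      activity = c(0.5, 0.9), weight = c(0.4, 0.8),
                      q = c(0.01, 0.001))
  rk <- absoluteRanking(calls)
  expect_equal(rk$regulator, c("A", "B"))
  # rank-sum tie broken by q then id
  calls2 <- data.frame(regulator = c("A", "B"),
                       class = "act",
                       activity = c(0.6, 0.3), weight = c(0.2, 0.5),
                       q = c(0.04, 0.01))
  rk2 <- absoluteRanking(calls2)
  expect_equal(unique(rk2$ranksum), 3)
  expect_equal(rk2$regulator, c("B", "A"))     # smaller q wins the tie
  # equal q falls back to lexicographic id
  calls2$q <- c(0.01, 0.01)
  expect_equal(absoluteRanking(calls2)$regulator, c("A", "B"))
  # ns regulators are excluded; single regulator gets rank 1
  calls3 <- data.frame(regulator = c("A", "Z"), class = c("act", "ns"),
                       activity = c(0.2, 0.9), weight = c(0.2, 0.9),
                       q = c(0.01, 0.9))
  rk3 <- absoluteRanking(calls3)
  expect_equal(rk3$regulator, "A")
  expect_equal(rk3$rank, 1L)
  expect_equal(nrow(absoluteRanking(calls3[0, ])), 0)
})

test_that("relativeRanking maximizes residual coverage greedily", {
  sub <- paste0("g", 1:10)
  u <- paste0("g", 1:40)
  mk <- function(set) list(regulator = NULL, activated = set,
                           inhibited = character(), unknown = character())
  tsets <- list(A = mk(paste0("g", 1:6)), B = mk(paste0("g", 5:10)))
  calls <- data.frame(regulator = c("A", "B"), class = "act",
                      activity = c(6 / 6, 6 / 6), weight = c(0.6, 0.6),
                      q = c(1e-6, 1e-5), classifyingSign = "positive")
  rel <- relativeRanking(calls, tsets, sub, u)
  expect_equal(rel$regulator, c("A", "B"))
  expect_equal(rel$gained, c(6L, 4L))
  expect_equal(rel$cumulativeCoverage, c(0.6, 1.0))

  # fully redundant second regulator contributes nothing and is listed last
  tsets2 <- list(A = mk(paste0("g", 1:6)), B = mk(paste0("g", 1:6)))
  rel2 <- relativeRanking(calls, tsets2, sub, u)
  expect_equal(rel2$gained, c(6L, 0L))
  expect_equal(rel2$cumulativeCoverage[2], 0.6)

  # a complementary pair beats a redundant high-overlap decoy on coverage
  tsets3 <- list(A = mk(paste0("g", 1:6)), B = mk(paste0("g", 7:10)),
                 C = mk(paste0("g", 1:5)))
  calls3 <- data.frame(regulator = c("A", "B", "C"), class = "act",
                       activity = c(1, 1, 1), weight = c(0.6, 0.4, 0.5),
                       q = 1e-6, classifyingSign = "positive")
  rel3 <- relativeRanking(calls3, tsets3, sub, u)
  expect_equal(rel3$regulator[1:2], c("A", "B"))
  expect_equal(rel3$cumulativeCoverage[2], 1.0)
  expect_equal(rel3$gained[3], 0L)
})

test_that("craftCausal recovers a planted driver end to end", {
  cfg <- simulationConfig(nGenes = 1200, nCase = 50, nControl = 50,
    moduleSpecs = data.frame(size = 60, lambdaCase = 0.8, lambdaControl = 0,
      traitEffect = 0, deFraction = 2 / 3, deDirection = "over"),
    regulomeSpec = list(nReceptors = 12, nTFs = 25, nTargets = 800,
                        coverage = 0.6, unkFraction = 0.1), seed = 19)
  sim <- simulateExpression(cfg)
  rg <- simulateRegulome(cfg, sim$truth)
  res <- craftCausal(rg$regulome, rownames(sim$case),
                     list(M1 = sim$truth$modules$M1),
                     deTableFromTruth(rg$truth))
  drv <- res$calls[res$calls$regulator == rg$truth$driver &
                     res$calls$submodule == "M1_o", ]
  expect_equal(drv$class, "act")
  expect_lt(drv$q, 0.05)
  expect_equal(drv$intervention, "blockade")
  expect_equal(res$rankings[["M1_o"]]$absolute$regulator[1], rg$truth$driver)
  # activity and weight are the overlap fractions of the classifying test
  tt <- res$tests[res$tests$regulator == rg$truth$driver &
                    res$tests$effect_sign == "positive", ]
  expect_equal(drv$activity, tt$k / tt$n)
  expect_equal(drv$weight, tt$k / tt$K)
  # TF-level machinery runs on the same inputs
  tfres <- craftCausal(rg$regulome, rownames(sim$case),
                       list(M1 = sim$truth$modules$M1),
                       deTableFromTruth(rg$truth), regulators = "tfs")
  expect_true(any(tfres$calls$class == "act"))
  # the driver's dedicated TFs rank at the top of the TF family
  topTF <- tfres$rankings[["M1_o"]]$absolute$regulator[1]
  drvTFs <- regulomeEdges(rg$regulome, "receptor_tf")
  drvTFs <- drvTFs$target[drvTFs$source == rg$truth$driver]
  expect_true(topTF %in% drvTFs)
})

test_that("an all-unknown regulome leaves every receptor untested", {
  reg <- Regulome(
    data.frame(source = c("R1", "R2"), target = c("T1", "T2"), sign = "unk"),
    data.frame(source = c("T1", "T2"), target = c("g1", "g2"), sign = "act"))
  expressed <- c("R1", "R2", "T1", "T2", paste0("g", 1:10))
  de <- data.frame(gene_id = paste0("g", 1:10), direction = "over", q = 0.01)
  expect_error(
    craftCausal(reg, expressed, list(M = paste0("g", 1:10)), de),
    "no testable")
})
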