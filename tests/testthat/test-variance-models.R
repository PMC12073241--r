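test_that("heritability follows the entry-mean formula and is monotone", {
  vc <- VarianceComponents(g = 0.031, gxe = 0.018, eps = 0.003,
                           nEnv = 4, nRep = 2)
  expect_equal(heritability(vc), 0.031 / (0.031 + 0.018 / 4 + 0.003 / 8))
  expect_equal(roundHalfUp(heritability(vc), 2), 0.86)
  expect_equal(heritability(VarianceComponents(g = 0.2, gxe = 0, eps = 0,
                                               nEnv = 3, nRep = 2)), 1)
  expect_equal(heritability(VarianceComponents(g = 0, gxe = 0.01,
                                               eps = 0.05, nEnv = 3,
                                               nRep = 2)), 0)
  expect_error(heritability(VarianceComponents(g = 0, gxe = 0, eps = 0,
                                               nEnv = 2, nRep = 2)),
               "undefined")
  h <- function(g, gxe, eps)
    heritability(VarianceComponents(g = g, gxe = gxe, eps = eps,
                                    nEnv = 4, nRep = 2))
  expect_gt(h(0.04, 0.018, 0.003), h(0.031, 0.018, 0.003))
  expect_lt(h(0.031, 0.030, 0.003), h(0.031, 0.018, 0.003))
  expect_lt(h(0.031, 0.018, 0.010), h(0.031, 0.018, 0.003))
})

test_that("variance shares are integer percentages of the four-term total", {
  vc <- VarianceComponents(g = 0.031, e = 0.015, gxe = 0.018,
                           eps = 0.003, nEnv = 4, nRep = 2)
  expect_equal(varianceShares(vc)[c("g", "e", "gxe")],
               c(g = 46, e = 22, gxe = 27))
  one <- VarianceComponents(g = 0.5, e = 0, gxe = 0, eps = 0,
                            nEnv = 4, nRep = 2)
  expect_equal(unname(varianceShares(one)), c(100, 0, 0, 0))
  eq <- VarianceComponents(g = 0.1, e = 0.1, gxe = 0.1, eps = 0.1,
                           nEnv = 4, nRep = 2)
  expect_equal(unname(varianceShares(eq)), rep(25, 4))
  expect_error(varianceShares(VarianceComponents(
    g = 0, e = 0, gxe = 0, eps = 0, nEnv = 4, nRep = 2)), "zero")
})

test_that("degenerate within-environment fits are handled", {
  # all observations equal: every component zero, all effects zero
  flat <- balancedGi(5, 2, gEff = rep(0, 5))
  r <- fitWithinEnv(flat)
  expect_equal(r$blup$effect, rep(0, 5))
  expect_equal(unname(varComp(r$vc)[c("g", "rep", "eps")]), c(0, 0, 0))
  # noise-free replicates: no shrinkage, BLUPs equal genotype means
  gEff <- seq(-0.2, 0.25, by = 0.05)
  clean <- balancedGi(10, 2, gEff = gEff)
  r2 <- suppressMessages(fitWithinEnv(clean))
  expect_equal(r2$blup$blup_gi, 0.4 + gEff, tolerance = 1e-10)
  expect_error(fitWithinEnv(balancedGi(1, 2, gEff = 0)),
               "fewer than 2 genotypes")
})

test_that("within-environment REML BLUPs solve Henderson's equations", {
  set.seed(11)
  d <- balancedGi(10, 2, gEff = rnorm(10, 0, 0.15),
                  repEff = c(-0.02, 0.02), noiseSd = 0.06)
  r <- fitWithinEnv(d)
  s2 <- varComp(r$vc)
  oracle <- hendersonBlup(d$gi, d$genotype_id, d$replicate,
                          s2[["g"]], s2[["rep"]], s2[["eps"]])
  expect_equal(r$blup$effect, unname(oracle$g), tolerance = 1e-6)
  expect_equal(r$mu, unname(oracle$mu), tolerance = 1e-6)
  # equivalently: shrunken genotype-mean deviations on balanced data
  gm <- tapply(d$gi, d$genotype_id, mean)
  shrink <- s2[["g"]] / (s2[["g"]] + s2[["eps"]] / 2)
  expect_equal(r$blup$effect, as.numeric(shrink * (gm - mean(d$gi))),
               tolerance = 1e-6)
  # shrinkage property: BLUP effects never exceed raw deviations
  expect_true(all(abs(r$blup$effect) <= abs(gm - mean(d$gi)) + 1e-12))
})

test_that("across-environment REML matches EMS on balanced data", {
  set.seed(3)
  G <- 25; E <- 4; R <- 2
  d <- expand.grid(genotype_id = paste0("g", 1:G),
                   environment_id = paste0("e", 1:E),
                   replicate = 1:R, stringsAsFactors = FALSE)
  g <- rnorm(G, 0, 0.18); e <- rnorm(E, 0, 0.12)
  ge <- matrix(rnorm(G * E, 0, 0.13), G)
  re <- matrix(rnorm(E * R, 0, 0.05), E)
  gi <- match(d$genotype_id, paste0("g", 1:G))
  ei <- match(d$environment_id, paste0("e", 1:E))
  d$gi <- 0.4 + g[gi] + e[ei] + ge[cbind(gi, ei)] +
    re[cbind(ei, d$replicate)] + rnorm(nrow(d), 0, 0.08)
  reml <- fitAcrossEnv(d)
  ems <- emsComponents(d)
  expect_lt(max(abs(varComp(reml$vc) - varComp(ems))), 1e-6)
  # balanced ANOVA is an exact orthogonal decomposition of the total SS
  av <- anova(lm(gi ~ genotype_id + environment_id +
                   environment_id:factor(replicate) +
                   genotype_id:environment_id, data = d))
  expect_equal(sum(av$`Sum Sq`), sum((d$gi - mean(d$gi))^2),
               tolerance = 1e-8)
  expect_equal(sum(av$Df), nrow(d) - 1)
})

test_that("across-environment REML agrees with a brute-force likelihood search", {
  set.seed(5)
  G <- 4; E <- 2; R <- 2
  d <- expand.grid(genotype_id = paste0("g", 1:G),
                   environment_id = paste0("e", 1:E),
                   replicate = 1:R, stringsAsFactors = FALSE)
  g <- rnorm(G, 0, 0.6); e <- rnorm(E, 0, 0.4)
  gi <- match(d$genotype_id, paste0("g", 1:G))
  ei <- match(d$environment_id, paste0("e", 1:E))
  ge <- matrix(rnorm(G * E, 0, 0.45), G)
  re <- matrix(rnorm(E * R, 0, 0.3), E)
  d$gi <- 1 + g[gi] + e[ei] + ge[cbind(gi, ei)] +
    re[cbind(ei, d$replicate)] + rnorm(nrow(d), 0, 0.25)
  pkg <- varComp(fitAcrossEnv(d)$vc)
  ems <- suppressMessages(varComp(emsComponents(d)))
  oracle <- bruteForceReml(d$gi, d$genotype_id, d$environment_id,
                           d$replicate,
                           starts = list(pmax(ems, 1e-4),
                                         c(0.36, 0.16, 0.2, 0.09, 0.06)))
  keep <- pkg > 1e-6  # boundary components are indistinguishable at 0
  expect_equal(pkg[keep], oracle[keep], tolerance = 1e-4)
  if (any(!keep))
    expect_lt(max(abs(pkg[!keep] - oracle[!keep])), 1e-3)
})

test_that("gxe-free noise-free trials recover a zero interaction component", {
  set.seed(21)
  G <- 12; E <- 3; R <- 2
  d <- expand.grid(genotype_id = paste0("g", 1:G),
                   environment_id = paste0("e", 1:E),
                   replicate = 1:R, stringsAsFactors = FALSE)
  gi <- match(d$genotype_id, paste0("g", 1:G))
  ei <- match(d$environment_id, paste0("e", 1:E))
  g <- rnorm(G, 0, 0.2); e <- rnorm(E, 0, 0.1)
  re <- matrix(rnorm(E * R, 0, 0.05), E)
  d$gi <- 0.4 + g[gi] + e[ei] + re[cbind(ei, d$replicate)]
  r <- fitAcrossEnv(d)
  expect_lte(varComp(r$vc)[["gxe"]], 1e-6)
  expect_lte(varComp(r$vc)[["eps"]], 1e-6)
})

test_that("single-environment input delegates to the within-environment model", {
  set.seed(2)
  d <- balancedGi(8, 2, gEff = rnorm(8, 0, 0.1), noiseSd = 0.03)
  d$environment_id <- "only"
  expect_warning(r <- fitAcrossEnv(d), "single environment")
  expect_equal(nrow(r$blup), 8)
  expect_true(is.na(varComp(r$vc)[["gxe"]]))
})

test_that("environment means get Tukey HSD letters in table order", {
  set.seed(8)
  nG <- 50
  gEff <- rnorm(nG, 0, 0.1)
  envMeans <- c(ZG2018 = 0.50, ZG2019 = 0.36, OS2020 = 0.33,
                ZG2020 = 0.19)
  blups <- do.call(rbind, lapply(names(envMeans), function(e)
    data.frame(genotype_id = sprintf("g%02d", 1:nG), environment_id = e,
               blup_gi = envMeans[e] + gEff + rnorm(nG, 0, 0.06))))
  cmp <- compareEnvMeans(blups)
  expect_equal(cmp$environment_id,
               c("ZG2018", "ZG2019", "OS2020", "ZG2020"))
  expect_equal(cmp$letter, c("a", "b", "b", "c"))
  # widely separated environments get distinct letters
  two <- data.frame(genotype_id = rep(sprintf("g%02d", 1:20), 2),
                    environment_id = rep(c("E1", "E2"), each = 20),
                    blup_gi = c(rnorm(20, 0.2, 0.01),
                                rnorm(20, 0.7, 0.01)))
  expect_equal(compareEnvMeans(two)$letter, c("a", "b"))
  # identical environments share one letter
  same <- data.frame(genotype_id = rep(sprintf("g%02d", 1:20), 2),
                     environment_id = rep(c("E1", "E2"), each = 20),
                     blup_gi = rep(rnorm(20, 0.4, 0.05), 2))
  expect_equal(unique(compareEnvMeans(same)$letter), "a")
})
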