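TABLE_COEF <- rbind(c(84.366, -13.681, 20.391, -17.321),
                    c(60.004, -11.097, 15.005, -6.976),
                    c(29.07, -4.448, 7.663, -3.308),
                    c(1.299, 0.242, -17.746, -0.104))

test_that("the built-in model carries the published 16 coefficients", {
  m <- builtinModel()
  b <- modelCoefficients(m)
  expect_equal(dim(b), c(4L, 4L))
  expect_equal(unname(b), unname(TABLE_COEF))
})

test_that("model coefficient files round-trip", {
  path <- withr::local_tempfile(fileext = ".json")
  writeModelCoefficients(builtinModel(), path)
  expect_equal(modelCoefficients(readModelCoefficients(path)),
               modelCoefficients(builtinModel()))
})

test_that("linear predictors follow the published linear form", {
  zero <- eyeModel(matrix(0, 4, 4))
  expect_equal(unname(linearPredictors(c(distm = 2, distskew = 1,
                                         lognnvar = 3), zero)),
               rep(0, 4))
  # intercept column at the feature origin
  expect_equal(unname(linearPredictors(c(distm = 0, distskew = 0,
                                         lognnvar = 0))),
               c(84.366, 60.004, 29.07, 1.299))
  # frozen hand arithmetic at (1.0, 0.5, -1.0)
  expect_equal(unname(linearPredictors(c(distm = 1.0, distskew = 0.5,
                                         lognnvar = -1.0))),
               c(98.2015, 63.3855, 31.7615, -7.228), tolerance = 1e-12)
  expect_error(linearPredictors(c(distm = NA, distskew = 0, lognnvar = 0)),
               "finite")
})

test_that("class probabilities implement the reference-class softmax", {
  zero <- eyeModel(matrix(0, 4, 4))
  expect_equal(unname(classProbabilities(c(distm = 1, distskew = 1,
                                           lognnvar = 1), zero)),
               rep(0.2, 5))
  # dominant intercept: PP0 ~ 1 at the origin
  pp0 <- classProbabilities(c(distm = 0, distskew = 0, lognnvar = 0))
  expect_gt(pp0["PP0"], 1 - 1e-10)
  # simplex for arbitrary features, including extreme ones (no overflow)
  set.seed(71)
  for (i in 1:20) {
    f <- c(distm = runif(1, -50, 50), distskew = runif(1, -50, 50),
           lognnvar = runif(1, -50, 50))
    pp <- classProbabilities(f)
    expect_true(all(is.finite(pp)))
    expect_true(all(pp >= 0))
    expect_equal(sum(pp), 1, tolerance = 1e-12)
    # agreement with the direct formula evaluated in long arithmetic
    a <- TABLE_COEF %*% c(1, f)
    direct <- exp(a - max(a, 0)) / (sum(exp(a - max(a, 0))) +
                                    exp(-max(a, 0)))
    expect_equal(unname(pp[1:4]), as.vector(direct), tolerance = 1e-12)
  }
})

test_that("IREG weights the class probabilities as published", {
  expect_equal(iregScore(c(1, 0, 0, 0, 0)), 1)
  expect_equal(iregScore(c(0, 0, 0, 0, 1)), 0)
  expect_equal(iregScore(rep(0.2, 5)), 0.5)
  expect_error(iregScore(c(0.5, 0.5)), "five")
  expect_error(iregScore(c(2, 0, 0, 0, -1)), "probabilities")
})

test_that("IREG is monotone under probability mass moving to better classes", {
  set.seed(72)
  for (i in 1:20) {
    pp <- as.vector(stats::rgamma(5, 1)); pp <- pp / sum(pp)
    from <- sample(2:5, 1); to <- sample(seq_len(from - 1), 1)
    eps <- pp[from] * runif(1)
    pp2 <- pp; pp2[from] <- pp2[from] - eps; pp2[to] <- pp2[to] + eps
    expect_gte(iregScore(pp2), iregScore(pp))
  }
})

test_that("correlation pruning eliminates redundant variables", {
  set.seed(73)
  n <- 60
  x <- rnorm(n)
  tab <- data.frame(A = x, B = x, C = rnorm(n), D = rnorm(n))
  kept <- pruneCorrelated(tab, threshold = 0.9, vars = c("A", "B", "C", "D"))
  expect_length(kept, 3L)
  expect_true(xor("A" %in% kept, "B" %in% kept))

  # independent columns survive across seeds
  for (s in 1:5) {
    set.seed(s)
    tab2 <- as.data.frame(matrix(rnorm(200 * 6), 200, 6))
    expect_length(pruneCorrelated(tab2, 0.9, vars = names(tab2)), 6L)
  }

  # planted pair r ~ 0.95 in a 5-variable table: exactly that pair reduced,
  # verified against the exhaustive pairwise correlation matrix
  set.seed(74)
  z <- rnorm(300)
  tab3 <- data.frame(V1 = z, V2 = 0.95 * z + sqrt(1 - 0.95^2) * rnorm(300),
                     V3 = rnorm(300), V4 = rnorm(300), V5 = rnorm(300))
  r <- abs(cor(tab3)); diag(r) <- 0
  expect_true(max(r) > 0.9 && max(r[-c(1, 6)]) == max(r))
  kept3 <- pruneCorrelated(tab3, 0.9, vars = names(tab3))
  expect_length(kept3, 4L)
  expect_true(all(c("V3", "V4", "V5") %in% kept3))

  # constant columns are dropped up front with a warning
  tab4 <- data.frame(K = rep(1, 30), X = rnorm(30), Y = rnorm(30))
  expect_warning(kept4 <- pruneCorrelated(tab4, 0.9, vars = names(tab4)),
                 "constant")
  expect_false("K" %in% kept4)
})

test_that("the ANOVA screen reproduces the sum-of-squares formulas", {
  # hand arithmetic: groups (1,2,3) and (5,6,7)
  tab <- data.frame(X = c(1, 2, 3, 5, 6, 7),
                    group = rep(c("a", "b"), each = 3))
  res <- anovaScreen(tab, vars = "X")
  expect_equal(res$ss_between, 24)
  expect_equal(res$ss_within, 4)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)
  expect_equal(res$F, 24)
  expect_equal(res$p, pf(24, 1, 4, lower.tail = FALSE))

  # cross-check against the standard linear-model ANOVA on random data
  set.seed(75)
  tab2 <- data.frame(X = rnorm(40), Y = rnorm(40),
                     group = sample(c("g1", "g2", "g3"), 40, replace = TRUE))
  res2 <- anovaScreen(tab2, vars = c("X", "Y"))
  for (v in c("X", "Y")) {
    ref <- anova(lm(tab2[[v]] ~ tab2$group))
    row <- res2[res2$variable == v, ]
    expect_equal(row$F, ref$`F value`[1])
    expect_equal(row$p, ref$`Pr(>F)`[1])
  }

  # zero within-variance: infinite F, p = 0
  tab3 <- data.frame(X = c(1, 1, 2, 2), group = c("a", "a", "b", "b"))
  res3 <- anovaScreen(tab3, vars = "X")
  expect_true(is.infinite(res3$F))
  expect_equal(res3$p, 0)

  # identical rows everywhere: F defined as 0
  tab4 <- data.frame(X = rep(3, 6), group = rep(c("a", "b"), each = 3))
  expect_equal(anovaScreen(tab4, vars = "X")$F, 0)
})

test_that("PC1 clustering recovers well-separated classes in order", {
  set.seed(76)
  centers <- c(-4, -2, 0, 2, 4)
  membership <- rep(1:5, each = 20)
  latent <- centers[membership] + rnorm(100, 0, 0.15)
  # DISTM rises with degeneration; the other columns echo the latent score
  tab <- data.frame(DISTM = latent + rnorm(100, 0, 0.05),
                    DISTVAR = -latent + rnorm(100, 0, 0.05),
                    LOGNNVAR = latent + rnorm(100, 0, 0.05))
  cl <- pcaCluster(tab, nClasses = 5, vars = names(tab))
  expect_equal(cl$class, membership - 1L)
  expect_equal(sum(cl$explained), 1)
  expect_gt(cl$explained[1], 0.9)
  # orientation: class 0 must sit at the low-DISTM end
  expect_lt(mean(tab$DISTM[cl$class == 0]), mean(tab$DISTM[cl$class == 4]))

  expect_equal(pcaCluster(tab, nClasses = 1, vars = names(tab))$class,
               rep(0L, 100))
  # determinism
  cl2 <- pcaCluster(tab, nClasses = 5, vars = names(tab))
  expect_identical(cl$class, cl2$class)
})

test_that("the multinomial fitter maximizes the likelihood it reports", {
  tab <- simulateModelFeatures(800, seed = 77)
  fit <- fitMultinomial(tab)
  expect_true(fit$converged)
  expect_false(fit$separated)
  expect_true(is.finite(fit$testAccuracy))
  expect_gt(fit$testAccuracy, 0.6)
  # perturbing any coefficient lowers the training log-likelihood
  train <- tab[tab$split == "train", ]
  X <- cbind(1, as.matrix(train[c("DISTM", "DISTSKEW", "LOGNNVAR")]))
  ll <- function(B) {
    A <- cbind(X %*% t(B), 0); A <- A - apply(A, 1, max)
    P <- exp(A) / rowSums(exp(A))
    sum(log(P[cbind(seq_len(nrow(X)), train$class + 1)]))
  }
  ll0 <- ll(fit$coefficients)
  set.seed(78)
  for (i in 1:8) {
    pert <- fit$coefficients
    idx <- sample(16, 1)
    pert[idx] <- pert[idx] + rnorm(1, 0, 0.3)
    expect_lte(ll(pert), ll0 + 1e-6)
  }
})

test_that("refitting on its own argmax labels is self-consistent", {
  tab <- simulateModelFeatures(600, seed = 79)
  tab$split <- "train"
  fit <- fitMultinomial(tab)
  B <- fit$coefficients
  A <- cbind(cbind(1, as.matrix(tab[c("DISTM", "DISTSKEW",
                                      "LOGNNVAR")])) %*% t(B), 0)
  tab2 <- tab
  tab2$class <- max.col(A) - 1L
  fit2 <- suppressWarnings(fitMultinomial(tab2))
  A2 <- cbind(cbind(1, as.matrix(tab2[c("DISTM", "DISTSKEW",
                                        "LOGNNVAR")])) %*%
              t(fit2$coefficients), 0)
  expect_equal(max.col(A2), max.col(A))
})

test_that("complete separation is detected and flagged", {
  tab <- data.frame(DISTM = c(rnorm(30, -3), rnorm(30, 3)),
                    DISTSKEW = 0, LOGNNVAR = 0,
                    class = rep(c(0, 1), each = 30))
  tab$DISTM <- tab$DISTM + c(-5, 5)[tab$class + 1]  # fully separable
  expect_warning(fit <- fitMultinomial(tab, "DISTM"), "separation")
  expect_true(fit$separated)
})

test_that("forward stepwise keeps informative variables and rejects noise", {
  # with a 0.05 entry threshold and four noise candidates, a ~18% per-seed
  # familywise false-entry rate is the expected behaviour of the procedure
  # itself, so noise is bounded in rate, not forbidden outright
  inf_hits <- 0; noise_total <- 0; null_ok <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    n <- 250
    x <- rnorm(n)
    noise <- matrix(rnorm(n * 4), n, 4,
                    dimnames = list(NULL, paste0("N", 1:4)))
    p <- plogis(2.5 * x)
    tab <- data.frame(INF = x, noise, class = rbinom(n, 1, p))
    sel <- suppressWarnings(
      stepwiseSelect(tab, c("INF", paste0("N", 1:4))))
    n_noise <- sum(paste0("N", 1:4) %in% sel)
    if ("INF" %in% sel) inf_hits <- inf_hits + 1
    noise_total <- noise_total + n_noise
    expect_lte(n_noise, 2)
    tab_null <- data.frame(noise, class = rbinom(n, 1, 0.5))
    sel_null <- suppressWarnings(
      stepwiseSelect(tab_null, paste0("N", 1:4)))
    if (length(sel_null) <= 1L) null_ok <- null_ok + 1
  }
  expect_gte(inf_hits, 18)
  expect_lte(noise_total, 10)  # ~0.2 expected false entries per seed
  expect_gte(null_ok, 18)

  # a single strongly informative candidate is selected
  set.seed(300)
  x <- rnorm(300)
  tab1 <- data.frame(INF = x, class = rbinom(300, 1, plogis(3 * x)))
  expect_identical(stepwiseSelect(tab1, "INF"), "INF")
})

test_that("the robustness check behaves at its degenerate settings", {
  tab <- simulateModelFeatures(400, seed = 80)
  # trainFrac 1: every split trains on all rows -> identical refits
  rc <- robustnessCheck(tab, nSplits = 2, seed = 5, trainFrac = 1)
  expect_equal(rc$maxAcrossSplitDiff, 0, tolerance = 1e-10)
  rc1 <- robustnessCheck(tab, nSplits = 1, seed = 5)
  expect_true(is.na(rc1$maxAcrossSplitDiff))
  expect_true(is.finite(rc1$betweenGroupDiff))
})

test_that("Kruskal-Wallis and Dunn agree with hand rank arithmetic", {
  res <- compareGroups(list(a = c(1, 2, 3), b = c(10, 11, 12),
                            c = c(20, 21, 22)))
  # ranks 1..9 without ties: H = 12/(9*10) * (3*4 + 3*25 + 3*64) - 3*10
  expect_equal(res$kruskal$H, 7.2, tolerance = 1e-12)
  expect_equal(res$kruskal$df, 2)
  expect_equal(res$kruskal$p, pchisq(7.2, 2, lower.tail = FALSE))
  # Dunn z for groups a vs c: (2 - 8) / sqrt((9*10/12) * (2/3))
  expect_equal(res$pairwise$z[res$pairwise$group1 == "a" &
                              res$pairwise$group2 == "c"],
               -6 / sqrt(7.5 * 2 / 3), tolerance = 1e-12)

  # identical groups: p ~ 1
  same <- compareGroups(list(a = c(5, 5, 5), b = c(5, 5, 5)))
  expect_equal(same$kruskal$H, 0)
  expect_equal(same$kruskal$p, 1)

  # rank statistics are shift-invariant
  sh <- compareGroups(list(a = c(1, 2, 3) + 100, b = c(10, 11, 12) + 100,
                           c = c(20, 21, 22) + 100))
  expect_equal(sh$kruskal$H, res$kruskal$H)
  expect_equal(sh$pairwise$z, res$pairwise$z)

  # adjustment flags
  adj <- compareGroups(list(a = c(1, 2, 3), b = c(10, 11, 12),
                            c = c(20, 21, 22)), adjust = "bonferroni")
  expect_equal(adj$pairwise$p_adjusted, pmin(adj$pairwise$p * 3, 1))
})
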