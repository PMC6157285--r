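test_that("OLS matches the closed-form normal equations", {
  fit <- fitOLS(c(0, 1, 1), cbind(intercept = 1, x = c(0, 1, 2)))
  expect_equal(fit$estimate, c(1 / 6, 0.5), tolerance = 1e-12)

  # constant response: zero slope
  fit0 <- fitOLS(rep(2, 10), cbind(intercept = 1, x = rnorm(10)))
  expect_equal(fit0$estimate[2], 0, tolerance = 1e-12)

  # exact linear response: zero residual sum of squares
  x <- 1:5
  fitx <- fitOLS(2 + 3 * x, cbind(intercept = 1, x = x))
  expect_equal(attr(fitx, "rss"), 0, tolerance = 1e-20)
})

test_that("OLS agrees with lm() on random designs", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(20:60, 1); k <- sample(2:5, 1)
    X <- cbind(1, matrix(rnorm(n * (k - 1)), n))
    colnames(X) <- paste0("c", seq_len(k))
    y <- X %*% rnorm(k) + rnorm(n)
    fit <- fitOLS(y, X)
    ref <- summary(lm(y ~ X - 1))$coefficients
    expect_equal(fit$estimate, unname(ref[, 1]), tolerance = 1e-8)
    expect_equal(fit$se, unname(ref[, 2]), tolerance = 1e-8)
    expect_equal(fit$p, unname(ref[, 4]), tolerance = 1e-8)
  }
})

test_that("OLS reports collinear columns and complete-case counts", {
  x <- rnorm(20)
  X <- cbind(intercept = 1, a = x, b = 2 * x)
  expect_error(fitOLS(rnorm(20), X), "collinear.*b")
  y <- rnorm(20); y[1:3] <- NA
  fit <- fitOLS(y, cbind(intercept = 1, x = x))
  expect_identical(attr(fit, "n"), 17L)
  expect_error(fitOLS(rnorm(3), cbind(1, rnorm(3), rnorm(3))), "complete")
})

test_that("methylation PCs match an eigendecomposition oracle", {
  set.seed(21)
  M <- matrix(rnorm(50 * 20), 50, 20)
  sc <- methylationPCs(M, 4)
  # orthogonal score columns, ordered by decreasing variance
  g <- crossprod(sc)
  expect_equal(g[upper.tri(g)], rep(0, 6), tolerance = 1e-8)
  v <- apply(sc, 2, var)
  expect_true(all(diff(v) <= 1e-12))
  # oracle: eigenvectors of the covariance of centred columns
  Mc <- scale(M, center = TRUE, scale = FALSE)
  ev <- eigen(cov(Mc), symmetric = TRUE)
  for (j in 1:4) {
    orc <- Mc %*% ev$vectors[, j]
    expect_equal(abs(sc[, j]), abs(orc), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # rank-1 matrix: one component carries ~all variance
  R <- outer(rnorm(30), rnorm(5))
  s1 <- methylationPCs(R, 1)
  expect_equal(var(as.numeric(s1)),
               sum(apply(scale(R, scale = FALSE), 2, var)),
               tolerance = 1e-8)
  expect_error(methylationPCs(R, 3), "rank")
})

test_that("genomic-control lambda behaves as a median ratio", {
  expect_equal(lambdaGC(rep(0.5, 11)), 1, tolerance = 1e-12)
  set.seed(31)
  expect_lt(abs(lambdaGC(runif(1e4)) - 1), 0.05)
  # scaling property: inflating every chi-square by 1.2 scales lambda
  # (median SE at m = 2e5 is ~0.003 on the lambda scale)
  stats <- rchisq(2e5, 1) * 1.2
  p <- pchisq(stats, 1, lower.tail = FALSE)
  expect_equal(lambdaGC(p), 1.2, tolerance = 0.01)
  expect_error(lambdaGC(numeric()), "p-values")
  expect_error(lambdaGC(c(0.5, 0)), "p-values")
})

test_that("Bonferroni threshold is alpha/m with strict-less significance", {
  expect_equal(bonferroniThreshold(0.05, 5), 0.01)
  expect_equal(bonferroniThreshold(0.05, 500), 1e-4)
  # convention check: a p-value exactly at the threshold is not significant
  p <- c(0.009, 0.01, 0.02)
  thr <- bonferroniThreshold(0.05, 5)
  expect_identical(sum(p < thr), 1L)
})

test_that("EWAS detects a strong direct CpG effect and logs TG", {
  set.seed(41)
  n <- 2000
  M <- simulateMethylation(n, 500, propensitySd = 0.5)
  logTG <- 4.7 + 0.5 * scale(M[, 1])[, 1] + rnorm(n, 0, 0.5)
  d <- data.frame(age = runif(n, 20, 80),
                  sex = sample(c("F", "M"), n, TRUE),
                  center = sample(c("MN", "SLC"), n, TRUE),
                  TG2 = exp(logTG))
  d <- cbind(d, as.data.frame(M))
  kinds <- c(age = "continuous", sex = "discrete", center = "discrete",
             TG2 = "continuous",
             setNames(rep("continuous", 500), colnames(M)))
  cohort <- cohortTable(d, kinds)
  scan <- runEWAS(cohort, visit = 2)
  res <- assocResults(scan)
  expect_identical(nrow(res), 500L)
  hit <- res[res$marker == colnames(M)[1], ]
  expect_lt(hit$p, significanceThreshold(scan))

  d$TG2[1] <- -1
  expect_error(runEWAS(cohortTable(d, kinds), visit = 2), "log")
})

test_that("EWAS keeps nominal type-I error on a null cohort", {
  sim <- simulateCohort(simConfig(nIndividuals = 1000, nNullCpgs = 500,
                                  seed = 14))
  scan <- runEWAS(sim$cohort, visit = 2)  # TG2 predates any SNP effect
  p <- assocResults(scan)$p
  frac <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / length(p))
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("change-model EWAS finds no CpG on a modification-only cohort", {
  # CpGs act only by modifying SNP effects, not through main effects
  sim <- simulateCohort(simConfig(nIndividuals = 680, nNullCpgs = 500,
                                  seed = 8))
  scan <- runEWAS(sim$cohort, changeModel = TRUE)
  res <- assocResults(scan)
  expect_true(all(res$p >= significanceThreshold(scan)))
  expect_gt(inflationFactor(scan), 0.9)
  expect_lt(inflationFactor(scan), 1.1)
})

test_that("change GWAS ranks the largest-h2 SNP first and filters MAF", {
  sim <- simulateCohort(simConfig(nIndividuals = 1000, seed = 3))
  scan <- runGWASChange(sim$cohort)
  res <- assocResults(scan)
  expect_identical(res$marker[which.min(res$p)], "rs9661059")

  # a SNP below the MAF floor is absent from the scan; monomorphic warns
  d <- cohortData(sim$cohort)
  d$rs_rare <- rbinom(nrow(d), 2, 0.005)
  d$rs_mono <- 0
  kinds <- c(varKinds(sim$cohort),
             rs_rare = "genotype", rs_mono = "genotype")
  cohort2 <- cohortTable(d, kinds)
  expect_warning(scan2 <- runGWASChange(cohort2), "monomorphic")
  expect_false("rs_rare" %in% assocResults(scan2)$marker)
  expect_false("rs_mono" %in% assocResults(scan2)$marker)
})

test_that("null change GWAS is calibrated", {
  set.seed(51)
  n <- 500
  G <- matrix(rbinom(n * 200, 2, 0.3), n, 200,
              dimnames = list(NULL, sprintf("rs%03d", 1:200)))
  d <- data.frame(age = runif(n, 20, 80),
                  sex = sample(c("F", "M"), n, TRUE),
                  center = sample(c("MN", "SLC"), n, TRUE),
                  TG2 = exp(rnorm(n, 4.7, 0.5)))
  d$TG4 <- d$TG2 * exp(rnorm(n, 0, 0.25))
  d <- cbind(d, as.data.frame(G))
  kinds <- c(age = "continuous", sex = "discrete", center = "discrete",
             TG2 = "continuous", TG4 = "continuous",
             setNames(rep("genotype", 200), colnames(G)))
  scan <- runGWASChange(cohortTable(d, kinds))
  expect_gt(inflationFactor(scan), 0.85)
  expect_lt(inflationFactor(scan), 1.15)
})

test_that("scan files carry the summary block", {
  sim <- simulateCohort(simConfig(nIndividuals = 200, seed = 4))
  scan <- runGWASChange(sim$cohort)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeScan(scan, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# lambda_gc=", lines)))
  expect_true(any(grepl("^# bonferroni=", lines)))
  tab <- read.delim(path, comment.char = "#")
  expect_identical(nrow(tab), nrow(assocResults(scan)))
})
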