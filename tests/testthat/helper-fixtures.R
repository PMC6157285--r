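# fixtures built in code; all randomness comes from the caller's seed

# bivariate Gaussian with correlation r
makeBivariate <- function(n, r) {
  x <- rnorm(n)
  y <- r * x + sqrt(1 - r^2) * rnorm(n)
  cohortTable(data.frame(X = x, Y = y),
              c(X = "continuous", Y = "continuous"))
}

# strong linear chain X -> Y -> Z
makeChain <- function(n, b = 1) {
  x <- rnorm(n)
  y <- b * x + rnorm(n)
  z <- b * y + rnorm(n)
  cohortTable(data.frame(X = x, Y = y, Z = z),
              c(X = "continuous", Y = "continuous", Z = "continuous"))
}

# random 4-node problem: one binary root + three continuous nodes whose
# parents are drawn at random among the earlier nodes
randomMixedCohort <- function(n = 150) {
  D <- sample(c("a", "b"), n, replace = TRUE)
  prev <- list(as.numeric(D == "b"))
  X <- matrix(0, n, 3)
  for (j in 1:3) {
    k <- length(prev)
    coefs <- runif(k, 0.6, 1.4) * sample(c(-1, 1), k, replace = TRUE) *
      rbinom(k, 1, 0.5)
    mu <- 0
    for (i in seq_len(k)) mu <- mu + coefs[i] * prev[[i]]
    X[, j] <- mu + rnorm(n)
    prev[[length(prev) + 1]] <- X[, j]
  }
  cohortTable(data.frame(D = D, X1 = X[, 1], X2 = X[, 2], X3 = X[, 3]),
              c(D = "discrete", X1 = "continuous", X2 = "continuous",
                X3 = "continuous"))
}

# independent brute-force DAG enumeration over all 2^(p(p-1)) digraphs,
# used as the oracle for enumerateDags(); p <= 3
bruteForceDags <- function(nodeNames, forbidInto = character()) {
  p <- length(nodeNames)
  pairs <- expand.grid(from = nodeNames, to = nodeNames,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  m <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^m - 1)) {
    sel <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    e <- as.matrix(pairs[sel, , drop = FALSE])
    if (nrow(e)) {
      if (any(e[, 2] %in% forbidInto)) next
      if (anyDuplicated(paste(pmin(e[, 1], e[, 2]),
                              pmax(e[, 1], e[, 2])))) next  # 2-cycle
      if (lipidBN:::.hasCycleEdges(e)) next
    }
    out[[length(out) + 1]] <- paste(sort(paste(e[, 1], e[, 2])),
                                    collapse = ";")
  }
  out
}

# canonical fingerprint of a dag's edge set
edgeFingerprint <- function(dag) {
  e <- dagEdges(dag)
  paste(sort(paste(e[, 1], e[, 2])), collapse = ";")
}

# a GAW20-style cohort restricted to a manageable node set
gawStyleNetworkCohort <- function(n = 500, h2Scale = 1, nCpgKeep = 2,
                                  seed = 1) {
  panel <- gaw20SnpPanel()
  panel$h2 <- pmin(panel$h2 * h2Scale, 0.9 / nrow(panel))
  sim <- simulateCohort(simConfig(nIndividuals = n, snps = panel,
                                  nNullCpgs = 0, seed = seed))
  cpgs <- panel$pairedCpg[seq_len(nCpgKeep)]
  cohort <- selectVariables(sim$cohort,
    c("TG2", "TG4", "age", "sex", "center", panel$name, cpgs))
  list(cohort = cohort,
       constraints = gaw20Constraints(snps = panel$name, cpgs = cpgs),
       truth = sim$truth, snps = panel$name, cpgs = cpgs)
}
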