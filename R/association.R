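#' AssocScan: results of a per-marker regression scan
#'
#' @slot results data.frame with one row per marker tested: `marker`,
#'   `beta`, `se`, `t`, `p`, `n`.
#' @slot lambdaGC genomic-control inflation factor of the scan.
#' @slot bonferroni Bonferroni-corrected significance threshold.
#' @slot alpha family-wise error rate used for the threshold.
#' @exportClass AssocScan
setClass("AssocScan",
  representation(results = "data.frame", lambdaGC = "numeric",
                 bonferroni = "numeric", alpha = "numeric"))

setValidity("AssocScan", function(object) {
  need <- c("marker", "beta", "se", "t", "p", "n")
  if (!all(need %in% colnames(object@results)))
    return(paste("results need columns:", paste(need, collapse = ", ")))
  p <- object@results$p
  if (any(!is.na(p) & (p <= 0 | p > 1))) return("p-values outside (0, 1]")
  TRUE
})

#' @describeIn runEWAS per-marker result table.
#' @param scan an `AssocScan`.
#' @export
assocResults <- function(scan) scan@results

#' @describeIn runEWAS genomic-control inflation factor of the scan.
#' @export
inflationFactor <- function(scan) scan@lambdaGC

#' @describeIn runEWAS Bonferroni-corrected threshold of the scan.
#' @export
significanceThreshold <- function(scan) scan@bonferroni

setMethod("show", "AssocScan", function(object) {
  cat("AssocScan:", nrow(object@results), "markers, lambda_GC =",
      format(object@lambdaGC, digits = 4), ", Bonferroni threshold =",
      format(object@bonferroni, digits = 4), "\n")
  nsig <- sum(object@results$p < object@bonferroni, na.rm = TRUE)
  cat("  markers below threshold:", nsig, "\n")
})

#' Ordinary least squares with a full coefficient table
#'
#' Complete-case least squares of `y` on a design matrix that already
#' contains its intercept. Standard errors use the residual variance with
#' `n - k` degrees of freedom; p-values are two-sided from the t
#' reference distribution.
#'
#' @param y numeric response.
#' @param design numeric matrix including the intercept column; column
#'   names label the coefficient table.
#' @return data.frame with columns `term`, `estimate`, `se`, `t`, `p`,
#'   plus attributes `n` (rows used), `df.residual` and `rss`.
#' @examples
#' fitOLS(c(0, 1, 1), cbind(intercept = 1, x = c(0, 1, 2)))
#' @export
fitOLS <- function(y, design) {
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  keep <- stats::complete.cases(y, design)
  y <- y[keep]; X <- design[keep, , drop = FALSE]
  n <- length(y); k <- ncol(X)
  if (n <= k)
    stop("need more complete observations (", n, ") than coefficients (",
         k, ")")
  qx <- qr(X)
  if (qx$rank < k) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):k]]
    stop("singular design: collinear column(s) ",
         paste(dropped, collapse = ", "))
  }
  coef <- qr.coef(qx, y)
  res <- y - X %*% coef
  rss <- sum(res^2)
  dfres <- n - k
  sigma2 <- rss / dfres
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot),
                               drop = FALSE]
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- coef / se
  pval <- 2 * stats::pt(abs(tval), dfres, lower.tail = FALSE)
  out <- data.frame(term = colnames(X), estimate = unname(coef),
                    se = unname(se), t = unname(tval), p = unname(pval))
  attr(out, "n") <- n
  attr(out, "df.residual") <- dfres
  attr(out, "rss") <- rss
  out
}

#' Principal component scores of a methylation matrix
#'
#' Columns are centred before the decomposition; scores are ordered by
#' decreasing explained variance and are mutually orthogonal.
#'
#' @param cpgMatrix individuals x CpGs numeric matrix.
#' @param k number of components.
#' @return individuals x `k` score matrix (columns `PC1`..`PCk`).
#' @export
methylationPCs <- function(cpgMatrix, k = 4) {
  cpgMatrix <- as.matrix(cpgMatrix)
  if (k < 1 || k > min(dim(cpgMatrix)))
    stop("'k' must lie in [1, min(dim)]")
  pc <- stats::prcomp(cpgMatrix, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < k ||
      pc$sdev[k] < max(pc$sdev[1], 1e-300) * 1e-10)
    stop("'k' exceeds the rank of the centred matrix")
  pc$x[, seq_len(k), drop = FALSE]
}

#' Genomic-control inflation factor
#'
#' The median of the 1-df chi-square statistics implied by the p-values,
#' divided by the null median `qchisq(0.5, 1)` (0.4549).
#'
#' @param pvalues vector of p-values in (0, 1].
#' @return The inflation factor lambda.
#' @export
lambdaGC <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (!length(pvalues)) stop("no p-values supplied")
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests. Significance is declared by strict
#'   less-than comparison of a p-value against the returned threshold.
#' @return `alpha / m`.
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (m < 1) stop("'m' must be >= 1")
  alpha / m
}

# covariate design shared by the scans: centred age + indicator columns
# for each discrete covariate level beyond the first
.covariateDesign <- function(df, covariates) {
  cols <- list()
  for (v in covariates) {
    x <- df[[v]]
    if (is.numeric(x)) {
      cols[[v]] <- x
    } else {
      x <- factor(x)
      for (lv in levels(x)[-1])
        cols[[paste0(v, lv)]] <- as.numeric(x == lv)
    }
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

.cpgColumns <- function(cohort) {
  kinds <- varKinds(cohort)
  nm <- names(kinds)[kinds == "continuous"]
  nm[grepl("^cg", nm)]
}

.scanLoop <- function(markers, outcome, baseDesign, df, alpha,
                      perMarker) {
  rows <- vector("list", length(markers))
  for (i in seq_along(markers)) {
    mk <- markers[i]
    fit <- fitOLS(outcome, cbind(marker = perMarker(mk), baseDesign))
    rows[[i]] <- data.frame(marker = mk,
                            beta = fit$estimate[1], se = fit$se[1],
                            t = fit$t[1], p = fit$p[1],
                            n = attr(fit, "n"))
  }
  res <- do.call(rbind, rows)
  new("AssocScan", results = res, lambdaGC = lambdaGC(res$p),
      bonferroni = bonferroniThreshold(alpha, nrow(res)), alpha = alpha)
}

#' Epigenome-wide association scan of (log) triglycerides on methylation
#'
#' One linear regression per CpG of log TG on the CpG beta-value, with
#' age, sex, center and the leading principal components of the CpG
#' matrix as covariates. With `changeModel = TRUE` the outcome is
#' `log(TG4)` and `log(TG2)` enters the covariates, so the scan tests
#' association with the change in TG under treatment. CpG columns are the
#' continuous columns whose name starts with `"cg"`.
#'
#' @param cohort a [CohortTable-class] with columns `TG2`/`TG4`, `age`,
#'   `sex`, `center` and CpG beta-value columns.
#' @param visit which TG measurement is the outcome (2 before, 4 after
#'   treatment); ignored when `changeModel = TRUE`.
#' @param changeModel test change in TG rather than level.
#' @param nPCs number of methylation principal components included.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @return An [AssocScan-class].
#' @export
runEWAS <- function(cohort, visit = c(2, 4), changeModel = FALSE,
                    nPCs = 4, alpha = 0.05) {
  visit <- match.arg(as.character(visit[1]), c("2", "4"))
  df <- cohortData(cohort)
  cpgs <- .cpgColumns(cohort)
  if (!length(cpgs)) stop("no CpG columns (continuous, prefix 'cg') found")
  tgCol <- if (changeModel) "TG4" else paste0("TG", visit)
  tg <- df[[tgCol]]
  if (any(!is.na(tg) & tg <= 0))
    stop("non-positive TG values cannot be log-transformed")
  outcome <- log(tg)
  M <- as.matrix(df[, cpgs, drop = FALSE])
  pcs <- if (nPCs > 0) methylationPCs(M, nPCs) else NULL
  covs <- .covariateDesign(df, intersect(c("age", "sex", "center"),
                                         varNames(cohort)))
  base <- cbind(intercept = 1, covs, pcs)
  if (changeModel) {
    tg2 <- df[["TG2"]]
    if (any(!is.na(tg2) & tg2 <= 0))
      stop("non-positive TG values cannot be log-transformed")
    base <- cbind(base, logTG2 = log(tg2))
  }
  .scanLoop(cpgs, outcome, base, df, alpha,
            perMarker = function(mk) df[[mk]])
}

#' Genome-wide scan for SNPs associated with change in TG
#'
#' One regression per SNP of `log(TG4)` on the minor-allele dosage with
#' `log(TG2)`, age, sex and center as covariates; including the
#' pre-treatment level as a covariate makes the dosage coefficient a test
#' of association with the change in TG under treatment. SNPs are
#' filtered to minor allele frequency strictly greater than `mafFilter`
#' before testing; SNPs monomorphic after filtering are skipped with a
#' warning.
#'
#' @param cohort a [CohortTable-class] with genotype columns.
#' @param mafFilter minor-allele-frequency floor (exclusive).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @return An [AssocScan-class].
#' @export
runGWASChange <- function(cohort, mafFilter = 0.01, alpha = 0.05) {
  df <- cohortData(cohort)
  kinds <- varKinds(cohort)
  snps <- names(kinds)[kinds == "genotype"]
  if (!length(snps)) stop("no genotype columns found")
  keep <- character()
  for (s in snps) {
    g <- df[[s]]
    f <- mean(g, na.rm = TRUE) / 2
    maf <- min(f, 1 - f)
    if (maf == 0) {
      warning("skipping monomorphic SNP '", s, "'")
    } else if (maf > mafFilter) {
      keep <- c(keep, s)
    }
  }
  if (!length(keep))
    stop("no SNP passes the MAF filter (> ", mafFilter, ")")
  tg2 <- df[["TG2"]]; tg4 <- df[["TG4"]]
  if (any(!is.na(tg2) & tg2 <= 0) || any(!is.na(tg4) & tg4 <= 0))
    stop("non-positive TG values cannot be log-transformed")
  covs <- .covariateDesign(df, intersect(c("age", "sex", "center"),
                                         varNames(cohort)))
  base <- cbind(intercept = 1, logTG2 = log(tg2), covs)
  .scanLoop(keep, log(tg4), base, df, alpha,
            perMarker = function(mk) df[[mk]])
}

#' Write a scan result as TSV with a summary block
#'
#' The per-marker table is preceded by `#`-prefixed summary lines giving
#' the marker count, the genomic-control lambda and the Bonferroni
#' threshold.
#'
#' @param scan an [AssocScan-class].
#' @param path output path.
#' @export
writeScan <- function(scan, path) {
  .writeAtomic(function(p) {
    con <- file(p, "w"); on.exit(close(con))
    writeLines(c(sprintf("# markers=%d", nrow(scan@results)),
                 sprintf("# lambda_gc=%.17g", scan@lambdaGC),
                 sprintf("# alpha=%.17g", scan@alpha),
                 sprintf("# bonferroni=%.17g", scan@bonferroni)), con)
    utils::write.table(.formatFull(scan@results), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  }, path)
}
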