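#' Specification of one simulated causal SNP
#'
#' @param name SNP identifier.
#' @param h2 target heritability of the drug response attributable to the
#'   SNP's additive effect, in `[0, 1)`.
#' @param maf minor allele frequency; the generator enforces the common
#'   analysis floor of 0.01.
#' @param pairedCpg identifier of the CpG whose methylation modifies the
#'   SNP effect, or `NA` for none.
#' @return A one-row data.frame (`snpSpec`) or the default five-SNP panel
#'   (`gaw20SnpPanel`): five drug-response SNPs with heritabilities 0.125,
#'   0.075, 0.100, 0.025 and 0.050, each paired with one CpG.
#' @export
snpSpec <- function(name, h2, maf = 0.3, pairedCpg = NA_character_) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(h2) || h2 < 0 || h2 >= 1)
    stop("'h2' must lie in [0, 1)")
  if (!is.numeric(maf) || maf < 0.01 || maf > 0.5)
    stop("'maf' must lie in [0.01, 0.5]")
  data.frame(name = name, maf = maf, h2 = h2,
             pairedCpg = as.character(pairedCpg))
}

#' @rdname snpSpec
#' @export
gaw20SnpPanel <- function() {
  rbind(
    snpSpec("rs9661059",  0.125, pairedCpg = "cg00000363"),
    snpSpec("rs736004",   0.075, pairedCpg = "cg10480950"),
    snpSpec("rs1012116",  0.100, pairedCpg = "cg18772399"),
    snpSpec("rs10828412", 0.025, pairedCpg = "cg00045910"),
    snpSpec("rs4399565",  0.050, pairedCpg = "cg01242676"))
}

#' Configuration for the synthetic drug-response cohort generator
#'
#' The generator emulates a two-visit lipid-lowering drug trial:
#' log-normal pre-treatment triglycerides (TG2), a post-treatment level
#' (TG4) shifted by a mean drug effect plus additive effects of causal
#' SNPs, each effect modified by the methylation of a paired CpG, CpG
#' beta-values with a shared per-individual methylation propensity, and
#' age/sex/center covariates.
#'
#' @param nIndividuals cohort size.
#' @param snps data.frame of causal SNPs as built by [snpSpec()] /
#'   [gaw20SnpPanel()]; total h2 must stay below 1.
#' @param nNullCpgs number of CpGs with no role in the response.
#' @param methylationPropensitySd std-dev (logit scale) of the shared
#'   per-individual methylation shift; 0 gives independent CpGs.
#' @param tg2LogMean,tg2LogSd log-scale mean and std-dev of TG2.
#' @param drugMeanEffect mean treatment shift of log TG.
#' @param residualSd std-dev of the unexplained log-TG4 residual.
#' @param covariateEffects named numeric `c(age=, sex=, center=)`: slopes
#'   of centred age and of the sex/center indicators on log TG4.
#' @param modificationMode how a paired CpG's beta-value M modifies the
#'   SNP effect: `"proportional"` (per-allele effect scales with M),
#'   `"complement"` (scales with 1 - M) or `"none"` (no epigenetic
#'   modification; the SNP acts purely additively, so each SNP explains
#'   exactly its configured h2 of the response variance).
#' @param seed integer RNG seed; identical configurations reproduce the
#'   cohort byte for byte.
#' @return A validated configuration list of class `"SimConfig"`.
#' @export
simConfig <- function(nIndividuals = 680,
                      snps = gaw20SnpPanel(),
                      nNullCpgs = 10,
                      methylationPropensitySd = 1,
                      tg2LogMean = log(110),
                      tg2LogSd = 0.5,
                      drugMeanEffect = -0.2,
                      residualSd = 0.25,
                      covariateEffects = c(age = 0, sex = 0, center = 0),
                      modificationMode = c("proportional", "complement",
                                           "none"),
                      seed = 1L) {
  modificationMode <- match.arg(modificationMode)
  stopifnot(nIndividuals >= 1, nNullCpgs >= 0,
            methylationPropensitySd >= 0)
  if (tg2LogSd <= 0 || residualSd <= 0)
    stop("'tg2LogSd' and 'residualSd' must be positive")
  if (any(snps$h2 < 0) || any(snps$h2 >= 1) || sum(snps$h2) >= 1)
    stop("per-SNP h2 must lie in [0, 1) and sum to < 1")
  if (any(snps$maf < 0.01 | snps$maf > 0.5))
    stop("SNP minor allele frequencies must lie in [0.01, 0.5]")
  ce <- c(age = 0, sex = 0, center = 0)
  ce[names(covariateEffects)] <- covariateEffects
  nm <- c(snps$name, snps$pairedCpg[!is.na(snps$pairedCpg)])
  if (anyDuplicated(nm))
    stop("duplicate SNP/CpG names in configuration")
  structure(list(nIndividuals = as.integer(nIndividuals), snps = snps,
                 nNullCpgs = as.integer(nNullCpgs),
                 methylationPropensitySd = methylationPropensitySd,
                 tg2LogMean = tg2LogMean, tg2LogSd = tg2LogSd,
                 drugMeanEffect = drugMeanEffect, residualSd = residualSd,
                 covariateEffects = ce,
                 modificationMode = modificationMode,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Sample Hardy-Weinberg genotype dosages
#'
#' Dosages (minor-allele counts 0/1/2) are drawn with Hardy-Weinberg
#' proportions \eqn{(1-p)^2, 2p(1-p), p^2}. Uses R's global RNG stream.
#'
#' @param maf minor allele frequency in `[0.01, 0.5]` (the analysis floor
#'   of 0.01 is enforced here as in the association scans).
#' @param n number of individuals.
#' @return Integer vector of dosages.
#' @examples
#' set.seed(1)
#' table(simulateGenotypes(0.2, 1000))
#' @export
simulateGenotypes <- function(maf, n) {
  if (!is.numeric(maf) || length(maf) != 1 || maf < 0.01 || maf > 0.5)
    stop("'maf' must be a single frequency in [0.01, 0.5]")
  if (n < 1) stop("'n' must be >= 1")
  stats::rbinom(n, 2L, maf)
}

#' Sample CpG beta-values with a shared methylation propensity
#'
#' Beta-values are generated on the logit scale as
#' \eqn{logit(M_{ij}) = \mu_j + a_i + e_{ij}} with per-CpG baselines
#' \eqn{\mu_j \sim U(-2, 2)}, a per-individual propensity
#' \eqn{a_i \sim N(0, propensitySd^2)} shared across CpGs, and unit-variance
#' site noise. The shared propensity makes individuals with high methylation
#' at one site tend to be high everywhere, inducing positive inter-CpG
#' correlation.
#'
#' @param n individuals.
#' @param nCpg number of CpG sites.
#' @param propensitySd std-dev of the shared propensity (logit scale).
#' @param cpgNames optional column names.
#' @return `n` x `nCpg` matrix with entries strictly inside (0, 1).
#' @export
simulateMethylation <- function(n, nCpg, propensitySd = 1,
                                cpgNames = NULL) {
  if (n < 1 || nCpg < 1) stop("'n' and 'nCpg' must be >= 1")
  if (propensitySd < 0) stop("'propensitySd' must be >= 0")
  mu <- stats::runif(nCpg, -2, 2)
  a <- stats::rnorm(n, 0, propensitySd)
  e <- matrix(stats::rnorm(n * nCpg), n, nCpg)
  m <- stats::plogis(sweep(e + a, 2, mu, `+`))
  colnames(m) <- if (is.null(cpgNames))
    sprintf("cg_sim_%05d", seq_len(nCpg)) else cpgNames
  m
}

#' Calibrate a per-allele effect size to a target heritability
#'
#' Under an additive model the variance explained by a SNP with dosage
#' variance \eqn{2\,maf(1-maf)} and per-allele effect \eqn{\beta} is
#' \eqn{\beta^2 \cdot 2\,maf(1-maf)}. The effect reproducing a target
#' heritability h2 of a response with variance `totalVar` is therefore
#' \deqn{\beta = \sqrt{h2 \cdot totalVar / (2\,maf(1-maf))}.}
#'
#' @param h2 target heritability in `[0, 1)`.
#' @param maf minor allele frequency in (0, 0.5].
#' @param totalVar variance of the drug-response scale.
#' @return Effect per minor allele on the log-TG-change scale.
#' @examples
#' calibrateEffectSize(0.125, 0.3, 1) # ~0.5455
#' @export
calibrateEffectSize <- function(h2, maf, totalVar = 1) {
  if (!is.numeric(h2) || any(h2 < 0) || any(h2 >= 1))
    stop("'h2' must lie in [0, 1)")
  vG <- 2 * maf * (1 - maf)
  if (any(vG <= 0)) stop("genotype variance 2*maf*(1-maf) must be positive")
  sqrt(h2 * totalVar / vG)
}

#' Simulate a drug-response cohort with a machine-readable truth record
#'
#' Generates `id`, `age` (Uniform(20, 80)), `sex` and `center` (balanced
#' two-level factors), pre-treatment `TG2` (log-normal), post-treatment
#' `TG4`, one dosage column per SNP and one beta-value column per CpG
#' (paired + null). On the log scale,
#' \deqn{\log TG4 = \log TG2 + \delta + \sum_k \beta_k G_k m(M_k)
#'       + \gamma' z + \varepsilon,}
#' where \eqn{\delta} is the mean drug effect, \eqn{G_k} the dosage,
#' \eqn{m(M)} the methylation modifier (`M`, `1 - M`, or the constant 1
#' under `modificationMode = "none"`), \eqn{z} the centred covariates and
#' \eqn{\varepsilon \sim N(0, residualSd^2)}. Effect sizes \eqn{\beta_k}
#' are calibrated with [calibrateEffectSize()] against `totalVar`, the
#' response variance implied by the configuration under
#' `modificationMode = "none"`, so that in that regime each SNP explains
#' exactly its configured h2.
#'
#' @param config a [simConfig()] object.
#' @return A list with elements `cohort` ([CohortTable-class]) and `truth`
#'   ([SimTruth-class]).
#' @export
simulateCohort <- function(config) {
  if (!inherits(config, "SimConfig"))
    stop("'config' must be built with simConfig()")
  set.seed(config$seed)
  n <- config$nIndividuals
  snps <- config$snps
  ce <- config$covariateEffects

  age <- stats::runif(n, 20, 80)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  center <- sample(c("MN", "SLC"), n, replace = TRUE)
  logTG2 <- stats::rnorm(n, config$tg2LogMean, config$tg2LogSd)

  G <- matrix(0L, n, nrow(snps), dimnames = list(NULL, snps$name))
  for (k in seq_len(nrow(snps))) G[, k] <- simulateGenotypes(snps$maf[k], n)
  pairedNames <- snps$pairedCpg[!is.na(snps$pairedCpg)]
  nullNames <- if (config$nNullCpgs)
    sprintf("cg_null_%05d", seq_len(config$nNullCpgs)) else character()
  M <- simulateMethylation(n, length(pairedNames) + length(nullNames),
                           config$methylationPropensitySd,
                           cpgNames = c(pairedNames, nullNames))

  # response variance under the no-epigenetics regime: solves
  # totalVar = sum(h2)*totalVar + var(covariate terms) + residualSd^2
  covVar <- ce[["age"]]^2 * (60^2 / 12) + ce[["sex"]]^2 * 0.25 +
    ce[["center"]]^2 * 0.25
  totalVar <- (config$residualSd^2 + covVar) / (1 - sum(snps$h2))
  beta <- calibrateEffectSize(snps$h2, snps$maf, totalVar)

  snpTerm <- 0
  for (k in seq_len(nrow(snps))) {
    mod <- switch(config$modificationMode,
      proportional = if (is.na(snps$pairedCpg[k])) 1
                     else M[, snps$pairedCpg[k]],
      complement   = if (is.na(snps$pairedCpg[k])) 1
                     else 1 - M[, snps$pairedCpg[k]],
      none         = 1)
    snpTerm <- snpTerm + beta[k] * G[, k] * mod
  }
  logTG4 <- logTG2 + config$drugMeanEffect + snpTerm +
    ce[["age"]] * (age - 50) + ce[["sex"]] * (sex == "M") +
    ce[["center"]] * (center == "SLC") +
    stats::rnorm(n, 0, config$residualSd)

  df <- data.frame(id = sprintf("ind%05d", seq_len(n)), age = age,
                   sex = sex, center = center,
                   TG2 = exp(logTG2), TG4 = exp(logTG4),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(G), as.data.frame(M))
  kinds <- c(id = "id", age = "continuous", sex = "discrete",
             center = "discrete", TG2 = "continuous", TG4 = "continuous",
             stats::setNames(rep("genotype", ncol(G)), colnames(G)),
             stats::setNames(rep("continuous", ncol(M)), colnames(M)))

  causal <- snps$h2 > 0
  edges <- data.frame(from = "TG2", to = "TG4")
  if (any(causal)) {
    edges <- rbind(edges,
                   data.frame(from = snps$name[causal], to = "TG4"))
    if (config$modificationMode != "none") {
      cp <- snps$pairedCpg[causal & !is.na(snps$pairedCpg)]
      if (length(cp))
        edges <- rbind(edges, data.frame(from = cp, to = "TG4"))
    }
  }
  truth <- new("SimTruth",
               snps = cbind(snps[, c("name", "maf", "h2")], beta = beta,
                            pairedCpg = snps$pairedCpg),
               edges = edges,
               params = list(totalVar = unname(totalVar),
                             modificationMode = config$modificationMode,
                             drugMeanEffect = config$drugMeanEffect,
                             residualSd = config$residualSd,
                             tg2LogMean = config$tg2LogMean,
                             tg2LogSd = config$tg2LogSd,
                             covariateEffects = ce,
                             nIndividuals = n, seed = config$seed))
  list(cohort = cohortTable(df, kinds), truth = truth)
}

#' @describeIn simulateCohort accessors for the truth record.
#' @param truth a `SimTruth`.
#' @export
truthSnps <- function(truth) truth@snps

#' @describeIn simulateCohort causal edge list of the generating model.
#' @export
truthEdges <- function(truth) truth@edges

#' @describeIn simulateCohort generator parameters, including `totalVar`.
#' @export
truthParams <- function(truth) truth@params

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@snps), "causal SNPs,",
      nrow(object@edges), "causal edges, mode",
      object@params$modificationMode, "\n")
})

#' Write a truth record as TSV
#'
#' Emits the causal edge list, a per-SNP block (name, maf, h2, realized
#' beta, paired CpG) and a `key=value` parameter block.
#'
#' @param truth a [SimTruth-class].
#' @param path output path.
#' @export
writeTruth <- function(truth, path) {
  .writeAtomic(function(p) {
    con <- file(p, "w"); on.exit(close(con))
    writeLines("# causal edges", con)
    utils::write.table(truth@edges, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines("# snps", con)
    utils::write.table(.formatFull(truth@snps), con, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    writeLines("# parameters", con)
    fmt <- function(v) if (is.double(v)) sprintf("%.17g", v)
                       else as.character(v)
    pars <- truth@params
    lines <- character()
    for (nm in names(pars)) {
      v <- pars[[nm]]
      if (length(v) > 1) {
        lines <- c(lines, sprintf("%s.%s=%s", nm, names(v),
                                  vapply(v, fmt, "")))
      } else {
        lines <- c(lines, sprintf("%s=%s", nm, fmt(v)))
      }
    }
    writeLines(lines, con)
  }, path)
}
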