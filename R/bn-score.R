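#' Decomposable conditional-Gaussian BIC local score
#'
#' Scores one node given a parent set on complete-case data, on the
#' convention `logLik - (k/2) * log(n)` (higher is better).
#'
#' For a continuous child the model is one Gaussian linear regression on
#' the continuous parents per configuration of the discrete parents; the
#' log-likelihood is summed over configurations at the maximum-likelihood
#' variance, and the parameter count is
#' `#configurations * (1 + #continuous parents + 1)` (intercept, slopes
#' and a variance per configuration), configurations counted over the
#' full cross-product of the discrete parents' levels. A configuration
#' observed fewer than twice cannot support a variance estimate: it
#' contributes zero log-likelihood and a warning is raised.
#'
#' For a discrete child (whose parents must all be discrete under the CG
#' restriction) the model is a multinomial per parent configuration with
#' `(#levels - 1) * prod(parent levels)` parameters.
#'
#' @param child node name.
#' @param parents character vector of parent node names (may be empty).
#' @param network a node mapping from [asNodes()], or a
#'   [CohortTable-class] (mapped with default options).
#' @return The local score (log scale), with attributes `logLik`, `k` and
#'   `n`.
#' @examples
#' d <- data.frame(x = rnorm(50), g = rep(c("a", "b"), 25))
#' ct <- cohortTable(d, c(x = "continuous", g = "discrete"))
#' localScore("x", "g", ct)
#' @export
localScore <- function(child, parents, network) {
  if (is(network, "CohortTable")) network <- asNodes(network)
  kind <- stats::setNames(network$nodes$kind, network$nodes$name)
  if (!child %in% names(kind)) stop("unknown node '", child, "'")
  if (!all(parents %in% names(kind)))
    stop("unknown parent node(s): ",
         paste(setdiff(parents, names(kind)), collapse = ", "))
  if (kind[[child]] == "discrete" && any(kind[parents] == "continuous"))
    stop("CG restriction violated: discrete node '", child,
         "' cannot have continuous parent(s)")
  .scoreNode(child, parents, .compileNetwork(network))
}

# flatten the model frame into numeric/integer vectors once; the search
# evaluates thousands of local scores, so data.frame subsetting is kept
# out of the inner loop
.compileNetwork <- function(network) {
  frame <- network$frame
  kind <- stats::setNames(network$nodes$kind, network$nodes$name)
  cols <- list()
  for (v in network$nodes$name) {
    if (kind[[v]] == "continuous") {
      x <- as.numeric(frame[[v]])
      cols[[v]] <- list(x = x, na = is.na(x))
    } else {
      f <- frame[[v]]
      code <- as.integer(f)
      cols[[v]] <- list(code = code, nlev = nlevels(f), na = is.na(code))
    }
  }
  list(cols = cols, kind = kind)
}

.degenerateWarning <- function(child, what) {
  warning(warningCondition(paste0(
    what, " for node '", child, "': zero likelihood contribution"),
    class = "lipidBN_degenerateConfig"))
}

.scoreNode <- function(child, parents, comp) {
  cols <- comp$cols
  na <- cols[[child]]$na
  for (p in parents) na <- na | cols[[p]]$na
  use <- which(!na)
  n <- length(use)
  if (n < 2) stop("fewer than 2 complete rows for node '", child, "'")
  discPar <- parents[comp$kind[parents] == "discrete"]
  contPar <- parents[comp$kind[parents] == "continuous"]

  nConfig <- 1L
  gid <- NULL
  if (length(discPar)) {
    gid <- 0L
    for (p in discPar) {
      cp <- cols[[p]]
      nConfig <- nConfig * cp$nlev
      gid <- gid * cp$nlev + (cp$code[use] - 1L)
    }
  }

  if (is.null(cols[[child]]$code)) {          # continuous child
    k <- nConfig * (1L + length(contPar) + 1L)
    y <- cols[[child]]$x[use]
    X <- if (length(contPar)) {
      m <- matrix(1, n, 1L + length(contPar))
      for (j in seq_along(contPar))
        m[, j + 1L] <- cols[[contPar[j]]]$x[use]
      m
    } else NULL
    groups <- if (length(discPar))
      split.default(seq_len(n), gid) else list(seq_len(n))
    ll <- 0
    for (idx in groups) {
      nc <- length(idx)
      if (nc < 2) {
        .degenerateWarning(child, "degenerate parent configuration")
        next
      }
      sigma2 <- if (is.null(X)) {
        yg <- y[idx]
        sum((yg - sum(yg) / nc)^2) / nc
      } else {
        fit <- stats::.lm.fit(X[idx, , drop = FALSE], y[idx])
        sum(fit$residuals^2) / nc
      }
      if (!is.finite(sigma2) || sigma2 <= 0) {
        .degenerateWarning(child, "zero residual variance")
        next
      }
      ll <- ll + (-nc / 2 * (log(2 * pi * sigma2) + 1))
    }
  } else {                                    # discrete child
    code <- cols[[child]]$code[use]
    nLev <- cols[[child]]$nlev
    k <- (nLev - 1L) * nConfig
    if (length(discPar)) {
      cell <- gid * nLev + (code - 1L)
      cts <- tabulate(cell + 1L, nConfig * nLev)
      ncfg <- tabulate(gid + 1L, nConfig)
      denom <- rep(ncfg, each = nLev)
      pos <- cts > 0
      ll <- sum(cts[pos] * log(cts[pos] / denom[pos]))
    } else {
      cts <- tabulate(code, nLev)
      pos <- cts > 0
      ll <- sum(cts[pos] * log(cts[pos] / n))
    }
  }
  score <- ll - k / 2 * log(n)
  attr(score, "logLik") <- ll
  attr(score, "k") <- k
  attr(score, "n") <- n
  score
}

# memoised scorer keyed by (child | sorted parents), shared across one
# search or one exhaustive enumeration
.makeScorer <- function(network) {
  comp <- .compileNetwork(network)
  cache <- new.env(parent = emptyenv())
  function(child, parents) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    # the search legitimately probes parent sets with sparse discrete
    # cells; those are penalised through the zero likelihood contribution
    s <- withCallingHandlers(
      as.numeric(.scoreNode(child, parents, comp)),
      lipidBN_degenerateConfig = function(w)
        invokeRestart("muffleWarning"))
    cache[[key]] <- s
    s
  }
}
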