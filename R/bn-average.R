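#' Refit the network on bootstrap resamples
#'
#' Draws `B` bootstrap resamples of the individuals (rows, with
#' replacement), runs [hillClimb()] on each under the same constraints,
#' and returns the fitted DAGs. Randomness uses R's global RNG stream.
#'
#' @inheritParams hillClimb
#' @param B number of bootstrap replicates (the conventional default is
#'   1000).
#' @param restarts random restarts per replicate; the full restart
#'   schedule can be expensive inside the bootstrap, so this is
#'   configurable down to 0.
#' @return List of `B` [BNDag-class] objects, each satisfying
#'   [validateDag()] under `constraints`.
#' @export
bootstrapNetworks <- function(cohort, constraints = bnConstraints(),
                              B = 1000, restarts = 1, perturb = NULL,
                              genotypesAs = c("discrete", "continuous")) {
  if (B < 1) stop("'B' must be >= 1")
  network <- if (is(cohort, "CohortTable"))
    asNodes(cohort, match.arg(genotypesAs)) else cohort
  n <- nrow(network$frame)
  out <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    resample <- network
    resample$frame <- network$frame[idx, , drop = FALSE]
    scorer <- .makeScorer(resample)
    fit <- .hillClimbEngine(resample, constraints, scorer, restarts,
                            perturb, tol = 1e-9)
    out[[b]] <- fit@dag
  }
  out
}

#' Per-edge strength and direction over a set of networks
#'
#' For every unordered node pair the *strength* is the proportion of
#' networks containing the edge in either direction; the *direction*
#' probability of an orientation is the proportion of that orientation
#' among the networks where the edge is present, so the two orientations
#' of a pair always sum to 1. Pairs present in no network have strength
#' 0 and `NA` direction.
#'
#' @param dags list of [BNDag-class] objects over one common node set
#'   (e.g. from [bootstrapNetworks()]).
#' @return An [AverageNetwork-class] (no threshold applied yet). Its edge
#'   table holds each pair once, oriented by its majority direction.
#' @export
edgeStatistics <- function(dags) {
  if (!length(dags)) stop("need at least one network")
  nm <- sort(dags[[1]]@nodes$name)
  for (d in dags)
    if (!identical(sort(d@nodes$name), nm))
      stop("networks do not share one node set")
  B <- length(dags)
  counts <- new.env(parent = emptyenv())
  for (d in dags) {
    e <- d@edges
    for (i in seq_len(nrow(e))) {
      key <- paste(e[i, 1], e[i, 2], sep = "\r")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  seen <- ls(counts)
  if (!length(seen)) {
    edges <- data.frame(from = character(), to = character(),
                        strength = numeric(), direction = numeric(),
                        retained = logical())
    return(new("AverageNetwork", edges = edges, threshold = NA_real_,
               B = B))
  }
  parts <- do.call(rbind, strsplit(seen, "\r", fixed = TRUE))
  pairKey <- paste(pmin(parts[, 1], parts[, 2]),
                   pmax(parts[, 1], parts[, 2]), sep = "\r")
  rows <- list()
  for (pk in unique(pairKey)) {
    ab <- strsplit(pk, "\r", fixed = TRUE)[[1]]
    fwd <- counts[[paste(ab[1], ab[2], sep = "\r")]] %||% 0L
    bwd <- counts[[paste(ab[2], ab[1], sep = "\r")]] %||% 0L
    present <- fwd + bwd
    # orient by majority; ties keep lexicographic order
    if (bwd > fwd) ab <- rev(ab)
    rows[[pk]] <- data.frame(
      from = ab[1], to = ab[2], strength = present / B,
      direction = max(fwd, bwd) / present, retained = TRUE)
  }
  edges <- do.call(rbind, rows)
  rownames(edges) <- NULL
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  new("AverageNetwork", edges = edges, threshold = NA_real_, B = B)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn edgeStatistics edge table of an average network.
#' @param avg an `AverageNetwork`.
#' @export
avgEdges <- function(avg) avg@edges

#' @describeIn edgeStatistics strength cutoff of an average network
#'   (`NA` before filtering).
#' @export
strengthCutoff <- function(avg) avg@threshold

#' @describeIn edgeStatistics direction probability of one orientation,
#'   `NA` when the pair was never present.
#' @param from,to node names of the orientation queried.
#' @export
directionProbability <- function(avg, from, to) {
  e <- avg@edges
  i <- which(e$from == from & e$to == to)
  if (length(i)) return(e$direction[i])
  j <- which(e$from == to & e$to == from)
  if (length(j)) return(1 - e$direction[j])
  NA_real_
}

setMethod("show", "AverageNetwork", function(object) {
  cat("AverageNetwork over", object@B, "networks:",
      nrow(object@edges), "node pairs")
  if (!is.na(object@threshold))
    cat(",", sum(object@edges$retained), "retained at strength >",
        format(object@threshold, digits = 3))
  cat("\n")
})

#' Significance threshold for edge strengths
#'
#' An ideal averaged network would give every significant edge strength
#' 1 and every noise edge strength 0, so its strength ECDF is a two-level
#' step function. The estimator returns the cutoff `t*` whose induced
#' two-level CDF (value = proportion of strengths at or below `t*` on
#' `[0, 1)`, then 1) is closest in L1 distance to the empirical CDF of
#' the observed strengths, minimised by brute force over the observed
#' strength values. Edges with strength strictly greater than `t*` are
#' considered significant.
#'
#' @param strengths numeric vector of strengths in `[0, 1]`.
#' @return The cutoff `t*`.
#' @examples
#' strengthThreshold(c(0.05, 0.1, 0.9, 0.95)) # 0.1: retains the top two
#' @export
strengthThreshold <- function(strengths) {
  if (!length(strengths)) stop("no strengths supplied")
  if (any(strengths < 0 | strengths > 1))
    stop("strengths must lie in [0, 1]")
  # candidate cutoffs: the observed strengths plus 0 (retain everything)
  cand <- unique(c(0, sort(unique(strengths))))
  # ECDF of strengths as step heights over segments of [0, 1]
  knots <- unique(c(0, cand, 1))
  heights <- stats::ecdf(strengths)(knots)
  segW <- diff(c(knots, 1))            # width of [knot_i, knot_{i+1})
  l1 <- vapply(cand, function(tt) {
    f <- mean(strengths <= tt)
    sum(abs(heights - f) * segW)
  }, 0)
  best <- cand[l1 <= min(l1) + 1e-12]
  best[1]
}

#' Apply a strength cutoff to an average network
#'
#' Pairs with strength strictly greater than the cutoff are retained,
#' each oriented by its majority direction; strengths and direction
#' probabilities are left untouched.
#'
#' @param avg an [AverageNetwork-class].
#' @param cutoff strength cutoff in `[0, 1]`, e.g. from
#'   [strengthThreshold()].
#' @return The network with its `retained` flags and `threshold` set.
#' @export
filterAverage <- function(avg, cutoff) {
  if (cutoff < 0 || cutoff > 1) stop("'cutoff' must lie in [0, 1]")
  e <- avg@edges
  e$retained <- e$strength > cutoff
  new("AverageNetwork", edges = e, threshold = cutoff, B = avg@B)
}

#' Write an average network as TSV
#'
#' Columns: from, to, strength, direction, retained (0/1); rows ordered
#' by node pair.
#'
#' @param avg an [AverageNetwork-class].
#' @param path output path.
#' @export
writeAverageNetwork <- function(avg, path) {
  e <- avg@edges
  e$retained <- as.integer(e$retained)
  .writeAtomic(function(p) {
    con <- file(p, "w"); on.exit(close(con))
    writeLines(c(sprintf("# B=%d", as.integer(avg@B)),
                 sprintf("# threshold=%s",
                         if (is.na(avg@threshold)) "NA"
                         else sprintf("%.17g", avg@threshold))), con)
    utils::write.table(.formatFull(e), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }, path)
}
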