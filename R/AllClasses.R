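#' @import methods
NULL

.VALID_KINDS <- c("continuous", "discrete", "genotype", "id")

#' CohortTable: rectangular individuals-by-variables store
#'
#' A thin S4 container around a `data.frame` of one row per individual,
#' carrying a per-column kind: `"continuous"` (numeric), `"discrete"`
#' (factor/character), `"genotype"` (minor-allele dosage 0/1/2) or `"id"`
#' (identifier, excluded from modelling). Missing values are `NA`.
#'
#' @slot data data.frame of measurements, one row per individual.
#' @slot kinds named character vector, one entry per column of `data`.
#' @exportClass CohortTable
setClass("CohortTable",
  representation(data = "data.frame", kinds = "character"))

setValidity("CohortTable", function(object) {
  msg <- character()
  if (is.null(names(object@kinds)) ||
      !identical(sort(names(object@kinds)), sort(colnames(object@data))))
    msg <- c(msg, "'kinds' must be named after every column of 'data'")
  bad <- setdiff(object@kinds, .VALID_KINDS)
  if (length(bad))
    msg <- c(msg, paste0("unknown column kind(s): ",
                         paste(unique(bad), collapse = ", ")))
  if (length(msg) == 0) {
    for (v in names(object@kinds)) {
      k <- object@kinds[[v]]
      x <- object@data[[v]]
      if (k %in% c("continuous") && !is.numeric(x))
        msg <- c(msg, paste0("continuous column '", v, "' is not numeric"))
      if (k == "genotype") {
        if (!is.numeric(x) || !all(x[!is.na(x)] %in% 0:2))
          msg <- c(msg, paste0("genotype column '", v,
                               "' must hold dosages 0/1/2"))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' BNConstraints: structural constraints for network search
#'
#' Whitelist edges must be present with the stated direction in every
#' network considered; blacklist edges may never be present; no-parent
#' nodes may not receive any incoming edge.
#'
#' @slot whitelist two-column character matrix (from, to).
#' @slot blacklist two-column character matrix (from, to).
#' @slot noParents character vector of node names.
#' @exportClass BNConstraints
setClass("BNConstraints",
  representation(whitelist = "matrix", blacklist = "matrix",
                 noParents = "character"))

.edgeKey <- function(m) paste(m[, 1], m[, 2], sep = "\r")

setValidity("BNConstraints", function(object) {
  msg <- character()
  for (s in c("whitelist", "blacklist")) {
    m <- slot(object, s)
    if (!is.character(m) || ncol(m) != 2)
      msg <- c(msg, paste0("'", s, "' must be a two-column character matrix"))
  }
  if (!length(msg)) {
    wl <- object@whitelist; bl <- object@blacklist
    if (nrow(wl) && anyDuplicated(.edgeKey(wl)))
      msg <- c(msg, "duplicate whitelist edges")
    if (nrow(wl) && nrow(bl) && length(intersect(.edgeKey(wl), .edgeKey(bl))))
      msg <- c(msg, "whitelist and blacklist overlap")
    if (nrow(wl) && any(wl[, 2] %in% object@noParents))
      msg <- c(msg, "whitelist edge enters a no-parent node")
    if (nrow(wl) && any(wl[, 1] == wl[, 2]))
      msg <- c(msg, "whitelist contains a self-loop")
    if (nrow(wl) && .hasCycleEdges(wl))
      msg <- c(msg, "whitelist edges alone contain a cycle")
  }
  if (length(msg)) msg else TRUE
})

#' BNDag: directed acyclic graph over typed nodes
#'
#' Nodes are typed `"continuous"` or `"discrete"`; discrete nodes carry a
#' level set. The conditional-Gaussian restriction applies: a discrete node
#' never has a continuous parent.
#'
#' @slot nodes data.frame with columns `name`, `kind`; attribute-free.
#' @slot levels named list of level vectors for discrete nodes.
#' @slot edges two-column character matrix of (parent, child) pairs.
#' @exportClass BNDag
setClass("BNDag",
  representation(nodes = "data.frame", levels = "list", edges = "matrix"))

setValidity("BNDag", function(object) {
  msg <- character()
  nd <- object@nodes
  if (!all(c("name", "kind") %in% colnames(nd)))
    msg <- c(msg, "'nodes' needs columns 'name' and 'kind'")
  else {
    if (anyDuplicated(nd$name)) msg <- c(msg, "duplicate node names")
    if (!all(nd$kind %in% c("continuous", "discrete")))
      msg <- c(msg, "node kind must be 'continuous' or 'discrete'")
    disc <- nd$name[nd$kind == "discrete"]
    for (v in disc)
      if (is.null(object@levels[[v]]) || length(object@levels[[v]]) < 2)
        msg <- c(msg, paste0("discrete node '", v, "' needs >= 2 levels"))
    e <- object@edges
    if (!is.character(e) || ncol(e) != 2)
      msg <- c(msg, "'edges' must be a two-column character matrix")
    else if (nrow(e)) {
      if (!all(c(e) %in% nd$name)) msg <- c(msg, "edge endpoint not a node")
      if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-loop")
      if (anyDuplicated(.edgeKey(e))) msg <- c(msg, "duplicate edges")
      kind <- stats::setNames(nd$kind, nd$name)
      if (any(kind[e[, 1]] == "continuous" & kind[e[, 2]] == "discrete"))
        msg <- c(msg, "a discrete node has a continuous parent")
      if (.hasCycleEdges(e)) msg <- c(msg, "graph contains a cycle")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ScoredNetwork: a DAG with its decomposed BIC score
#'
#' @slot dag the [BNDag-class].
#' @slot localScores named numeric, one BIC contribution per node.
#' @slot total sum of the local scores.
#' @exportClass ScoredNetwork
setClass("ScoredNetwork",
  representation(dag = "BNDag", localScores = "numeric", total = "numeric"))

setValidity("ScoredNetwork", function(object) {
  if (!isTRUE(all.equal(unname(object@total), sum(object@localScores),
                        tolerance = 1e-9)))
    return("'total' does not equal the sum of the local scores")
  if (!identical(sort(names(object@localScores)),
                 sort(object@dag@nodes$name)))
    return("local scores must be named after the dag nodes")
  TRUE
})

#' AverageNetwork: bootstrap-averaged network
#'
#' Per unordered node pair: the strength (proportion of bootstrap networks
#' containing the edge in either direction) and the direction probability
#' of the `from -> to` orientation among replicates where the edge is
#' present. Pairs never observed have strength 0 and `NA` direction.
#'
#' @slot edges data.frame with columns `from`, `to`, `strength`,
#'   `direction`, `retained`.
#' @slot threshold strength cutoff applied (NA before filtering).
#' @slot B bootstrap replicate count.
#' @exportClass AverageNetwork
setClass("AverageNetwork",
  representation(edges = "data.frame", threshold = "numeric", B = "numeric"))

setValidity("AverageNetwork", function(object) {
  e <- object@edges
  need <- c("from", "to", "strength", "direction", "retained")
  if (!all(need %in% colnames(e)))
    return(paste0("'edges' needs columns ", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (any(e$strength < 0 | e$strength > 1)) return("strength outside [0,1]")
    d <- e$direction[!is.na(e$direction)]
    if (any(d < 0 | d > 1)) return("direction outside [0,1]")
  }
  TRUE
})

#' SimTruth: generating model behind a simulated cohort
#'
#' @slot snps data.frame with one row per simulated causal SNP: `name`,
#'   `maf`, `h2`, `beta` (realized effect per minor allele on the log-TG
#'   change scale), `pairedCpg`.
#' @slot edges data.frame of causal edges (`from`, `to`).
#' @slot params list of generator parameters, including `totalVar` (the
#'   variance of log-TG change used for effect-size calibration), the
#'   modification mode and the seed.
#' @exportClass SimTruth
setClass("SimTruth",
  representation(snps = "data.frame", edges = "data.frame", params = "list"))

setValidity("SimTruth", function(object) {
  if (!all(c("name", "maf", "h2", "beta", "pairedCpg") %in%
           colnames(object@snps)))
    return("'snps' is missing required columns")
  causal <- object@snps$name[object@snps$h2 > 0]
  have <- object@edges$from[object@edges$to == "TG4"]
  if (!all(causal %in% have))
    return("causal edge list must contain SNP->TG4 for every SNP with h2 > 0")
  TRUE
})
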