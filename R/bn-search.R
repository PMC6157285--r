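#' Construct a typed DAG
#'
#' @param nodes data.frame with columns `name` and `kind`
#'   (`"continuous"`/`"discrete"`), or a node mapping from [asNodes()].
#' @param edges two-column matrix/data.frame of (parent, child) pairs, or
#'   `NULL` for an empty graph.
#' @param levels named list of level vectors for discrete nodes (taken
#'   from the mapping when `nodes` comes from [asNodes()]).
#' @return A [BNDag-class].
#' @export
bnDag <- function(nodes, edges = NULL, levels = list()) {
  if (is.list(nodes) && !is.data.frame(nodes) &&
      all(c("nodes", "levels") %in% names(nodes))) {
    levels <- nodes$levels
    nodes <- nodes$nodes
  }
  new("BNDag", nodes = nodes[, c("name", "kind")], levels = levels,
      edges = .asEdgeMatrix(edges))
}

#' @describeIn bnDag node table of a DAG.
#' @param dag a `BNDag`.
#' @export
dagNodes <- function(dag) dag@nodes

#' @describeIn bnDag edge matrix (parent, child) of a DAG.
#' @export
dagEdges <- function(dag) dag@edges

#' @describeIn bnDag parents of one node.
#' @param node node name.
#' @export
dagParents <- function(dag, node) {
  e <- dag@edges
  unname(e[e[, 2] == node, 1])
}

setMethod("show", "BNDag", function(object) {
  cat("BNDag:", nrow(object@nodes), "nodes,", nrow(object@edges),
      "edges\n")
  if (nrow(object@edges)) {
    e <- apply(object@edges, 1, paste, collapse = " -> ")
    cat(" ", paste(utils::head(e, 10), collapse = "; "),
        if (length(e) > 10) "..." else "", "\n")
  }
})

#' @describeIn hillClimb DAG of a scored network.
#' @param x a `ScoredNetwork`.
#' @export
networkDag <- function(x) x@dag

#' @describeIn hillClimb total BIC score of a scored network.
#' @export
networkScore <- function(x) x@total

#' @describeIn hillClimb per-node local scores of a scored network.
#' @export
localScores <- function(x) x@localScores

setMethod("show", "ScoredNetwork", function(object) {
  cat("ScoredNetwork: total BIC score",
      format(object@total, digits = 8), "\n")
  show(object@dag)
})

# ---- validation -------------------------------------------------------------

#' Check a DAG against structural rules and constraints
#'
#' Reports every violation: cycles, the conditional-Gaussian restriction
#' (discrete node with a continuous parent), missing whitelist edges,
#' present blacklist edges and parents of no-parent nodes.
#'
#' @param dag a [BNDag-class].
#' @param constraints a [BNConstraints-class].
#' @return Character vector of violation messages; length zero when the
#'   DAG satisfies everything.
#' @export
validateDag <- function(dag, constraints = bnConstraints()) {
  msg <- character()
  e <- dag@edges
  kind <- stats::setNames(dag@nodes$kind, dag@nodes$name)
  if (nrow(e)) {
    if (.hasCycleEdges(e)) msg <- c(msg, "cycle: graph is not acyclic")
    cg <- kind[e[, 1]] == "continuous" & kind[e[, 2]] == "discrete"
    if (any(cg))
      msg <- c(msg, sprintf(
        "CG restriction: continuous parent of discrete node (%s -> %s)",
        e[cg, 1], e[cg, 2]))
  }
  keys <- if (nrow(e)) .edgeKey(e) else character()
  wl <- constraints@whitelist
  if (nrow(wl)) {
    miss <- !(.edgeKey(wl) %in% keys)
    if (any(miss))
      msg <- c(msg, sprintf("missing whitelist edge: %s -> %s",
                            wl[miss, 1], wl[miss, 2]))
  }
  bl <- constraints@blacklist
  if (nrow(bl)) {
    hit <- .edgeKey(bl) %in% keys
    if (any(hit))
      msg <- c(msg, sprintf("blacklisted edge present: %s -> %s",
                            bl[hit, 1], bl[hit, 2]))
  }
  if (length(constraints@noParents) && nrow(e)) {
    bad <- e[, 2] %in% constraints@noParents
    if (any(bad))
      msg <- c(msg, sprintf("no-parent node has parent: %s -> %s",
                            e[bad, 1], e[bad, 2]))
  }
  msg
}

# ---- neighbourhood ----------------------------------------------------------

# constraint lookup tables for the inner loops
.constraintIndex <- function(constraints) {
  list(wl = .edgeKey(constraints@whitelist),
       bl = .edgeKey(constraints@blacklist),
       np = constraints@noParents)
}

# can edge u -> v exist at all (ignoring acyclicity)?
.edgeAllowed <- function(u, v, kind, cidx) {
  if (u == v) return(FALSE)
  if (v %in% cidx$np) return(FALSE)
  if (kind[[u]] == "continuous" && kind[[v]] == "discrete") return(FALSE)
  if (paste(u, v, sep = "\r") %in% cidx$bl) return(FALSE)
  TRUE
}

#' Enumerate the valid single-edge moves from a DAG
#'
#' Lists every add, delete and reverse of one edge that yields a DAG
#' respecting acyclicity, the conditional-Gaussian restriction and the
#' constraints; whitelist edges are never deleted or reversed. The order
#' is deterministic: operation type (add, delete, reverse), then parent,
#' then child, lexicographically.
#'
#' @param dag a [BNDag-class].
#' @param constraints a [BNConstraints-class].
#' @return data.frame with columns `op` (`add`/`delete`/`reverse`),
#'   `from`, `to`.
#' @export
dagNeighbors <- function(dag, constraints = bnConstraints()) {
  nodes <- sort(dag@nodes$name)
  kind <- stats::setNames(dag@nodes$kind, dag@nodes$name)
  adj <- .adjFromEdges(dag@nodes$name, dag@edges)
  cidx <- .constraintIndex(constraints)
  adds <- dels <- revs <- list()
  for (u in nodes) for (v in nodes) {
    if (u == v) next
    key <- paste(u, v, sep = "\r")
    if (!adj[u, v]) {
      if (adj[v, u]) next  # reverse of v->u handled at (v, u)
      if (.edgeAllowed(u, v, kind, cidx) && !.reaches(adj, v, u))
        adds[[length(adds) + 1]] <- c("add", u, v)
    } else {
      if (key %in% cidx$wl) next
      dels[[length(dels) + 1]] <- c("delete", u, v)
      if (.edgeAllowed(v, u, kind, cidx)) {
        adj[u, v] <- FALSE
        ok <- !.reaches(adj, u, v)
        adj[u, v] <- TRUE
        if (ok) revs[[length(revs) + 1]] <- c("reverse", u, v)
      }
    }
  }
  out <- do.call(rbind, c(adds, dels, revs))
  if (is.null(out))
    return(data.frame(op = character(), from = character(),
                      to = character()))
  data.frame(op = out[, 1], from = out[, 2], to = out[, 3])
}

.applyOp <- function(edges, op, from, to) {
  if (op == "add") return(rbind(edges, c(from, to)))
  hit <- edges[, 1] == from & edges[, 2] == to
  if (op == "delete") return(edges[!hit, , drop = FALSE])
  edges[hit, ] <- c(to, from)  # reverse
  edges
}

# ---- hill climbing ----------------------------------------------------------

#' Learn a network structure by constrained hill climbing
#'
#' Greedy search over single-edge moves maximising the decomposable
#' conditional-Gaussian BIC score ([localScore()]). The search starts
#' from the constraint-minimal graph (whitelist edges only), repeatedly
#' applies the best strictly score-improving move (ties within `tol`
#' broken uniformly at random) until no move improves, then performs
#' `restarts` random restarts: the local optimum is perturbed by
#' `perturb` random valid edge additions/deletions and re-climbed, and
#' the best-scoring network seen is returned. Randomness uses R's global
#' RNG stream; call `set.seed()` for reproducibility.
#'
#' @param cohort a [CohortTable-class] (every column must map to a node;
#'   drop identifier columns first) or a node mapping from [asNodes()].
#' @param constraints a [BNConstraints-class].
#' @param restarts number of random restarts (default 10).
#' @param perturb number of random perturbation moves per restart;
#'   default twice the node count.
#' @param genotypesAs treat genotype columns as `"discrete"` (levels
#'   0/1/2, the default) or `"continuous"` dosages.
#' @param tol score-tie tolerance.
#' @return A [ScoredNetwork-class]; its DAG satisfies [validateDag()].
#' @export
hillClimb <- function(cohort, constraints = bnConstraints(),
                      restarts = 10, perturb = NULL,
                      genotypesAs = c("discrete", "continuous"),
                      tol = 1e-9) {
  network <- if (is(cohort, "CohortTable"))
    asNodes(cohort, match.arg(genotypesAs)) else cohort
  scorer <- .makeScorer(network)
  .hillClimbEngine(network, constraints, scorer, restarts, perturb, tol)
}

.hillClimbEngine <- function(network, constraints, scorer, restarts,
                             perturb, tol) {
  nodeNames <- network$nodes$name
  kind <- stats::setNames(network$nodes$kind, nodeNames)
  cidx <- .constraintIndex(constraints)
  if (length(bad <- setdiff(c(constraints@whitelist,
                              constraints@blacklist, constraints@noParents),
                            nodeNames)))
    stop("constraint references unknown node(s): ",
         paste(unique(bad), collapse = ", "))
  if (is.null(perturb)) perturb <- 2L * length(nodeNames)

  template <- bnDag(network, edges = constraints@whitelist)

  climb <- function(edges) {
    dag <- template; dag@edges <- edges
    local <- vapply(nodeNames,
                    function(v) scorer(v, dagParents(dag, v)), 0)
    repeat {
      ops <- dagNeighbors(dag, constraints)
      if (!nrow(ops)) break
      delta <- numeric(nrow(ops))
      for (i in seq_len(nrow(ops))) {
        from <- ops$from[i]; to <- ops$to[i]
        pa <- dagParents(dag, to)
        delta[i] <- switch(ops$op[i],
          add = scorer(to, c(pa, from)) - local[[to]],
          delete = scorer(to, setdiff(pa, from)) - local[[to]],
          reverse = (scorer(to, setdiff(pa, from)) - local[[to]]) +
            (scorer(from, c(dagParents(dag, from), to)) - local[[from]]))
      }
      best <- max(delta)
      if (best <= tol) break
      pick <- which(delta >= best - tol)
      i <- if (length(pick) > 1) sample(pick, 1) else pick
      from <- ops$from[i]; to <- ops$to[i]
      dag@edges <- .applyOp(dag@edges, ops$op[i], from, to)
      local[[to]] <- scorer(to, dagParents(dag, to))
      if (ops$op[i] == "reverse")
        local[[from]] <- scorer(from, dagParents(dag, from))
    }
    list(dag = dag, local = local, total = sum(local))
  }

  cur <- climb(template@edges)
  best <- cur
  for (r in seq_len(restarts)) {
    edges <- cur$dag@edges
    dag <- template
    for (j in seq_len(perturb)) {
      dag@edges <- edges
      ops <- dagNeighbors(dag, constraints)
      ops <- ops[ops$op != "reverse", , drop = FALSE]
      if (!nrow(ops)) break
      i <- sample(nrow(ops), 1)
      edges <- .applyOp(edges, ops$op[i], ops$from[i], ops$to[i])
    }
    cur <- climb(edges)
    if (cur$total > best$total) best <- cur
  }
  new("ScoredNetwork", dag = best$dag,
      localScores = best$local[network$nodes$name], total = best$total)
}

# ---- exhaustive oracle ------------------------------------------------------

#' Enumerate every DAG over a small node set
#'
#' Brute-force enumeration over the three states (absent, forward,
#' backward) of each unordered node pair, filtered for acyclicity, the
#' conditional-Gaussian restriction and the constraints. Guarded to at
#' most 5 nodes.
#'
#' @param nodes node table (or [asNodes()] mapping, or [BNDag-class])
#'   supplying names, kinds and levels.
#' @param constraints a [BNConstraints-class].
#' @return List of [BNDag-class] objects, duplicate-free, in a fixed
#'   enumeration order.
#' @export
enumerateDags <- function(nodes, constraints = bnConstraints()) {
  template <- if (is(nodes, "BNDag")) nodes else bnDag(nodes)
  nm <- sort(template@nodes$name)
  p <- length(nm)
  if (p > 5) stop("enumeration is limited to 5 nodes (got ", p, ")")
  kind <- stats::setNames(template@nodes$kind, template@nodes$name)
  cidx <- .constraintIndex(constraints)
  pairs <- if (p >= 2) utils::combn(nm, 2) else
    matrix(character(), nrow = 2)
  nPairs <- ncol(pairs)
  # per-pair admissible states: 0 absent, 1 a->b, 2 b->a
  states <- vector("list", max(nPairs, 1))
  wlKeys <- cidx$wl
  for (j in seq_len(nPairs)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    st <- 0L
    if (.edgeAllowed(a, b, kind, cidx)) st <- c(st, 1L)
    if (.edgeAllowed(b, a, kind, cidx)) st <- c(st, 2L)
    if (paste(a, b, sep = "\r") %in% wlKeys) st <- 1L
    if (paste(b, a, sep = "\r") %in% wlKeys) st <- 2L
    states[[j]] <- st
  }
  grid <- do.call(expand.grid, states[seq_len(nPairs)])
  out <- list()
  for (i in seq_len(max(nrow(grid), 1))) {
    edges <- .emptyEdges()
    if (nPairs) {
      st <- as.integer(grid[i, ])
      sel <- st != 0L
      if (any(sel)) {
        from <- ifelse(st[sel] == 1L, pairs[1, sel], pairs[2, sel])
        to <- ifelse(st[sel] == 1L, pairs[2, sel], pairs[1, sel])
        edges <- cbind(from = from, to = to)
      }
    }
    if (nrow(edges) && .hasCycleEdges(edges)) next
    dag <- template
    dag@edges <- .asEdgeMatrix(edges)
    out[[length(out) + 1]] <- dag
  }
  out
}

#' Exact best-scoring network by exhaustive enumeration
#'
#' Scores every DAG from [enumerateDags()] and returns the maximum; used
#' as the exact oracle against which [hillClimb()] is checked on small
#' problems. Ties keep the first DAG in enumeration order.
#'
#' @inheritParams hillClimb
#' @return A [ScoredNetwork-class].
#' @export
exhaustiveBest <- function(cohort, constraints = bnConstraints(),
                           genotypesAs = c("discrete", "continuous")) {
  network <- if (is(cohort, "CohortTable"))
    asNodes(cohort, match.arg(genotypesAs)) else cohort
  scorer <- .makeScorer(network)
  dags <- enumerateDags(network, constraints)
  bestTotal <- -Inf; bestDag <- NULL; bestLocal <- NULL
  for (dag in dags) {
    local <- vapply(network$nodes$name,
                    function(v) scorer(v, dagParents(dag, v)), 0)
    total <- sum(local)
    if (total > bestTotal + 1e-12) {
      bestTotal <- total; bestDag <- dag; bestLocal <- local
    }
  }
  new("ScoredNetwork", dag = bestDag, localScores = bestLocal,
      total = bestTotal)
}
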