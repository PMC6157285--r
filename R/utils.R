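# internal graph helpers shared by classes and search

# cycle test on a raw edge matrix (character, 2 cols) by Kahn's algorithm
.hasCycleEdges <- function(edges) {
  if (!nrow(edges)) return(FALSE)
  nodes <- unique(c(edges))
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges[, 2])
  indeg[names(tab)] <- as.integer(tab)
  kids <- split(edges[, 2], factor(edges[, 1], levels = nodes))
  queue <- nodes[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (w in kids[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  seen < length(nodes)
}

# reachability from 'from' to 'to' over a logical adjacency matrix
# adj[u, v] TRUE iff edge u -> v
.reaches <- function(adj, from, to) {
  if (from == to) return(TRUE)
  stack <- from
  visited <- logical(nrow(adj))
  names(visited) <- rownames(adj)
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (visited[[v]]) next
    visited[[v]] <- TRUE
    nxt <- rownames(adj)[adj[v, ]]
    if (to %in% nxt) return(TRUE)
    stack <- c(stack, nxt[!visited[nxt]])
  }
  FALSE
}

.adjFromEdges <- function(nodeNames, edges) {
  adj <- matrix(FALSE, length(nodeNames), length(nodeNames),
                dimnames = list(nodeNames, nodeNames))
  if (nrow(edges)) adj[edges] <- TRUE
  adj
}

.emptyEdges <- function() {
  matrix(character(), ncol = 2, dimnames = list(NULL, c("from", "to")))
}

.asEdgeMatrix <- function(x) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0) ||
      (is.data.frame(x) && nrow(x) == 0))
    return(.emptyEdges())
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.character(x) && is.null(dim(x)) && length(x) == 2)
    x <- matrix(x, ncol = 2)
  storage.mode(x) <- "character"
  colnames(x) <- c("from", "to")
  rownames(x) <- NULL
  x
}

.stampedMessage <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
}
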