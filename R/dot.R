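#' Write / read a DAG as an edge-list TSV with a node-type header
#'
#' The header block consists of `#`-prefixed lines `# node NAME KIND
#' [LEVELS]` (levels comma-separated for discrete nodes), followed by a
#' two-column `from`/`to` table.
#'
#' @param dag a [BNDag-class].
#' @param path file path.
#' @return `path` invisibly (`writeDag`); a `BNDag` (`readDag`).
#' @export
writeDag <- function(dag, path) {
  .writeAtomic(function(p) {
    con <- file(p, "w"); on.exit(close(con))
    nd <- dag@nodes
    writeLines(sprintf("# node %s %s%s", nd$name, nd$kind,
      vapply(nd$name, function(v)
        if (!is.null(dag@levels[[v]]))
          paste0(" ", paste(dag@levels[[v]], collapse = ",")) else "",
        "")), con)
    utils::write.table(as.data.frame(dag@edges), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }, path)
}

#' @rdname writeDag
#' @export
readDag <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# node ", lines, value = TRUE)
  if (!length(hdr)) stop("no '# node' header block in '", path, "'")
  parts <- strsplit(sub("^# node ", "", hdr), "[[:space:]]+")
  nodes <- data.frame(name = vapply(parts, `[`, "", 1),
                      kind = vapply(parts, `[`, "", 2))
  levels <- list()
  for (pp in parts)
    if (length(pp) >= 3 && pp[2] == "discrete")
      levels[[pp[1]]] <- strsplit(pp[3], ",", fixed = TRUE)[[1]]
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  edges <- NULL
  if (length(body) > 1) {
    tab <- utils::read.delim(text = body, stringsAsFactors = FALSE,
                             colClasses = "character")
    edges <- as.matrix(tab[, c("from", "to")])
  }
  bnDag(nodes, edges = edges, levels = levels)
}

.dotQuote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Export a network in GraphViz DOT format
#'
#' Discrete nodes are drawn as boxes and continuous nodes as ellipses.
#' For an [AverageNetwork-class], edge pen-width is proportional to
#' strength and the direction probability labels the edge; only retained
#' edges are drawn.
#'
#' @param x a [BNDag-class], [ScoredNetwork-class] or
#'   [AverageNetwork-class].
#' @param path output path.
#' @param nodes node table used to type the nodes of an average network
#'   (a `BNDag` or data.frame with `name`/`kind`); optional.
#' @return `path`, invisibly.
#' @export
writeDot <- function(x, path, nodes = NULL) {
  if (is(x, "ScoredNetwork")) x <- x@dag
  if (is(x, "BNDag")) {
    nd <- x@nodes
    edgeLines <- if (nrow(x@edges))
      sprintf("  %s -> %s;", .dotQuote(x@edges[, 1]),
              .dotQuote(x@edges[, 2])) else character()
  } else if (is(x, "AverageNetwork")) {
    e <- x@edges[x@edges$retained, , drop = FALSE]
    nd <- if (is(nodes, "BNDag")) nodes@nodes else nodes
    if (is.null(nd))
      nd <- data.frame(name = sort(unique(c(e$from, e$to))),
                       kind = "continuous")
    edgeLines <- sprintf(
      '  %s -> %s [penwidth=%.3f, label="%.2f", fontcolor=red];',
      .dotQuote(e$from), .dotQuote(e$to), 0.5 + 3 * e$strength,
      e$direction)
  } else {
    stop("cannot export objects of class '", class(x)[1], "'")
  }
  shape <- ifelse(nd$kind == "discrete", "box", "ellipse")
  nodeLines <- sprintf("  %s [shape=%s];", .dotQuote(nd$name), shape)
  .writeAtomic(function(p) writeLines(
    c("digraph network {", nodeLines, edgeLines, "}"), p), path)
}
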