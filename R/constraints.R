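#' Construct a constraint set for network search
#'
#' @param whitelist edges that must be present with the stated direction:
#'   a two-column matrix/data.frame of (from, to), or `NULL`.
#' @param blacklist directed edges that may never be present.
#' @param noParents node names that may not receive incoming edges.
#' @return A [BNConstraints-class].
#' @examples
#' bnConstraints(whitelist = c("TG2", "TG4"), noParents = c("sex"))
#' @export
bnConstraints <- function(whitelist = NULL, blacklist = NULL,
                          noParents = character()) {
  new("BNConstraints", whitelist = .asEdgeMatrix(whitelist),
      blacklist = .asEdgeMatrix(blacklist),
      noParents = as.character(noParents))
}

setMethod("show", "BNConstraints", function(object) {
  cat("BNConstraints:", nrow(object@whitelist), "whitelisted,",
      nrow(object@blacklist), "blacklisted edges,",
      length(object@noParents), "no-parent nodes\n")
})

#' The drug-response analysis constraint scheme
#'
#' Builds the constraint set used for modelling change in TG: the
#' pre-treatment level is forced to be a parent of the post-treatment
#' level (`TG2 -> TG4`), SNPs have no parents, post-treatment CpG
#' methylation may not be a parent of the pre-treatment TG level, and
#' the categorical covariates have no parents.
#'
#' @param snps character vector of SNP node names.
#' @param cpgs character vector of CpG node names.
#' @param discreteCovariates categorical covariates constrained to have
#'   no parents.
#' @param tg2,tg4 names of the pre-/post-treatment TG nodes.
#' @return A [BNConstraints-class].
#' @export
gaw20Constraints <- function(snps = character(), cpgs = character(),
                             discreteCovariates = c("sex", "center"),
                             tg2 = "TG2", tg4 = "TG4") {
  bl <- if (length(cpgs)) cbind(from = cpgs, to = tg2) else NULL
  bnConstraints(whitelist = c(tg2, tg4), blacklist = bl,
                noParents = c(snps, discreteCovariates))
}

#' Read / write a constraints file
#'
#' Line-oriented text format with directives `whitelist FROM TO`,
#' `blacklist FROM TO` and `no-parents NODE`; `#` starts a comment.
#'
#' @param path file path.
#' @return A [BNConstraints-class] (`readConstraints`); `path` invisibly
#'   (`writeConstraints`).
#' @export
readConstraints <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  wl <- bl <- list(); np <- character()
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "whitelist" && length(tok) == 3) {
      wl[[length(wl) + 1]] <- tok[2:3]
    } else if (tok[1] == "blacklist" && length(tok) == 3) {
      bl[[length(bl) + 1]] <- tok[2:3]
    } else if (tok[1] == "no-parents" && length(tok) == 2) {
      np <- c(np, tok[2])
    } else {
      stop("malformed constraints line: '", ln, "'")
    }
  }
  bnConstraints(
    whitelist = if (length(wl)) do.call(rbind, wl) else NULL,
    blacklist = if (length(bl)) do.call(rbind, bl) else NULL,
    noParents = np)
}

#' @rdname readConstraints
#' @param constraints a [BNConstraints-class].
#' @export
writeConstraints <- function(constraints, path) {
  .writeAtomic(function(p) {
    wl <- constraints@whitelist; bl <- constraints@blacklist
    writeLines(c(
      if (nrow(wl)) sprintf("whitelist %s %s", wl[, 1], wl[, 2]),
      if (nrow(bl)) sprintf("blacklist %s %s", bl[, 1], bl[, 2]),
      if (length(constraints@noParents))
        sprintf("no-parents %s", constraints@noParents)), p)
  }, path)
}
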