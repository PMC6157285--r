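#' Construct a CohortTable
#'
#' @param data data.frame, one row per individual.
#' @param kinds named character vector mapping every column of `data` to
#'   one of `"continuous"`, `"discrete"`, `"genotype"`, `"id"`.
#' @return A [CohortTable-class].
#' @examples
#' d <- data.frame(id = c("a", "b"), TG2 = c(80, 120), sex = c("F", "M"),
#'                 rs1 = c(0, 2))
#' cohortTable(d, c(id = "id", TG2 = "continuous", sex = "discrete",
#'                  rs1 = "genotype"))
#' @export
cohortTable <- function(data, kinds) {
  if (anyDuplicated(colnames(data)))
    stop("duplicate variable names in cohort data")
  new("CohortTable", data = data, kinds = kinds[colnames(data)])
}

#' @describeIn cohortTable number of individuals (rows).
#' @param x a `CohortTable`.
#' @export
nIndividuals <- function(x) nrow(x@data)

#' @describeIn cohortTable the variable names.
#' @export
varNames <- function(x) colnames(x@data)

#' @describeIn cohortTable named vector of per-column kinds.
#' @export
varKinds <- function(x) x@kinds

#' @describeIn cohortTable the underlying data.frame.
#' @export
cohortData <- function(x) x@data

setMethod("show", "CohortTable", function(object) {
  k <- table(factor(object@kinds, levels = .VALID_KINDS))
  cat("CohortTable:", nrow(object@data), "individuals x",
      ncol(object@data), "variables\n")
  cat("  continuous:", k[["continuous"]], " discrete:", k[["discrete"]],
      " genotype:", k[["genotype"]], " id:", k[["id"]], "\n")
})

#' Subset the columns of a CohortTable
#'
#' @param x a `CohortTable`.
#' @param columns character vector of column names to keep.
#' @return A `CohortTable` with only the requested columns.
#' @export
selectVariables <- function(x, columns) {
  missing <- setdiff(columns, varNames(x))
  if (length(missing))
    stop("unknown variable(s): ", paste(missing, collapse = ", "))
  cohortTable(x@data[, columns, drop = FALSE], x@kinds[columns])
}

# ---- node mapping for network analysis --------------------------------------

#' Map cohort columns to typed network nodes
#'
#' Continuous columns become continuous nodes; discrete columns become
#' discrete nodes with their observed levels; genotype columns become, by
#' default, discrete nodes with levels 0/1/2, or continuous dosage nodes
#' when `genotypesAs = "continuous"`. Columns of kind `"id"` are refused:
#' drop them with [selectVariables()] first.
#'
#' @param cohort a [CohortTable-class].
#' @param genotypesAs `"discrete"` (default) or `"continuous"`.
#' @return A list with `nodes` (data.frame name/kind), `levels` (named list
#'   for discrete nodes) and `frame` (data.frame with discrete columns as
#'   factors, continuous as numeric) ready for scoring.
#' @export
asNodes <- function(cohort, genotypesAs = c("discrete", "continuous")) {
  genotypesAs <- match.arg(genotypesAs)
  kinds <- varKinds(cohort)
  if (any(kinds == "id"))
    stop("column(s) of kind 'id' cannot map to network nodes: ",
         paste(names(kinds)[kinds == "id"], collapse = ", "),
         " (drop them with selectVariables())")
  frame <- cohortData(cohort)
  nodeKind <- character(length(kinds))
  levels <- list()
  for (i in seq_along(kinds)) {
    v <- names(kinds)[i]
    nodeKind[i] <- switch(kinds[[i]],
      continuous = "continuous",
      discrete = "discrete",
      genotype = if (genotypesAs == "discrete") "discrete" else "continuous")
    if (nodeKind[i] == "discrete") {
      if (kinds[[i]] == "genotype") {
        frame[[v]] <- factor(frame[[v]], levels = 0:2)
      } else {
        frame[[v]] <- factor(frame[[v]])
      }
      levels[[v]] <- levels(frame[[v]])
    } else {
      frame[[v]] <- as.numeric(frame[[v]])
    }
  }
  list(nodes = data.frame(name = names(kinds), kind = nodeKind),
       levels = levels, frame = frame)
}

# ---- text IO ----------------------------------------------------------------

.writeAtomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("cannot write to '", path, "'")
  invisible(path)
}

.formatFull <- function(df) {
  for (i in seq_along(df)) {
    if (is.double(df[[i]])) {
      x <- sprintf("%.17g", df[[i]])
      x[is.na(df[[i]])] <- NA
      df[[i]] <- x
    }
  }
  df
}

#' Write / read a cohort as TSV plus a column-type sidecar
#'
#' The cohort file has a header row and one row per individual, missing
#' values written as `NA`; numeric values are written at full double
#' precision. The sidecar maps each column name to its kind.
#'
#' @param cohort a [CohortTable-class].
#' @param path path for the cohort TSV.
#' @param typesPath path for the column-type sidecar TSV.
#' @return `path`, invisibly (`writeCohort`); a `CohortTable`
#'   (`readCohort`).
#' @export
writeCohort <- function(cohort, path, typesPath) {
  df <- .formatFull(cohortData(cohort))
  .writeAtomic(function(p) utils::write.table(
    df, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"), path)
  types <- data.frame(column = varNames(cohort),
                      kind = unname(varKinds(cohort)))
  .writeAtomic(function(p) utils::write.table(
    types, p, sep = "\t", quote = FALSE, row.names = FALSE), typesPath)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path, typesPath) {
  types <- utils::read.delim(typesPath, stringsAsFactors = FALSE)
  if (!all(c("column", "kind") %in% colnames(types)))
    stop("type sidecar needs columns 'column' and 'kind'")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = "NA", check.names = FALSE)
  missing <- setdiff(types$column, colnames(df))
  if (length(missing))
    stop("cohort file lacks column(s): ", paste(missing, collapse = ", "))
  kinds <- stats::setNames(types$kind, types$column)
  for (v in names(kinds))
    if (kinds[[v]] %in% c("continuous", "genotype"))
      df[[v]] <- as.numeric(df[[v]])
    else
      df[[v]] <- as.character(df[[v]])
  cohortTable(df[, types$column, drop = FALSE], kinds)
}
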