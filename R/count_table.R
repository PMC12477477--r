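#' Construct an abundance table of samples by taxa
#'
#' A `count_table` is a numeric matrix with samples as rows and taxa as
#' columns, carrying a unit flag that records whether the entries are raw
#' counts, percentages (rows sum to at most 100), or proportions (rows sum
#' to at most 1).  All downstream stages of the pipeline consume this class.
#'
#' @param values Numeric matrix, samples in rows (rownames are sample ids),
#'   taxa in columns (colnames are taxon ids).  No negative or missing
#'   entries are allowed.
#' @param unit One of `"counts"`, `"percent"` or `"proportion"`.
#' @return A `count_table` object (a matrix with a `unit` attribute).
#' @examples
#' m <- matrix(c(30, 70, 50, 50), 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("taxA", "taxB")))
#' count_table(m, unit = "percent")
#' @export
count_table <- function(values, unit = c("counts", "percent", "proportion")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x taxa)")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("'values' must have sample ids as rownames and taxon ids as colnames")
  dup_s <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  dup_t <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_t))
    stop("duplicate taxon id(s): ", paste(unique(dup_t), collapse = ", "))
  if (anyNA(values))
    stop("missing values are not allowed in a count table")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  tol <- 1e-6
  if (unit == "percent" && nrow(values) && any(rowSums(values) > 100 * (1 + tol)))
    stop("unit is 'percent' but some row sums exceed 100")
  if (unit == "proportion" && nrow(values) && any(rowSums(values) > 1 + tol))
    stop("unit is 'proportion' but some row sums exceed 1")
  structure(values, unit = unit, class = c("count_table", "matrix", "array"))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d sample(s) x %d taxa [unit: %s]\n",
              nrow(x), ncol(x), attr(x, "unit")))
  print(unclass_table(x), ...)
  invisible(x)
}

# strip class/attributes for printing and arithmetic
unclass_table <- function(x) {
  attr(x, "unit") <- NULL
  class(x) <- NULL
  x
}

#' @rdname count_table
#' @param x A `count_table`.
#' @export
table_unit <- function(x) attr(x, "unit")

#' Sample and taxon identifiers of a count table
#' @param x A `count_table` (or any matrix with dimnames).
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) rownames(x)

#' @rdname sample_ids
#' @export
taxon_ids <- function(x) colnames(x)

#' Construct a table of environmental factors
#'
#' Samples in rows, factors (e.g. pH, organic matter ORM in g/kg, altitude
#' HT in m, clay CP, sand SP and silt SSG in g/kg) in columns.  No missing
#' cells are allowed; when paired with a `count_table` in ordination the two
#' must share the same sample set.
#'
#' @param values Numeric matrix with sample rownames and factor colnames.
#' @return An `env_table` object.
#' @export
env_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x factors)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample ids as rownames and factor names as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample id(s) in environment table")
  if (anyDuplicated(colnames(values)))
    stop("duplicate factor name(s) in environment table")
  if (anyNA(values))
    stop("environment table must have no missing cells")
  structure(values, class = c("env_table", "matrix", "array"))
}

#' @export
print.env_table <- function(x, ...) {
  cat(sprintf("env_table: %d sample(s) x %d factor(s)\n", nrow(x), ncol(x)))
  y <- x; class(y) <- NULL
  print(y, ...)
  invisible(x)
}
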