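#' Read an abundance table from a delimited text file
#'
#' The expected layout is one header row of taxon ids (first field is the
#' sample-id column header) followed by one row per sample.  Parsing is
#' locale independent: the decimal separator is always the point.
#'
#' @param path Path to the file.
#' @param unit Declared unit of the values: `"counts"`, `"percent"` or
#'   `"proportion"`.
#' @param sep Field separator; tab by default, `","` accepted for CSV input.
#' @return A [count_table()].
#' @seealso [write_count_table()]
#' @export
read_count_table <- function(path, unit = c("counts", "percent", "proportion"),
                             sep = "\t") {
  unit <- match.arg(unit)
  m <- read_id_matrix(path, sep, what = "taxon")
  count_table(m, unit = unit)
}

#' Write an abundance table to a delimited text file
#' @param x A [count_table()].
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_count_table <- function(x, path, sep = "\t") {
  write_id_matrix(unclass_table(x), path, sep, id_header = "sample_id")
}

#' Read / write a table of environmental factors
#'
#' Same layout as [read_count_table()]: header row of factor names, one row
#' per sample.
#' @inheritParams read_count_table
#' @return An [env_table()].
#' @export
read_env_table <- function(path, sep = "\t") {
  env_table(read_id_matrix(path, sep, what = "factor"))
}

#' @rdname read_env_table
#' @param x An [env_table()].
#' @export
write_env_table <- function(x, path, sep = "\t") {
  y <- x; class(y) <- NULL
  write_id_matrix(y, path, sep, id_header = "sample_id")
}

# Shared id-matrix reader with strict diagnostics: ragged rows are reported
# with their line number, unparseable or negative cells with coordinates.
read_id_matrix <- function(path, sep, what = "column") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(fields[[1]])
  col_ids <- header[-1]
  if (anyDuplicated(col_ids))
    stop(sprintf("duplicate %s id(s): %s", what,
                 paste(unique(col_ids[duplicated(col_ids)]), collapse = ", ")))
  n_col <- length(header)
  body <- fields[-1]
  n_fields <- lengths(body)
  if (any(n_fields != n_col)) {
    bad <- which(n_fields != n_col)[1]
    stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                 bad + 1L, n_col, n_fields[bad]))
  }
  row_ids <- trimws(vapply(body, `[`, character(1), 1L))
  if (anyDuplicated(row_ids))
    stop("duplicate sample id(s): ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  m <- matrix(NA_real_, length(body), length(col_ids),
              dimnames = list(row_ids, col_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("cannot parse value '%s' at sample '%s', %s '%s'",
                   body[[i]][j + 1L], row_ids[i], what, col_ids[j]))
    }
    m[i, ] <- v
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative value at sample '%s', %s '%s'",
                 row_ids[neg[1, 1]], what, col_ids[neg[1, 2]]))
  m
}

write_id_matrix <- function(m, path, sep, id_header) {
  header <- paste(c(id_header, colnames(m)), collapse = sep)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = 15, trim = TRUE,
                                   scientific = FALSE)),
          collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a phylogenetic tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that turns silent failures into
#' errors and enforces named, unique leaves so tips can be matched to taxon
#' ids for UniFrac.
#'
#' @param path Path to a Newick file (or a Newick string containing `;`).
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch({
    if (grepl(";", path, fixed = TRUE)) ape::read.tree(text = path)
    else ape::read.tree(path)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick input: ", path)
  if (is.null(tr$tip.label) || any(!nzchar(tr$tip.label)))
    stop("tree has unnamed leaves; every leaf must carry a taxon id")
  if (anyDuplicated(tr$tip.label))
    stop("tree leaf names are not unique: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Write a distance matrix as CSV
#'
#' The full square symmetric matrix is written with ids in the first row and
#' column; the metric label is preserved in the header comment-free form by
#' [read_distance_csv()] via the `metric` argument.
#'
#' @param d A `dist` object (as produced by [bray_curtis()] and friends).
#' @param path Output path.
#' @export
write_distance_csv <- function(d, path) {
  m <- as.matrix(d)
  write_id_matrix(m, path, sep = ",", id_header = "id")
}

#' @rdname write_distance_csv
#' @param metric Metric label to attach to the returned `dist`.
#' @export
read_distance_csv <- function(path, metric = "unknown") {
  m <- read_id_matrix(path, sep = ",", what = "id")
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("distance matrix must be square and symmetric")
  d <- stats::as.dist(m)
  attr(d, "method") <- metric
  d
}

#' Serialize analysis results to JSON and back
#'
#' `write_results()` stores supported result objects (currently
#' [grey_relation()] results and plain lists/vectors) in a typed JSON
#' document; `read_results()` reconstructs an object that is field-by-field
#' equal to the original (ids exact, numerics to full double precision).
#'
#' @param obj Object to serialize.
#' @param path Output path.
#' @export
write_results <- function(obj, path) {
  doc <- encode_result(obj)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  decode_result(doc)
}

encode_result <- function(obj) {
  if (inherits(obj, "grey_relation")) {
    list(type = "grey_relation",
         rho = obj$rho,
         normalization = obj$normalization,
         labels = obj$labels,
         points = obj$points,
         parent_raw = obj$parent_raw,
         parent_norm = obj$parent_norm,
         series_raw = encode_matrix(obj$series_raw),
         series_norm = encode_matrix(obj$series_norm),
         delta = encode_matrix(obj$delta),
         delta_min = obj$delta_min,
         delta_max = obj$delta_max,
         xi = encode_matrix(obj$xi),
         degrees = as.list(obj$degrees),
         ranking = obj$ranking)
  } else if (inherits(obj, "rda_result")) {
    list(type = "rda_result",
         transform = obj$transform,
         constrained_eig = as.list(obj$constrained_eig),
         unconstrained_eig = as.list(obj$unconstrained_eig),
         total_variance = obj$total_variance,
         constrained_fraction = obj$constrained_fraction,
         site_scores = encode_matrix(obj$site_scores),
         species_scores = encode_matrix(obj$species_scores),
         biplot_scores = encode_matrix(obj$biplot_scores),
         dca_axis_length = obj$dca_axis_length)
  } else {
    list(type = "list", value = obj)
  }
}

decode_result <- function(doc) {
  switch(doc$type,
    grey_relation = structure(list(
      rho = doc$rho,
      normalization = doc$normalization,
      labels = unlist(doc$labels),
      points = unlist(doc$points),
      parent_raw = unlist(doc$parent_raw),
      parent_norm = unlist(doc$parent_norm),
      series_raw = decode_matrix(doc$series_raw),
      series_norm = decode_matrix(doc$series_norm),
      delta = decode_matrix(doc$delta),
      delta_min = doc$delta_min,
      delta_max = doc$delta_max,
      xi = decode_matrix(doc$xi),
      degrees = unlist(doc$degrees),
      ranking = unlist(doc$ranking)), class = "grey_relation"),
    rda_result = structure(list(
      transform = doc$transform,
      constrained_eig = unlist(doc$constrained_eig),
      unconstrained_eig = unlist(doc$unconstrained_eig),
      total_variance = doc$total_variance,
      constrained_fraction = doc$constrained_fraction,
      site_scores = decode_matrix(doc$site_scores),
      species_scores = decode_matrix(doc$species_scores),
      biplot_scores = decode_matrix(doc$biplot_scores),
      dca_axis_length = doc$dca_axis_length), class = "rda_result"),
    list = doc$value,
    stop("unknown result type in JSON document: ", doc$type)
  )
}

encode_matrix <- function(m) {
  if (is.null(m)) return(NULL)
  list(rows = rownames(m), cols = colnames(m),
       values = lapply(seq_len(nrow(m)), function(i) unname(m[i, ])))
}

decode_matrix <- function(x) {
  if (is.null(x)) return(NULL)
  v <- do.call(rbind, lapply(x$values, unlist))
  rownames(v) <- unlist(x$rows)
  colnames(v) <- unlist(x$cols)
  v
}
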