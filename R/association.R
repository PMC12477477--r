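#' Mean-normalize a series
#'
#' Divides every value by the series mean, so the normalized series has mean
#' 1.  This is the dimensionless-scaling step applied to the parent and
#' every characteristic series before grey relational analysis; it makes the
#' analysis invariant to the measurement scale of each series and tolerates
#' zero entries (only the mean must be positive).
#'
#' @param x Numeric vector with a positive mean.
#' @return The normalized vector.
#' @export
mean_normalize <- function(x) {
  if (!is.numeric(x) || !length(x)) stop("'x' must be a non-empty numeric vector")
  if (anyNA(x)) stop("'x' must not contain missing values")
  m <- mean(x)
  if (m <= 0) stop("series mean must be positive for mean normalization")
  x / m
}

#' Grey relational analysis (Deng coefficients)
#'
#' Ranks characteristic series (taxon abundance profiles) by the closeness
#' of their shape to a parent series (a compound concentration measured over
#' the same observation points).  After normalizing the parent \eqn{x_0} and
#' each series \eqn{x_i} (mean normalization by default), the per-point
#' absolute differences \eqn{\Delta_i(k) = |x_0'(k) - x_i'(k)|} are formed
#' and the global extrema \eqn{\Delta_{min}, \Delta_{max}} are taken over
#' all series and points.  The Deng grey relational coefficient is
#' \deqn{\xi_i(k) = \frac{\Delta_{min} + \rho\,\Delta_{max}}
#'                      {\Delta_i(k) + \rho\,\Delta_{max}}}
#' with resolution coefficient \eqn{\rho \in (0, 1]} (default 0.50), and the
#' grey relational degree of series \eqn{i} is the unweighted mean of its
#' coefficients, \eqn{r_i = \mathrm{mean}_k\, \xi_i(k)}.  Larger degrees
#' mean a profile that tracks the parent more closely; ranking ties are
#' broken lexicographically by label.
#'
#' @param parent Numeric parent (reference) series over k observation
#'   points.
#' @param series Characteristic series: a numeric matrix with the k points
#'   in rows and one labelled column per series, or a [count_table()] whose
#'   rows are the observation points (groups) and whose columns are taxa.
#' @param rho Resolution coefficient in (0, 1].
#' @param normalization `"mean"` (default, divide by series mean),
#'   `"initial"` (divide by first value) or `"minmax"` (rescale to \[0, 1\]).
#' @return An object of class `grey_relation`; see Details for fields.
#' @details The returned list carries `rho`, `normalization`, `labels`,
#'   `points`, the raw and normalized parent and series, the `delta` matrix
#'   with its global extrema `delta_min`/`delta_max`, the coefficient matrix
#'   `xi` (points x series), the per-series `degrees`, and `ranking` (labels
#'   sorted by decreasing degree).
#' @examples
#' pts <- c(p1 = 1, p2 = 2, p3 = 4)
#' s <- cbind(follows = c(2, 4, 8), flat = c(3, 3, 3))
#' rownames(s) <- names(pts)
#' grey_relation(pts, s)$degrees
#' @export
grey_relation <- function(parent, series, rho = 0.5,
                          normalization = c("mean", "initial", "minmax")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0 || rho > 1)
    stop("'rho' must be a single value in (0, 1]")
  if (inherits(series, "count_table")) series <- unclass_table(series)
  if (is.data.frame(series)) series <- as.matrix(series)
  if (!is.matrix(series) || !is.numeric(series))
    stop("'series' must be a numeric matrix (points x series)")
  if (is.null(colnames(series))) stop("'series' columns must be labelled")
  if (!is.numeric(parent) || length(parent) != nrow(series))
    stop(sprintf("parent length (%d) must equal the number of points (%d)",
                 length(parent), nrow(series)))
  if (nrow(series) < 2) stop("at least 2 observation points are required")
  if (anyNA(parent) || anyNA(series)) stop("missing values are not allowed")

  points <- rownames(series)
  if (is.null(points)) points <- names(parent)
  if (is.null(points)) points <- paste0("k", seq_len(nrow(series)))

  norm_fun <- switch(normalization,
    mean = mean_normalize,
    initial = function(v) {
      if (v[1] == 0) stop("initial normalization undefined: first value is 0")
      v / v[1]
    },
    minmax = function(v) {
      r <- range(v)
      if (diff(r) == 0) stop("min-max normalization undefined: constant series")
      (v - r[1]) / diff(r)
    })

  p_norm <- norm_fun(parent)
  s_norm <- apply(series, 2, norm_fun)
  delta <- abs(s_norm - p_norm)
  dimnames(delta) <- list(points, colnames(series))
  d_min <- min(delta)
  d_max <- max(delta)
  xi <- if (d_max == 0) {
    # every series coincides with the parent: perfect relation throughout
    matrix(1, nrow(delta), ncol(delta), dimnames = dimnames(delta))
  } else {
    (d_min + rho * d_max) / (delta + rho * d_max)
  }
  degrees <- colMeans(xi)
  ranking <- colnames(series)[order(-degrees, colnames(series))]

  structure(list(
    rho = rho,
    normalization = normalization,
    labels = colnames(series),
    points = points,
    parent_raw = as.numeric(parent),
    parent_norm = as.numeric(p_norm),
    series_raw = `dimnames<-`(series, list(points, colnames(series))),
    series_norm = `dimnames<-`(s_norm, list(points, colnames(series))),
    delta = delta,
    delta_min = d_min,
    delta_max = d_max,
    xi = xi,
    degrees = degrees,
    ranking = ranking), class = "grey_relation")
}

#' @export
print.grey_relation <- function(x, ...) {
  cat(sprintf(
    "Grey relational analysis: %d series over %d points (rho = %.2f, %s normalization)\n",
    length(x$labels), length(x$points), x$rho, x$normalization))
  rpt <- gra_rank_report(x)
  print(rpt, row.names = FALSE)
  invisible(x)
}

#' Ranked grey relational degree report
#'
#' Series sorted by decreasing grey relational degree (ties broken
#' lexicographically), with presentation rounding applied only here — the
#' internal math of [grey_relation()] is full precision.
#'
#' @param result A `grey_relation` object.
#' @param digits Decimal places for display (default 3).
#' @return Data frame with columns `rank`, `label`, `degree`.
#' @export
gra_rank_report <- function(result, digits = 3) {
  if (!inherits(result, "grey_relation"))
    stop("'result' must be a grey_relation object")
  data.frame(rank = seq_along(result$ranking),
             label = result$ranking,
             degree = round(unname(result$degrees[result$ranking]), digits),
             stringsAsFactors = FALSE)
}

#' Per-point grey relational coefficient table
#'
#' The coefficient matrix \eqn{\xi_i(k)} with points in rows and series in
#' columns, rounded for presentation.
#'
#' @inheritParams gra_rank_report
#' @return Data frame of rounded coefficients.
#' @export
gra_coefficient_report <- function(result, digits = 3) {
  if (!inherits(result, "grey_relation"))
    stop("'result' must be a grey_relation object")
  as.data.frame(round(result$xi, digits))
}

#' Pairwise co-occurrence correlation network of the most abundant taxa
#'
#' Retains the `top_n` taxa by total abundance, computes all pairwise
#' correlation coefficients with two-sided tests, and keeps as network edges
#' the pairs with p below `alpha`.  No multiplicity correction is applied by
#' default (each pair is tested marginally); Benjamini-Hochberg adjustment
#' of the edge filter is available via `adjust = "BH"`.
#'
#' @param x A [count_table()].
#' @param top_n Number of most abundant taxa to retain (default 100).
#' @param method Correlation statistic: `"spearman"` (default, rank-based,
#'   robust for compositional abundances) or `"pearson"`.
#' @param alpha Two-sided significance level for the edge filter.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An object of class `correlation_network`: `taxon_ids`, symmetric
#'   matrices `rho` and `p`, and `edges` (data frame `taxon_a`, `taxon_b`,
#'   `rho`, `p` of the pairs passing the filter).  Pairs involving a
#'   constant taxon have undefined correlation and are skipped with a
#'   warning.
#' @export
correlation_network <- function(x, top_n = 100,
                                method = c("spearman", "pearson"),
                                alpha = 0.05, adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (!inherits(x, "count_table")) stop("'x' must be a count_table")
  if (nrow(x) < 4)
    warning("fewer than 4 samples: pairwise tests have very low power")
  if (top_n < 2) stop("'top_n' must be at least 2")
  m <- unclass_table(x)
  totals <- colSums(m)
  keep <- colnames(m)[order(-totals, colnames(m))][seq_len(min(top_n, ncol(m)))]
  m <- m[, keep, drop = FALSE]
  k <- ncol(m)
  rho <- matrix(NA_real_, k, k, dimnames = list(keep, keep))
  pmat <- matrix(NA_real_, k, k, dimnames = list(keep, keep))
  diag(rho) <- 1; diag(pmat) <- 0
  constant <- apply(m, 2, function(v) stats::sd(v) == 0)
  if (any(constant))
    warning("constant taxa skipped in correlation tests: ",
            paste(keep[constant], collapse = ", "))
  ea <- character(0); eb <- character(0); er <- numeric(0); ep <- numeric(0)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (constant[i] || constant[j]) next
    ct <- suppressWarnings(
      stats::cor.test(m[, i], m[, j], method = method,
                      alternative = "two.sided", exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    pmat[i, j] <- pmat[j, i] <- ct$p.value
    ea <- c(ea, keep[i]); eb <- c(eb, keep[j])
    er <- c(er, unname(ct$estimate)); ep <- c(ep, ct$p.value)
  }
  p_filter <- if (adjust == "BH") stats::p.adjust(ep, method = "BH") else ep
  sel <- which(p_filter < alpha)
  edges <- data.frame(taxon_a = ea[sel], taxon_b = eb[sel],
                      rho = er[sel], p = ep[sel],
                      stringsAsFactors = FALSE)
  if (adjust == "BH") edges$p_adj <- p_filter[sel]
  structure(list(taxon_ids = keep, method = method, alpha = alpha,
                 adjust = adjust, rho = rho, p = pmat, edges = edges),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf(
    "correlation_network: %d taxa, %s, alpha = %g (%s adjustment), %d edge(s)\n",
    length(x$taxon_ids), x$method, x$alpha, x$adjust, nrow(x$edges)))
  invisible(x)
}
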