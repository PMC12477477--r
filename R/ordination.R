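#' First DCA axis length (gradient length, SD units)
#'
#' Runs detrended correspondence analysis ([vegan::decorana()], 26 detrending
#' segments with Hill's nonlinear rescaling) and returns the length of the
#' first axis in standard deviations of species turnover.  The conventional
#' gate: below ~3 SD species responses are close to linear and a linear
#' constrained method (RDA) is appropriate; above it a unimodal method
#' would be indicated.
#'
#' @param x A [count_table()] with at least 3 samples and 3 taxa and no
#'   zero-sum rows or columns.
#' @return Length of the first DCA axis in SD units (0 when all samples have
#'   identical composition).
#' @export
dca_axis_length <- function(x) {
  if (!inherits(x, "count_table")) stop("'x' must be a count_table")
  if (nrow(x) < 3 || ncol(x) < 3)
    stop("DCA needs at least 3 samples and 3 taxa")
  m <- unclass_table(x)
  if (any(rowSums(m) <= 0) || any(colSums(m) <= 0))
    stop("zero-sum rows or columns are not allowed in DCA")
  # no gradient at all: every sample has the same composition
  rel <- m / rowSums(m)
  if (max(apply(rel, 2, function(v) diff(range(v)))) < 1e-12) return(0)
  dca <- vegan::decorana(m)
  proj <- dca$rproj[, 1]
  diff(range(proj))
}

#' Redundancy analysis of community composition on environmental factors
#'
#' Constrained ordination: the (optionally transformed) community matrix is
#' regressed on the standardized environmental factors and the fitted part
#' is decomposed into orthogonal constrained axes
#' (via [vegan::rda()]).  Scores are returned in scaling 2 (correlation
#' biplot), the scaling under which angles between factor arrows and sample
#' points are read as correlations.
#'
#' @param y A [count_table()] (samples x taxa).
#' @param x An [env_table()] over the same samples.
#' @param transform Species pre-transform: `"hellinger"` (default; square
#'   root of relative abundances, the standard choice for abundance data in
#'   linear ordination), `"none"` (textbook RDA on centred raw values) or
#'   `"standardize"` (unit-variance taxa).
#' @return An object of class `rda_result` with elements
#'   `constrained_eig`, `unconstrained_eig`, `total_variance`,
#'   `constrained_fraction`, `site_scores`, `species_scores`,
#'   `biplot_scores` (factors x axes), `transform`, and the underlying
#'   vegan fit as `fit`.
#' @export
rda_fit <- function(y, x, transform = c("hellinger", "none", "standardize")) {
  transform <- match.arg(transform)
  if (!inherits(y, "count_table")) stop("'y' must be a count_table")
  if (!inherits(x, "env_table")) stop("'x' must be an env_table")
  if (!setequal(sample_ids(y), rownames(x)))
    stop("'y' and 'x' must cover the same samples")
  xm <- x[sample_ids(y), , drop = FALSE]
  class(xm) <- NULL
  sds <- apply(xm, 2, stats::sd)
  if (any(sds == 0))
    stop("constant environmental factor(s): ",
         paste(colnames(xm)[sds == 0], collapse = ", "))
  if (nrow(y) <= ncol(xm))
    warning(sprintf(
      "only %d samples for %d factors; the constrained model is saturated",
      nrow(y), ncol(xm)))
  xs <- scale(xm)

  ym <- unclass_table(y)
  yt <- switch(transform,
    none = ym,
    hellinger = vegan::decostand(ym, method = "hellinger"),
    standardize = scale(ym))

  dat <- as.data.frame(xs)
  fit <- vegan::rda(yt ~ ., data = dat)

  # collinearity diagnostic: variance inflation of the standardized factors
  vif <- tryCatch(vegan::vif.cca(fit), error = function(e) NULL)
  if (!is.null(vif) && any(is.finite(vif) & vif > 20))
    warning("collinear environmental factors (VIF > 20): ",
            paste(sprintf("%s=%.1f", names(vif)[vif > 20], vif[vif > 20]),
                  collapse = ", "))

  c_eig <- fit$CCA$eig
  u_eig <- if (is.null(fit$CA) || is.null(fit$CA$eig)) numeric(0) else fit$CA$eig
  u_eig <- u_eig[u_eig > -1e-12]
  total <- fit$tot.chi
  k <- length(c_eig)
  sc <- vegan::scores(fit, display = c("sites", "species", "bp"),
                      scaling = 2, choices = seq_len(k))
  structure(list(
    constrained_eig = c_eig,
    unconstrained_eig = u_eig,
    total_variance = total,
    constrained_fraction = sum(c_eig) / total,
    site_scores = sc$sites,
    species_scores = sc$species,
    biplot_scores = sc$biplot,
    transform = transform,
    dca_axis_length = NULL,
    fit = fit), class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("RDA (%s transform): %d constrained axes, %.1f%% of variance constrained\n",
              x$transform, length(x$constrained_eig),
              100 * x$constrained_fraction))
  cat("constrained eigenvalues:\n")
  print(signif(x$constrained_eig, 4))
  if (!is.null(x$dca_axis_length))
    cat(sprintf("first DCA axis length: %.3f SD (%s)\n", x$dca_axis_length,
                if (x$dca_axis_length < 3) "linear method indicated"
                else "unimodal method indicated"))
  invisible(x)
}

#' Run the gradient-length gate, then RDA
#'
#' Convenience wrapper reproducing the standard decision procedure: compute
#' the first DCA axis length; report whether a linear method is indicated
#' (< 3 SD); fit the RDA either way and annotate the result.
#'
#' @inheritParams rda_fit
#' @return An `rda_result` with `dca_axis_length` filled in.
#' @export
rda_gated <- function(y, x, transform = c("hellinger", "none", "standardize")) {
  # the gate ignores never-observed taxa, which carry no gradient information
  observed <- count_table(unclass_table(y)[, colSums(y) > 0, drop = FALSE],
                          unit = table_unit(y))
  len <- dca_axis_length(observed)
  res <- rda_fit(y, x, transform = transform)
  res$dca_axis_length <- len
  res
}

#' Interpret a sample/factor pair on the RDA biplot
#'
#' Applies the standard correlation-biplot reading rules: the sign of the
#' association is given by the angle between the sample's site-score vector
#' and the factor's arrow (acute = positive, obtuse = negative, right angle
#' = none within tolerance), and the influence of the factors on that sample
#' is ordered by the magnitude of the scalar projection of the sample point
#' onto each arrow (the closer the projection point to the arrow head, the
#' larger the influence).
#'
#' @param result An `rda_result` from [rda_fit()].
#' @param sample_id Sample to interpret.
#' @param factor_name Environmental factor to interpret.
#' @param tol Cosine tolerance inside which the angle counts as right.
#' @return A list with `sign` (`"+"`, `"-"`, `"0"`, or `NA` for a
#'   zero-length site vector), `angle_deg`, `projection` (signed scalar
#'   projection onto the factor arrow), `projection_rank` (1 = the factor
#'   with the largest absolute projection for this sample) and
#'   `factor_order` (all factors sorted by influence on this sample).
#' @export
interpret_rda <- function(result, sample_id, factor_name, tol = 1e-9) {
  if (!inherits(result, "rda_result")) stop("'result' must be an rda_result")
  if (!sample_id %in% rownames(result$site_scores))
    stop("unknown sample: ", sample_id)
  if (!factor_name %in% rownames(result$biplot_scores))
    stop("unknown factor: ", factor_name)
  v <- result$site_scores[sample_id, ]
  arrows <- result$biplot_scores
  proj <- apply(arrows, 1, function(a) sum(v * a) / sqrt(sum(a^2)))
  ord <- order(-abs(proj), rownames(arrows))
  factor_order <- rownames(arrows)[ord]
  a <- arrows[factor_name, ]
  nv <- sqrt(sum(v^2)); na <- sqrt(sum(a^2))
  if (nv < tol || na < tol) {
    return(list(sign = NA_character_, angle_deg = NA_real_,
                projection = unname(proj[factor_name]),
                projection_rank = match(factor_name, factor_order),
                factor_order = factor_order))
  }
  cosang <- max(-1, min(1, sum(v * a) / (nv * na)))
  sign <- if (cosang > tol) "+" else if (cosang < -tol) "-" else "0"
  list(sign = sign,
       angle_deg = acos(cosang) * 180 / pi,
       projection = unname(proj[factor_name]),
       projection_rank = match(factor_name, factor_order),
       factor_order = factor_order)
}
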