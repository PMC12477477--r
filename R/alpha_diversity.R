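#' Shannon diversity index (natural log)
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over taxa with positive counts, where
#' \eqn{p_i = n_i / N}.  Reported in nats.
#'
#' @param counts Non-negative numeric vector of per-taxon abundances with at
#'   least one positive entry.
#' @return The Shannon index.
#' @examples
#' shannon(c(10, 10, 10, 10))  # log(4)
#' @export
shannon <- function(counts) {
  check_counts(counts)
  if (sum(counts) <= 0) stop("Shannon index undefined for an all-zero vector")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Simpson dominance index
#'
#' The finite-sample dominance form
#' \eqn{D = \sum_i n_i (n_i - 1) / (N (N - 1))}: the probability that two
#' reads drawn without replacement belong to the same taxon.  Higher values
#' mean lower diversity.
#'
#' @inheritParams shannon
#' @return Dominance in \[0, 1\].
#' @export
simpson <- function(counts) {
  check_counts(counts, integer = TRUE)
  n <- sum(counts)
  if (n < 2) stop("Simpson dominance requires a total count of at least 2")
  sum(counts * (counts - 1)) / (n * (n - 1))
}

#' Chao1 richness estimator
#'
#' Bias-corrected form \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} by
#' default, which stays finite when no doubletons are present; the classic
#' \eqn{S_{obs} + F_1^2 / (2 F_2)} is available with
#' `bias_corrected = FALSE`.
#'
#' @inheritParams shannon
#' @param bias_corrected Use the bias-corrected form (default `TRUE`).
#' @return Estimated richness; always `>= ` the observed richness.
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  check_counts(counts, integer = TRUE)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) return(s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
  if (f2 == 0) return(s_obs + f1 * (f1 - 1) / 2)  # graceful F2 = 0 branch
  s_obs + f1^2 / (2 * f2)
}

#' ACE richness estimator (Chao & Lee)
#'
#' Taxa with counts at or below `rare_threshold` form the rare group.  With
#' sample coverage \eqn{C_{ACE} = 1 - F_1 / N_{rare}} and rare-group
#' coefficient of variation \eqn{\hat\gamma^2} (floored at 0),
#' \deqn{ACE = S_{abund} + S_{rare} / C_{ACE} + (F_1 / C_{ACE}) \hat\gamma^2.}
#' When every rare taxon is a singleton the coverage is 0 and the estimator
#' is undefined; [chao1()] is returned instead with a warning.
#'
#' @inheritParams shannon
#' @param rare_threshold Largest count still considered "rare" (default 10,
#'   the community convention).
#' @return Estimated richness.
#' @export
ace <- function(counts, rare_threshold = 10) {
  check_counts(counts, integer = TRUE)
  counts <- counts[counts > 0]
  if (!length(counts)) stop("ACE undefined for an all-zero vector")
  rare <- counts[counts <= rare_threshold]
  s_abund <- sum(counts > rare_threshold)
  s_rare <- length(rare)
  if (s_rare == 0) return(sum(counts > 0))  # no rare group: S_obs
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) {
    warning("all rare taxa are singletons (C_ace = 0); falling back to Chao1")
    return(chao1(counts))
  }
  i <- seq_len(rare_threshold)
  f_i <- vapply(i, function(k) sum(rare == k), numeric(1))
  gamma2 <- max(s_rare / c_ace * sum(i * (i - 1) * f_i) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Good's coverage
#'
#' \eqn{C = 1 - F_1 / N}: the estimated probability that the next read
#' belongs to an already observed taxon.
#'
#' @inheritParams shannon
#' @return Coverage in \[0, 1\].
#' @export
goods_coverage <- function(counts) {
  check_counts(counts, integer = TRUE)
  n <- sum(counts)
  if (n <= 0) stop("coverage undefined for an all-zero vector")
  1 - sum(counts == 1) / n
}

#' Per-sample alpha-diversity report
#'
#' Computes, for every sample of a counts table, the total read count,
#' observed richness, singleton and doubleton counts, Shannon, Simpson
#' dominance, Chao1, ACE and Good's coverage.
#'
#' @param x A [count_table()] with `unit = "counts"`.
#' @param rare_threshold Passed to [ace()].
#' @return A data frame with one row per sample.
#' @export
alpha_report <- function(x, rare_threshold = 10) {
  if (!inherits(x, "count_table")) stop("'x' must be a count_table")
  if (table_unit(x) != "counts")
    stop("alpha-diversity estimators require raw counts, not ",
         table_unit(x))
  rows <- lapply(sample_ids(x), function(s) {
    v <- as.numeric(x[s, ])
    data.frame(sample_id = s,
               seq_num = sum(v),
               s_obs = sum(v > 0),
               f1 = sum(v == 1),
               f2 = sum(v == 2),
               shannon = shannon(v),
               simpson = simpson(v),
               chao1 = chao1(v),
               ace = ace(v, rare_threshold = rare_threshold),
               coverage = goods_coverage(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

check_counts <- function(counts, integer = FALSE) {
  if (!is.numeric(counts) || !length(counts))
    stop("'counts' must be a non-empty numeric vector")
  if (anyNA(counts)) stop("'counts' must not contain missing values")
  if (any(counts < 0)) stop("'counts' must be non-negative")
  if (integer && any(abs(counts - round(counts)) > 1e-8))
    stop("richness estimators require integer counts")
  invisible(TRUE)
}
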