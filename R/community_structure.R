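#' Convert an abundance table to relative abundances (percent)
#'
#' Each sample row is rescaled to sum to 100.
#'
#' @param x A [count_table()] (any unit; rows must have positive sums).
#' @return A `count_table` with `unit = "percent"`.
#' @export
relative_abundance <- function(x) {
  if (!inherits(x, "count_table")) stop("'x' must be a count_table")
  rs <- rowSums(x)
  if (any(rs <= 0))
    stop("zero-sum sample(s): ",
         paste(sample_ids(x)[rs <= 0], collapse = ", "))
  count_table(unclass_table(x) / rs * 100, unit = "percent")
}

#' Rank the most abundant taxa per sample
#'
#' Taxa are ranked within each sample by relative abundance, descending,
#' with ties broken lexicographically by taxon id.  Taxa named in `exclude`
#' (e.g. an "Unclassified" bucket) are removed before ranking.
#'
#' @param x A [count_table()].
#' @param n Number of top taxa to report per sample.
#' @param exclude Character vector of taxon ids to drop before ranking.
#' @return A data frame with columns `sample_id`, `rank`, `taxon_id`,
#'   `abundance` (percent of the retained taxa... relative to the full
#'   sample total, i.e. excluded taxa still count towards the denominator).
#' @export
top_taxa <- function(x, n, exclude = character()) {
  if (!inherits(x, "count_table")) stop("'x' must be a count_table")
  if (n < 1) stop("'n' must be at least 1")
  rel <- relative_abundance(x)
  keep <- setdiff(taxon_ids(rel), exclude)
  if (!length(keep)) stop("no taxa left after exclusion")
  if (n > length(keep)) {
    warning(sprintf("n = %d exceeds the %d available taxa; returning all",
                    n, length(keep)))
    n <- length(keep)
  }
  rows <- lapply(sample_ids(rel), function(s) {
    v <- rel[s, keep]
    ord <- order(-v, keep)  # descending abundance, ties lexicographic
    data.frame(sample_id = s,
               rank = seq_len(n),
               taxon_id = keep[ord][seq_len(n)],
               abundance = unname(v[ord][seq_len(n)]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pool samples into groups by averaging
#'
#' Each group's abundance is the arithmetic mean of its member samples'
#' values, per taxon.  This is the pooling rule that turns per-sample
#' relative abundances into per-origin rows (e.g. samples A1 and A3 from
#' nearby origins pooled into a single "A1/A3" point).
#'
#' @param x A [count_table()] (typically percent).
#' @param grouping Named character vector mapping sample id -> group label,
#'   e.g. `c(A1 = "A1/A3", A3 = "A1/A3")`.  Every named sample must exist in
#'   `x`; samples not named are dropped.
#' @return A `count_table` over the groups, in order of first appearance.
#' @export
pool_groups <- function(x, grouping) {
  if (!inherits(x, "count_table")) stop("'x' must be a count_table")
  if (is.null(names(grouping)))
    stop("'grouping' must be a named vector: sample id -> group label")
  unknown <- setdiff(names(grouping), sample_ids(x))
  if (length(unknown))
    stop("unknown sample(s) in grouping: ", paste(unknown, collapse = ", "))
  groups <- unique(unname(grouping))
  m <- t(vapply(groups, function(g) {
    members <- names(grouping)[grouping == g]
    colMeans(unclass_table(x)[members, , drop = FALSE])
  }, numeric(ncol(x))))
  rownames(m) <- groups
  colnames(m) <- taxon_ids(x)
  count_table(m, unit = table_unit(x))
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{BC(i,j) = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})},
#' computed with [vegan::vegdist()].  A pair of all-zero samples has an
#' undefined quotient and is reported as distance 0 with a warning.
#'
#' @param x A [count_table()] with at least two samples.
#' @return A `dist` object with `method` label `"braycurtis"`.
#' @export
bray_curtis <- function(x) {
  community_dist(x, "bray", "braycurtis", binary = FALSE)
}

#' Jaccard distance on presence/absence
#'
#' One minus the Jaccard similarity of the presence sets of two samples.
#'
#' @inheritParams bray_curtis
#' @return A `dist` object with `method` label `"jaccard"`.
#' @export
jaccard_distance <- function(x) {
  community_dist(x, "jaccard", "jaccard", binary = TRUE)
}

community_dist <- function(x, vegdist_method, label, binary) {
  if (!inherits(x, "count_table")) stop("'x' must be a count_table")
  if (nrow(x) < 2) stop("at least two samples are required")
  m <- unclass_table(x)
  d <- suppressWarnings(
    vegan::vegdist(m, method = vegdist_method, binary = binary))
  if (anyNA(d)) {
    warning("all-zero sample pair(s); their distance is defined as 0")
    d[is.na(d)] <- 0
  }
  attr(d, "method") <- label
  d
}

#' UniFrac distance between samples
#'
#' Phylogenetic beta diversity over a rooted tree with branch lengths.
#' Unweighted UniFrac is the fraction of the branch length of the union of
#' the two communities' subtrees that is unique to one community.  Weighted
#' UniFrac sums branch lengths weighted by the absolute difference in the
#' relative abundance carried through each branch,
#' \eqn{\sum_b L_b |p_{ib} - p_{jb}|}, optionally normalized by
#' \eqn{\sum_b L_b (p_{ib} + p_{jb})} so it lies in \[0, 1\].
#'
#' Tree tips absent from the table are pruned; any taxon with positive
#' abundance that is missing from the tree is an error.
#'
#' @param x A [count_table()].
#' @param tree An [ape::phylo] tree whose tip labels are taxon ids.
#' @param weighted Use abundance weighting (default `FALSE`).
#' @param normalized For weighted UniFrac, normalize to \[0, 1\]
#'   (default `TRUE`); ignored when `weighted = FALSE`.
#' @return A `dist` object with `method` label `"unifrac"`/`"wunifrac"`.
#' @export
unifrac <- function(x, tree, weighted = FALSE, normalized = TRUE) {
  if (!inherits(x, "count_table")) stop("'x' must be a count_table")
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape phylo tree")
  if (nrow(x) < 2) stop("at least two samples are required")
  present <- taxon_ids(x)[colSums(x) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("taxa absent from the tree: ", paste(missing, collapse = ", "))
  extra <- setdiff(tree$tip.label, taxon_ids(x))
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")

  m <- unclass_table(x)[, tree$tip.label, drop = FALSE]
  n_tip <- length(tree$tip.label)
  # tip sets under each edge (edge -> child node -> descendant tips)
  clades <- edge_tip_sets(tree)
  lens <- tree$edge.length
  # per-sample branch mass: fraction of the sample's total under each edge
  rs <- rowSums(m)
  rel <- m / ifelse(rs > 0, rs, 1)
  branch_mass <- vapply(clades, function(tips)
    rowSums(rel[, tips, drop = FALSE]), numeric(nrow(m)))
  if (nrow(m) == 1) branch_mass <- matrix(branch_mass, nrow = 1)

  n <- nrow(m)
  dm <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    pi <- branch_mass[i, ]; pj <- branch_mass[j, ]
    if (weighted) {
      num <- sum(lens * abs(pi - pj))
      dm[i, j] <- if (normalized) {
        den <- sum(lens * (pi + pj))
        if (den > 0) num / den else 0
      } else num
    } else {
      ai <- pi > 0; aj <- pj > 0
      union_len <- sum(lens[ai | aj])
      dm[i, j] <- if (union_len > 0) sum(lens[xor(ai, aj)]) / union_len else 0
    }
    dm[j, i] <- dm[i, j]
  }
  d <- stats::as.dist(dm)
  attr(d, "method") <- if (weighted) "wunifrac" else "unifrac"
  d
}

# list over edges of the tip labels descending from each edge's child node
edge_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  collect <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], collect), use.names = FALSE)
  }
  lapply(tree$edge[, 2], collect)
}

#' UPGMA (average-linkage) clustering of a distance matrix
#'
#' Agglomerates with [stats::hclust()] `method = "average"`, producing an
#' ultrametric dendrogram whose merge heights are non-decreasing.
#'
#' @param d A `dist` object without missing values.
#' @return An `hclust` object.
#' @seealso [ape::as.phylo()] to export the dendrogram as Newick.
#' @export
upgma <- function(d) {
  if (!inherits(d, "dist")) stop("'d' must be a dist object")
  if (anyNA(d)) stop("distance matrix contains missing values")
  if (attr(d, "Size") < 2) stop("at least two observations are required")
  stats::hclust(d, method = "average")
}
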