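# Shared fixtures and independently coded oracles.

make_ct <- function(values, samples = NULL, taxa = NULL, unit = "counts") {
  m <- as.matrix(values)
  rownames(m) <- if (is.null(samples)) paste0("s", seq_len(nrow(m))) else samples
  colnames(m) <- if (is.null(taxa)) paste0("t", seq_len(ncol(m))) else taxa
  count_table(m, unit = unit)
}

pooled_genus_table <- function() {
  read_count_table(rhizolink_example("znitidum_pooled_genus_percent.tsv"),
                   unit = "percent")
}

nitidine_parent <- function() {
  df <- utils::read.delim(rhizolink_example("znitidum_nitidine_chloride.tsv"))
  stats::setNames(df[[2]], df[[1]])
}

golden_gra <- function() {
  tab <- pooled_genus_table()
  grey_relation(nitidine_parent()[sample_ids(tab)], tab, rho = 0.5,
                normalization = "mean")
}

# published per-point grey relational coefficients over the three pooled
# origins, by taxon label
published_coefficients <- local({
  vals <- rbind(
    `A1/A3` = c(unclassified = 0.627, Sphingomonas = 0.585,
                Povallibacter = 0.703, Bradyrhizobium = 0.950,
                Gemmatimonas = 0.735, Rudaea = 0.754, Lysobacter = 0.352,
                Erwinia = 0.751, Pantoea = 0.735, Lacibacterium = 0.338,
                Subdivision3_genera_incertae_sedis = 0.882, Gp2 = 0.765,
                Gp1 = 0.777, Gp6 = 0.387,
                Spartobacteria_genera_incertae_sedis = 1.000),
    `A2/B1` = c(unclassified = 0.753, Sphingomonas = 0.747,
                Povallibacter = 0.521, Bradyrhizobium = 0.654,
                Gemmatimonas = 0.841, Rudaea = 0.865, Lysobacter = 0.697,
                Erwinia = 0.694, Pantoea = 0.693, Lacibacterium = 0.708,
                Subdivision3_genera_incertae_sedis = 0.558, Gp2 = 0.431,
                Gp1 = 0.421, Gp6 = 0.798,
                Spartobacteria_genera_incertae_sedis = 0.491),
    `B2/B3` = c(unclassified = 0.516, Sphingomonas = 0.737,
                Povallibacter = 0.424, Bradyrhizobium = 0.626,
                Gemmatimonas = 0.639, Rudaea = 0.668, Lysobacter = 0.419,
                Erwinia = 0.559, Pantoea = 0.550, Lacibacterium = 0.396,
                Subdivision3_genera_incertae_sedis = 0.515, Gp2 = 0.501,
                Gp1 = 0.483, Gp6 = 0.431,
                Spartobacteria_genera_incertae_sedis = 0.495))
  function() vals
})

# published grey relational degrees, in ranked order
published_degrees <- function() {
  c(Rudaea = 0.762, Bradyrhizobium = 0.744, Gemmatimonas = 0.739,
    Sphingomonas = 0.690, Erwinia = 0.668,
    Spartobacteria_genera_incertae_sedis = 0.662, Pantoea = 0.659,
    Subdivision3_genera_incertae_sedis = 0.651, unclassified = 0.632,
    Gp2 = 0.566, Gp1 = 0.560, Povallibacter = 0.549, Gp6 = 0.539,
    Lysobacter = 0.489, Lacibacterium = 0.481)
}

# --- independent oracles -------------------------------------------------

# ACE by direct transcription of the Chao-Lee estimator, written against
# frequency-of-frequency counts rather than the vectorized package path
ace_oracle <- function(counts, rare_threshold = 10) {
  counts <- counts[counts > 0]
  rare <- counts[counts <= rare_threshold]
  abund <- counts[counts > rare_threshold]
  if (length(rare) == 0) return(length(abund))
  n_rare <- sum(rare)
  f <- tabulate(rare, nbins = rare_threshold)
  c_ace <- 1 - f[1] / n_rare
  s_rare <- length(rare)
  num <- 0
  for (i in seq_len(rare_threshold)) num <- num + i * (i - 1) * f[i]
  gamma2 <- max(s_rare * num / (c_ace * n_rare * (n_rare - 1)) - 1, 0)
  length(abund) + s_rare / c_ace + f[1] * gamma2 / c_ace
}

bray_oracle <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- sum(abs(m[i, ] - m[j, ]))
    den <- sum(m[i, ] + m[j, ])
    d[i, j] <- if (den > 0) num / den else 0
  }
  d
}

jaccard_oracle <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- m[i, ] > 0; b <- m[j, ] > 0
    u <- sum(a | b)
    d[i, j] <- if (u > 0) 1 - sum(a & b) / u else 0
  }
  d
}

# UniFrac by path enumeration: the branch set of a community is the union of
# edges on the root-to-tip paths of its present taxa
unifrac_oracle <- function(m, tree, weighted = FALSE) {
  root <- length(tree$tip.label) + 1L
  edge_id <- function(child) which(tree$edge[, 2] == child)
  tip_edges <- lapply(seq_along(tree$tip.label), function(t) {
    path <- ape::nodepath(tree, root, t)
    vapply(path[-1], edge_id, integer(1))
  })
  names(tip_edges) <- tree$tip.label
  lens <- tree$edge.length
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (weighted) {
      pi <- m[i, ] / sum(m[i, ]); pj <- m[j, ] / sum(m[j, ])
      mass_i <- mass_j <- numeric(length(lens))
      for (t in colnames(m)) {
        mass_i[tip_edges[[t]]] <- mass_i[tip_edges[[t]]] + pi[t]
        mass_j[tip_edges[[t]]] <- mass_j[tip_edges[[t]]] + pj[t]
      }
      num <- sum(lens * abs(mass_i - mass_j))
      den <- sum(lens * (mass_i + mass_j))
      d[i, j] <- if (den > 0) num / den else 0
    } else {
      ei <- unique(unlist(tip_edges[colnames(m)[m[i, ] > 0]]))
      ej <- unique(unlist(tip_edges[colnames(m)[m[j, ] > 0]]))
      u <- union(ei, ej)
      uniq <- setdiff(u, intersect(ei, ej))
      d[i, j] <- if (length(u)) sum(lens[uniq]) / sum(lens[u]) else 0
    }
  }
  d
}

# constrained ordination from first principles: centre Y, standardize X,
# project, eigendecompose the fitted and residual covariances
rda_oracle <- function(Y, X) {
  Yc <- scale(Y, scale = FALSE)
  Xs <- scale(X)
  n <- nrow(Y)
  H <- Xs %*% solve(crossprod(Xs)) %*% t(Xs)
  Yhat <- H %*% Yc
  eig_c <- eigen(crossprod(Yhat) / (n - 1), symmetric = TRUE,
                 only.values = TRUE)$values
  eig_u <- eigen(crossprod(Yc - Yhat) / (n - 1), symmetric = TRUE,
                 only.values = TRUE)$values
  total <- sum(Yc^2) / (n - 1)
  list(constrained = eig_c[eig_c > 1e-10],
       unconstrained = eig_u[eig_u > 1e-10],
       total = total,
       fraction = sum(eig_c[eig_c > 0]) / total)
}
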