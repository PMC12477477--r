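test_that("relative_abundance rescales rows to 100", {
  ct <- make_ct(rbind(c(30, 70), c(1, 3)))
  rel <- relative_abundance(ct)
  expect_equal(unname(rel[, ]), rbind(c(30, 70), c(25, 75)))
  expect_identical(table_unit(rel), "percent")
  expect_equal(unname(relative_abundance(make_ct(cbind(7)))[1, 1]), 100)
  expect_equal(unname(relative_abundance(make_ct(rbind(c(1, 1, 2))))[1, ]),
               c(25, 25, 50))
  expect_error(relative_abundance(make_ct(rbind(c(1, 2), c(0, 0)))), "s2")
})

test_that("top_taxa ranks by abundance with lexicographic ties and exclusion", {
  # the most abundant genus of the B2/B3-style profile leads the ranking
  b3 <- make_ct(rbind(c(19.14, 18.32, 4.04, 3.07, 2.93)), samples = "B3",
                taxa = c("Sphingomonas", "unclassified", "Rudaea",
                         "Bradyrhizobium", "Gemmatimonas"), unit = "percent")
  tt <- top_taxa(b3, n = 5)
  expect_identical(tt$taxon_id[1], "Sphingomonas")
  tt2 <- top_taxa(b3, n = 1, exclude = c("Sphingomonas", "unclassified"))
  expect_identical(tt2$taxon_id, "Rudaea")
  # tie at equal abundance resolves lexicographically
  tie <- make_ct(rbind(c(10, 10, 80)), taxa = c("zeta", "alpha", "major"))
  expect_identical(top_taxa(tie, 3)$taxon_id, c("major", "alpha", "zeta"))
  expect_warning(out <- top_taxa(tie, 5), "exceeds")
  expect_equal(nrow(out), 3)
  expect_identical(top_taxa(make_ct(cbind(3)), 1)$taxon_id, "t1")
})

test_that("pool_groups averages member samples and reproduces published cells", {
  per_sample <- read_count_table(
    rhizolink_example("znitidum_genus_percent_per_sample.tsv"),
    unit = "percent")
  pooled <- pool_groups(per_sample, c(A1 = "A1/A3", A3 = "A1/A3"))
  expect_equal(unname(pooled["A1/A3", "unclassified"]), 29.875)
  expect_equal(unname(pooled["A1/A3", "Sphingomonas"]), 9.07)
  expect_equal(unname(pooled["A1/A3", "Gp6"]), 8.7)
  # a singleton group is the identity
  solo <- pool_groups(per_sample, c(A1 = "only"))
  expect_equal(unname(unclass(solo)["only", ]),
               unname(unclass(per_sample)["A1", ]))
  expect_error(pool_groups(per_sample, c(Zz = "g")), "unknown sample")
})

test_that("pooling is idempotent and commutes with relative_abundance at equal depth", {
  ct <- make_ct(rbind(c(10, 20, 30), c(30, 20, 10), c(5, 5, 50)))
  g <- c(s1 = "a", s2 = "a", s3 = "b")
  pooled <- pool_groups(ct, g)
  again <- pool_groups(pooled, c(a = "a", b = "b"))
  expect_equal(unclass(again), unclass(pooled))
  # equal-depth rows: mean of percentages == percentage of mean counts
  expect_equal(unclass(pool_groups(relative_abundance(ct), g)),
               unclass(relative_abundance(pool_groups(ct, g))))
})

test_that("bray-curtis and jaccard match hand cases and the brute-force oracle", {
  same <- make_ct(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(max(bray_curtis(same)), 0)
  expect_equal(max(jaccard_distance(same)), 0)
  disjoint <- make_ct(rbind(c(1, 0), c(0, 1)))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)
  expect_equal(as.numeric(jaccard_distance(disjoint)), 1)
  set.seed(5)
  for (i in 1:15) {
    m <- matrix(rpois(5 * 8, 2), 5, 8,
                dimnames = list(paste0("s", 1:5), paste0("t", 1:8)))
    m[1, ] <- m[1, ] + 1  # avoid all-zero rows
    ct <- make_ct(m, samples = rownames(m), taxa = colnames(m))
    bc <- as.matrix(bray_curtis(ct))
    expect_equal(unname(bc), unname(bray_oracle(m)), tolerance = 1e-12)
    expect_true(isSymmetric(bc) && all(diag(bc) == 0))
    expect_true(all(bc >= 0 & bc <= 1))
    jd <- as.matrix(jaccard_distance(ct))
    expect_equal(unname(jd), unname(jaccard_oracle(m)), tolerance = 1e-12)
  }
  allzero <- make_ct(rbind(c(0, 0), c(0, 0), c(1, 1)))
  expect_warning(d <- bray_curtis(allzero), "all-zero")
  expect_equal(as.matrix(d)["s1", "s2"], 0)
})

test_that("unifrac matches hand partition, the path oracle, and picante", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  ct <- make_ct(rbind(c(5, 0, 0), c(0, 0, 4)), taxa = c("A", "B", "C"))
  d <- unifrac(ct, tr)
  expect_equal(as.numeric(d), 1)  # all union branch length is unique
  same <- make_ct(rbind(c(1, 1, 1), c(2, 2, 2)), taxa = c("A", "B", "C"))
  expect_equal(as.numeric(unifrac(same, tr)), 0)
  expect_equal(as.numeric(unifrac(same, tr, weighted = TRUE)), 0)
  # disjoint taxa on a star tree with equal branch lengths: full turnover
  star <- read_newick("(A:1,B:1,C:1,D:1);")
  dis <- make_ct(rbind(c(1, 2, 0, 0), c(0, 0, 3, 1)),
                 taxa = c("A", "B", "C", "D"))
  expect_equal(as.numeric(unifrac(dis, star)), 1)
  expect_error(unifrac(make_ct(rbind(c(1, 2), c(2, 1)), taxa = c("A", "X")),
                       tr), "X")
  set.seed(21)
  for (i in 1:8) {
    tree <- simulate_tree(paste0("t", 1:8), seed = i)
    m <- matrix(rpois(5 * 8, 3), 5, 8,
                dimnames = list(paste0("s", 1:5), paste0("t", 1:8)))
    m <- m + 1  # every taxon present: exercises the weighted mass path too
    ct <- make_ct(m, samples = rownames(m), taxa = colnames(m))
    expect_equal(as.matrix(unifrac(ct, tree)),
                 unifrac_oracle(m, tree), tolerance = 1e-12)
    expect_equal(as.matrix(unifrac(ct, tree, weighted = TRUE)),
                 unifrac_oracle(m, tree, weighted = TRUE), tolerance = 1e-12)
  }
  skip_if_not_installed("picante")
  set.seed(31)
  tree <- simulate_tree(paste0("t", 1:10), seed = 99)
  m <- matrix(rbinom(4 * 10, 5, 0.4), 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("t", 1:10)))
  m[, 1] <- m[, 1] + 1
  ct <- make_ct(m, samples = rownames(m), taxa = colnames(m))
  expect_equal(as.matrix(unifrac(ct, tree)),
               as.matrix(picante::unifrac(m, tree)), tolerance = 1e-10)
})

test_that("upgma agglomerates with non-decreasing ultrametric heights", {
  d2 <- stats::as.dist(matrix(c(0, 0.4, 0.4, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  hc <- upgma(d2)
  expect_equal(hc$height, 0.4)
  m <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  hc3 <- upgma(stats::as.dist(m))
  expect_equal(hc3$height, c(1, 10))   # (1,2) first, then at exactly 10
  expect_equal(sort(abs(hc3$merge[1, ])), c(1, 2))
  # ultrametric input is reproduced exactly; heights never decrease
  set.seed(3)
  for (i in 1:10) {
    ct <- make_ct(matrix(rpois(24, 6), 4, 6))
    h <- upgma(bray_curtis(ct))
    expect_true(all(diff(h$height) >= -1e-12))
  }
  dd <- bray_curtis(make_ct(matrix(rpois(12, 5), 3, 4)))
  dd[1] <- NaN
  expect_error(upgma(dd), "missing")
})
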