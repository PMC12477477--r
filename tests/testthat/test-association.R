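test_that("mean normalization rescales to unit mean and is idempotent", {
  expect_equal(mean_normalize(c(0.205, 0.25, 0.87)),
               c(0.46415, 0.56604, 1.96981), tolerance = 1e-5)
  expect_equal(mean_normalize(c(3, 3, 3)), c(1, 1, 1))
  v <- c(0.2, 1.5, 7)
  expect_equal(mean_normalize(mean_normalize(v)), mean_normalize(v))
  expect_error(mean_normalize(c(0, 0)), "positive")
})

test_that("a series identical to the parent attains coefficient 1 throughout", {
  p <- c(1, 3, 2, 5)
  gr <- grey_relation(p, cbind(self = p, other = c(2, 2, 2, 2)))
  expect_true(all(gr$xi[, "self"] == 1))
  expect_equal(unname(gr$degrees["self"]), 1)
  # degenerate: every series equals the parent
  gr2 <- grey_relation(p, cbind(a = p, b = p))
  expect_true(all(gr2$xi == 1))
})

test_that("the pooled genus fixture reproduces the published coefficients", {
  gr <- golden_gra()
  expect_equal(unname(gr$xi[, "Rudaea"]), c(0.754, 0.865, 0.668),
               tolerance = 2e-3)
  expect_equal(unname(round(gr$degrees["Rudaea"], 3)), 0.762)
  expect_equal(unname(gr$xi[, "Lacibacterium"]), c(0.338, 0.708, 0.396),
               tolerance = 2e-3)
  expect_equal(unname(round(gr$degrees["Lacibacterium"], 3)), 0.481)
  # global extrema: both attained at the first pooled point
  expect_equal(gr$delta_min, 0.01867149, tolerance = 1e-6)
  expect_equal(gr$delta_max, 2.423985, tolerance = 1e-6)
  amin <- which(gr$delta == gr$delta_min, arr.ind = TRUE)
  expect_identical(colnames(gr$delta)[amin[1, 2]],
                   "Spartobacteria_genera_incertae_sedis")
  amax <- which(gr$delta == gr$delta_max, arr.ind = TRUE)
  expect_identical(colnames(gr$delta)[amax[1, 2]], "Lacibacterium")
  expect_identical(rownames(gr$delta)[c(amin[1, 1], amax[1, 1])],
                   rep("A1/A3", 2))
})

test_that("grey relational coefficients are scale invariant and in (0, 1]", {
  set.seed(23)
  p <- runif(5, 0.1, 2)
  s <- matrix(runif(15, 0.1, 5), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  base <- grey_relation(p, s)
  for (i in 1:20) {
    k_p <- runif(1, 0.01, 100)
    k_s <- runif(3, 0.01, 100)
    scaled <- grey_relation(k_p * p, sweep(s, 2, k_s, `*`))
    expect_equal(scaled$xi, base$xi, tolerance = 1e-12)
    expect_equal(scaled$degrees, base$degrees, tolerance = 1e-12)
  }
  expect_true(all(base$xi > 0 & base$xi <= 1))
  expect_equal(sum(base$xi == 1), sum(base$delta == base$delta_min))
})

test_that("raising the resolution coefficient raises every off-minimum coefficient", {
  gr_lo <- golden_gra()
  tab <- pooled_genus_table()
  gr_hi <- grey_relation(nitidine_parent()[sample_ids(tab)], tab, rho = 0.9)
  off <- gr_lo$delta > gr_lo$delta_min
  expect_true(all(gr_hi$xi[off] > gr_lo$xi[off]))
  expect_true(all(gr_hi$xi[!off] == 1))
})

test_that("ranking breaks degree ties lexicographically and rounds only on report", {
  p <- c(1, 2, 3)
  s <- cbind(zeta = c(2, 4, 6), alpha = c(2, 4, 6))
  gr <- grey_relation(p, s)
  expect_identical(gr$ranking, c("alpha", "zeta"))
  rpt <- gra_rank_report(gr, digits = 3)
  expect_identical(rpt$label, c("alpha", "zeta"))
  expect_identical(rpt$degree[1], rpt$degree[2])
  # internal degrees retain full precision; rounding happens only on report
  golden <- golden_gra()
  expect_false(any(golden$degrees == round(golden$degrees, 3)))
  expect_true(all(gra_rank_report(golden)$degree ==
                    round(gra_rank_report(golden)$degree, 3)))
})

test_that("grey relation rejects invalid inputs", {
  p <- c(1, 2, 3)
  s <- cbind(a = c(1, 2, 3))
  expect_error(grey_relation(p, s, rho = 0), "rho")
  expect_error(grey_relation(p, s, rho = 1.2), "rho")
  expect_error(grey_relation(c(1, 2), s), "length")
  expect_error(grey_relation(p, unname(s)), "labelled")
})

test_that("alternate normalizations are available and differ from the default", {
  tab <- pooled_genus_table()
  p <- nitidine_parent()[sample_ids(tab)]
  gr_init <- grey_relation(p, tab, normalization = "initial")
  expect_s3_class(gr_init, "grey_relation")
  expect_false(isTRUE(all.equal(gr_init$degrees, golden_gra()$degrees)))
})

test_that("correlation network flags perfect correlations and constant taxa", {
  set.seed(29)
  x <- rnorm(8)
  m <- cbind(a = x, dup = x, neg = -x, noise = rnorm(8), flat = rep(2, 8))
  ct <- make_ct(m - min(m) + 0.1, taxa = colnames(m))
  expect_warning(net <- correlation_network(ct, top_n = 5, method = "spearman"),
                 "constant")
  expect_equal(net$rho["a", "dup"], 1)
  expect_equal(net$rho["a", "neg"], -1)
  expect_true(any(net$edges$taxon_a == "a" & net$edges$taxon_b == "dup" |
                  net$edges$taxon_a == "dup" & net$edges$taxon_b == "a"))
  expect_true(all(is.na(net$rho["flat", setdiff(colnames(m), "flat")])))
  expect_true(all(abs(net$rho) <= 1, na.rm = TRUE))
  # top_n restricts to the most abundant taxa
  net2 <- suppressWarnings(correlation_network(ct, top_n = 3))
  expect_length(net2$taxon_ids, 3)
})

test_that("benjamini-hochberg adjustment never admits more edges", {
  set.seed(37)
  m <- matrix(rexp(10 * 12), 10, 12,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:12)))
  ct <- make_ct(m, samples = rownames(m), taxa = colnames(m))
  plain <- correlation_network(ct, top_n = 12)
  bh <- correlation_network(ct, top_n = 12, adjust = "BH")
  expect_lte(nrow(bh$edges), nrow(plain$edges))
})
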