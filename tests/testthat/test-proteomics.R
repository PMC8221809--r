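toy_psms <- function() {
  d <- data.frame(
    protein = c("P1", "P1", "P2", "P3"),
    peptide = c("AAA", "AAB", "BBB", "CCC"),
    psm_id = paste0("psm", 1:4),
    coiso = c(0.1, 0.6, 0.2, 0.1),
    sn = c(30, 40, 20, 5),
    c1 = c(100, 50, 200, 10),
    c2 = c(110, 60, 210, 12),
    c3 = c(120, 70, 220, 14),
    c4 = c(130, 80, 230, 16))
  psm_table(d, paste0("c", 1:4))
}

test_that("filter_aggregate_psms applies both filters and sums per protein", {
  m <- filter_aggregate_psms(toy_psms())
  # P1's second PSM (coiso 0.6) excluded; P3's only PSM fails S/N 5 < 10
  expect_setequal(rownames(m), c("P1", "P2"))
  expect_equal(m["P1", ], c(c1 = 100, c2 = 110, c3 = 120, c4 = 130))
  expect_equal(m["P2", ], c(c1 = 200, c2 = 210, c3 = 220, c4 = 230))

  # all pass when thresholds are relaxed
  m2 <- filter_aggregate_psms(toy_psms(), coiso_max = 1, sn_min = 0)
  expect_equal(m2["P1", "c1"], 150)
  expect_equal(nrow(m2), 3L)

  # empty in, empty out (not an error)
  empty <- toy_psms()[0, ]
  m3 <- filter_aggregate_psms(psm_table(empty, paste0("c", 1:4)))
  expect_equal(nrow(m3), 0L)
})

test_that("loading_normalize: identity, arithmetic, equal-sum property, idempotence", {
  m <- matrix(c(1, 2, 1, 2), 2, 2, dimnames = list(c("P1", "P2"), c("a", "b")))
  ln <- loading_normalize(m)
  expect_equal(unname(ln$factors), c(1, 1))
  expect_equal(ln$matrix, m)

  m2 <- matrix(c(40, 60, 120, 180), 2, 2,
               dimnames = list(c("P1", "P2"), c("a", "b")))
  ln2 <- loading_normalize(m2)
  expect_equal(unname(ln2$factors), c(0.5, 1.5))

  set.seed(31)
  m3 <- matrix(rlnorm(200, 10, 1), 20, 10,
               dimnames = list(paste0("P", 1:20), paste0("c", 1:10)))
  ln3 <- loading_normalize(m3)
  sums <- colSums(ln3$matrix)
  expect_lt(max(abs(sums - mean(sums))) / mean(sums), 1e-9)
  # idempotent
  ln4 <- loading_normalize(ln3$matrix)
  expect_equal(ln4$matrix, ln3$matrix, tolerance = 1e-12)
  expect_equal(unname(ln4$factors), rep(1, 10), tolerance = 1e-12)

  m3[, 3] <- 0
  expect_error(loading_normalize(m3), "c3")
})

test_that("log2_center: centering arithmetic and per-kit scale invariance", {
  des <- plex_design(paste0("c", 1:4), kit = c("k1", "k1", "k2", "k2"),
                     sample = paste0("s", 1:4))
  m <- matrix(c(2, 8, 4, 16), 1, 4,
              dimnames = list("P1", paste0("c", 1:4)))
  cen <- log2_center(m, des)
  expect_equal(as.numeric(cen), c(-1, 1, -1, 1))

  # constant protein across a kit -> zeros
  mc <- matrix(c(5, 5, 7, 7), 1, 4, dimnames = list("P1", paste0("c", 1:4)))
  expect_equal(as.numeric(log2_center(mc, des)), rep(0, 4))

  # per-kit global rescaling leaves the centered matrix unchanged
  set.seed(32)
  m2 <- matrix(rlnorm(40, 8, 1), 10, 4,
               dimnames = list(paste0("P", 1:10), paste0("c", 1:4)))
  m2s <- m2; m2s[, 1:2] <- m2s[, 1:2] * 37; m2s[, 3:4] <- m2s[, 3:4] * 0.01
  expect_equal(unclass(log2_center(m2s, des)), unclass(log2_center(m2, des)),
               tolerance = 1e-12, ignore_attr = TRUE)

  m2[1, 1] <- 0
  expect_error(log2_center(m2, des), "impute")
})

test_that("impute_low_abundance: identity, determinism, sub-quantile property", {
  set.seed(33)
  m <- matrix(rlnorm(500, 10, 1), 50, 10,
              dimnames = list(paste0("P", 1:50), paste0("c", 1:10)))
  expect_equal(impute_low_abundance(m, seed = 1), m, ignore_attr = TRUE)

  miss <- m; miss[sample(length(miss), 60)] <- NA
  a <- impute_low_abundance(miss, seed = 7)
  b <- impute_low_abundance(miss, seed = 7)
  expect_identical(a, b)

  for (j in seq_len(ncol(miss))) {
    was_miss <- is.na(miss[, j])
    if (!any(was_miss)) next
    cut <- quantile(miss[!was_miss, j], 0.05, names = FALSE)
    expect_true(all(a[was_miss, j] <= cut))
    expect_identical(a[!was_miss, j], m[!was_miss, j])
  }

  allmiss <- miss; allmiss[, 2] <- NA
  expect_error(impute_low_abundance(allmiss, seed = 1), "fully missing")
})

test_that("bh_adjust matches the brute-force step-up on 1000 random p-vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)   # single test: q = p

  set.seed(34)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # cross-check against the stats implementation too
  p <- runif(500)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("differential_expression: t-test arithmetic, null case, group guards", {
  des <- plex_design(paste0("c", 1:8), kit = "k1", sample = paste0("s", 1:8),
                     group = rep(c("A", "B"), each = 4))
  set.seed(35)
  m <- matrix(rlnorm(80, 8, 0.2), 10, 8,
              dimnames = list(paste0("P", 1:10), paste0("c", 1:8)))
  cen <- log2_center(m, des)
  groups <- setNames(des$group, des$channel)
  de <- differential_expression(cen, groups)

  # oracle: stats::t.test with var.equal = TRUE per protein
  for (i in c(1, 5, 10)) {
    tt <- t.test(cen[i, 5:8], cen[i, 1:4], var.equal = TRUE)
    expect_equal(de$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(de$t[i], unname(tt$statistic), tolerance = 1e-12)
  }
  expect_equal(de$q, bh_adjust(de$p))

  # identical group means with nonzero variance -> t = 0, p = 1
  m1 <- matrix(rep(c(1, 2, 3, 1.5, 1, 2, 3, 1.5), 2), 2, 8, byrow = TRUE,
               dimnames = list(c("Pa", "Pb"), paste0("c", 1:8)))
  de0 <- differential_expression(structure(m1, design = des,
                                           class = c("normalized_matrix", "matrix")),
                                 groups)
  expect_equal(de0$t, c(0, 0))
  expect_equal(de0$p, c(1, 1))

  bad <- setNames(c("A", "A", "A", "A", "A", "A", "A", "B"), des$channel)
  expect_error(differential_expression(cen, bad), ">= 2 channels")
})

test_that("annotation_subset restricts rows and reports the fraction", {
  m <- matrix(1, 4, 2, dimnames = list(c("P1", "P2", "P3", "P4"), c("a", "b")))
  s <- annotation_subset(m, c("P2", "P4", "P9"))
  expect_setequal(rownames(s), c("P2", "P4"))
  expect_equal(attr(s, "subset_fraction"), 0.5)
  expect_identical(rownames(annotation_subset(m, rownames(m))), rownames(m))
  expect_warning(annotation_subset(m, "ZZZ"), "no matrix rows")
  expect_error(annotation_subset(m, character(0)), "empty")
})

test_that("plex_design validates kits and bridges; bridge_qc correlates kits", {
  expect_error(plex_design(c("c1", "c2"), kit = c("k1", "k2"),
                           sample = c("s", "s")), ">= 2 channels")
  expect_error(plex_design(paste0("c", 1:4), kit = c("k1", "k1", "k2", "k2"),
                           sample = paste0("s", 1:4),
                           is_bridge = c(TRUE, FALSE, FALSE, FALSE)),
               "every kit")

  sim <- make_tmt(n_proteins = 40, kits = 2, channels_per_kit = 4, seed = 9)
  des <- sim$design
  des$is_bridge <- des$channel %in% c("k1_c1", "k2_c1")
  m <- loading_normalize(filter_aggregate_psms(sim$psms))$matrix
  cen <- log2_center(m, des)
  qc <- bridge_qc(cen)
  expect_equal(nrow(qc), 1L)
  expect_true(is.finite(qc$cor))
})
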