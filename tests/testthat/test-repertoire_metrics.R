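test_that("clone_frequencies normalizes and orders deterministically", {
  rep <- toy_repertoire(c(30, 70))
  p <- clone_frequencies(rep)
  expect_equal(unname(p), c(0.7, 0.3))
  expect_equal(sum(p), 1)

  expect_equal(unname(clone_frequencies(toy_repertoire(1))), 1)
  expect_equal(unname(clone_frequencies(toy_repertoire(rep(25, 4)))),
               rep(0.25, 4))
  # ties in count are broken by cdr3_nt, so ordering is reproducible
  rep_tie <- toy_repertoire(rep(10, 5))
  expect_identical(names(clone_frequencies(rep_tie)),
                   sort(rep_tie$clonotypes$cdr3_nt))
  expect_error(clone_frequencies(filter_repertoire(toy_repertoire(1),
                                                   min_count = 2)),
               "empty")
})

test_that("diversity formulas reproduce closed-form values", {
  expect_equal(shannon_diversity(c(0.5, 0.5)), 1)
  expect_equal(shannon_diversity(1), 0)
  expect_equal(shannon_diversity(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_diversity(c(0.5, 0.4)), "sum to 1")

  expect_equal(simpson_diversity(1), 0)
  expect_equal(simpson_diversity(rep(0.25, 4)), 0.75)
  expect_equal(simpson_diversity(c(0.9, 0.1)), 0.18)
  expect_equal(simpson_diversity(c(0.9, 0.1), concentration = TRUE), 0.82)

  expect_equal(clonality(1), 1)
  for (S in 2:6) expect_equal(clonality(rep(1 / S, S)), 0)
  expect_equal(clonality(c(0.5, 0.25, 0.25)), 1 - 1.5 / log2(3))
})

test_that("shannon/simpson/clonality agree with high-precision direct summation", {
  set.seed(202)
  for (i in 1:100) {
    S <- sample(2:200, 1)
    p <- runif(S) + 1e-4
    p <- p / sum(p)
    p <- p / sum(p)  # renormalize twice to push sum within 1e-12 of 1
    expect_equal(shannon_diversity(p), oracle_shannon(p), tolerance = 1e-12)
    expect_equal(simpson_diversity(p), oracle_simpson(p), tolerance = 1e-12)
    expect_equal(clonality(p), oracle_clonality(p), tolerance = 1e-12)
  }
})

test_that("metric invariants hold on random repertoires", {
  set.seed(7)
  for (i in 1:25) {
    p <- clone_frequencies(toy_repertoire(sample(1:100, sample(2:30, 1))))
    S <- length(p)
    cl <- clonality(p)
    expect_gte(cl, 0); expect_lte(cl, 1)
    expect_lte(shannon_diversity(p), log2(S) + 1e-12)
    expect_lte(simpson_diversity(p), 1 - 1 / S + 1e-12)
    expect_equal(cl, 1 - shannon_diversity(p) / log2(S), tolerance = 1e-12)
  }
  # equality iff uniform
  u <- rep(1 / 8, 8)
  expect_equal(shannon_diversity(u), 3)
  expect_equal(simpson_diversity(u), 1 - 1 / 8)
})

test_that("clonality strictly decreases as mass moves from largest to smallest clone", {
  # 3-clone sweep: start dominated, shift reads to the smallest clone
  total <- 90L
  prev <- Inf
  for (shift in seq(0L, 25L, by = 5L)) {
    counts <- c(60L - shift, 20L, 10L + shift)
    cl <- clonality(counts / total)
    expect_lt(cl, prev)
    prev <- cl
  }
})

test_that("richness counts distinct clonotypes and warns on raw repertoires", {
  rep5 <- toy_repertoire(rep(10, 5))
  expect_warning(expect_equal(richness(rep5), 5L), "normalize")
  norm <- downsample_reads(toy_repertoire(c(50, 1, 1, 40, 1)), 10, seed = 2)
  expect_lte(richness(norm), 5L)
  expect_silent(richness(norm))
  empty <- filter_repertoire(toy_repertoire(1), min_count = 5)
  expect_equal(richness(empty), 0L)
})

test_that("mean_cdr3_length supports clonotype and read weighting", {
  rep <- toy_repertoire(c(5, 3, 2),
                        cdr3_aa = c(strrep("A", 14), strrep("C", 14),
                                    strrep("D", 16)))
  expect_equal(mean_cdr3_length(rep), mean(c(14, 14, 16)))

  rep2 <- toy_repertoire(c(9, 1), cdr3_aa = c(strrep("A", 10), strrep("C", 20)))
  expect_equal(mean_cdr3_length(rep2), 15)
  expect_equal(mean_cdr3_length(rep2, weighting = "read"), 11)

  rep3 <- toy_repertoire(10, cdr3_aa = "")
  expect_error(mean_cdr3_length(rep3), "cdr3_aa")
})

test_that("shm_fraction applies the strict < 98% germline-identity rule", {
  rep <- toy_repertoire(c(5, 5, 5), locus = "IGH",
                        v_identity = c(100, 97.9, 98.0))
  expect_equal(shm_fraction(rep), 1 / 3)  # 98.0 is NOT mutated
  expect_equal(shm_fraction(toy_repertoire(c(1, 2), locus = "IGH",
                                           v_identity = c(100, 100))), 0)
  expect_equal(shm_fraction(toy_repertoire(c(1, 2), locus = "IGH",
                                           v_identity = c(90, 90))), 1)
  expect_error(shm_fraction(toy_repertoire(5, v_identity = 97)), "IGH")
  expect_error(shm_fraction(toy_repertoire(c(5, 5), locus = "IGH",
                                           v_identity = c(95, NA))),
               "missing")
})

test_that("v_usage builds row-normalized frequency matrices", {
  r1 <- toy_repertoire(c(10, 10, 10), v_gene = c("A", "A", "B"))
  m <- v_usage(list(r1))
  expect_equal(unname(m[1, ]), c(2 / 3, 1 / 3))

  r2 <- toy_repertoire(c(4, 6), v_gene = c("C", "D"), subject_id = "S2")
  m2 <- v_usage(list(r1, r2))
  expect_equal(dim(m2), c(2L, 4L))
  expect_equal(unname(rowSums(m2)), c(1, 1))
  expect_equal(sum(m2[1, c("C", "D")]), 0)  # complementary zeros

  r3 <- toy_repertoire(c(90, 10), v_gene = c("A", "B"))
  expect_equal(unname(v_usage(list(r3), weighting = "read")[1, ]),
               c(0.9, 0.1))
})

test_that("usage_pca decomposes covariance correctly", {
  const <- matrix(rep(c(0.5, 0.3, 0.2), each = 4), nrow = 4)
  res <- usage_pca(const, n_components = 2)
  expect_equal(max(abs(res$scores)), 0)
  expect_equal(res$explained_variance, c(0, 0))

  # rank-1 perturbation: PC1 carries all variance
  pert <- const
  pert[, 1] <- pert[, 1] + c(-0.02, -0.01, 0.01, 0.02)
  pert[, 2] <- pert[, 2] - c(-0.02, -0.01, 0.01, 0.02)
  res1 <- usage_pca(pert, n_components = 2)
  expect_equal(res1$explained_variance[1], 1)
  expect_true(all(diff(res1$explained_variance) <= 1e-12))

  # full-rank reconstruction identity
  set.seed(31)
  x <- matrix(runif(60), nrow = 10)
  x <- x / rowSums(x)
  k <- qr(scale(x, center = TRUE, scale = FALSE))$rank
  res2 <- usage_pca(x, n_components = k)
  recon <- res2$scores %*% t(res2$loadings)
  expect_lt(max(abs(recon - scale(x, center = TRUE, scale = FALSE))), 1e-8)

  expect_error(usage_pca(x[1, , drop = FALSE]), "2 subjects")
})

test_that("repertoire_metrics bundles the statistics and Pgen summaries", {
  single <- toy_repertoire(100)
  m <- repertoire_metrics(single)
  expect_equal(m$clonality, 1)
  expect_equal(m$richness, 1L)
  expect_equal(m$shannon_bits, 0)
  expect_equal(m$evenness, 0)

  rep <- toy_repertoire(c(10, 10))
  rep$clonotypes$pgen <- c(1e-8, 1e-12)
  m2 <- repertoire_metrics(rep)
  expect_equal(m2$public_fraction, 0.5)  # only Pgen > 1e-9 is public
  expect_equal(m2$mean_pgen, mean(c(1e-8, 1e-12)))

  m3 <- repertoire_metrics(toy_repertoire(c(10, 10)))
  expect_true(is.na(m3$mean_pgen))
  expect_true(is.na(m3$public_fraction))
  expect_false(is.na(m3$clonality))

  m4 <- repertoire_metrics(toy_repertoire(c(5, 5)), pgen_model = toy_model())
  expect_false(is.na(m4$mean_pgen))
})

test_that("rarefying a uniform 1000-clone repertoire leaves clonality near 0", {
  rep <- toy_repertoire(rep(10L, 1000))
  for (s in 1:50) {
    d <- downsample_reads(rep, 1000, seed = s)
    expect_lt(clonality(clone_frequencies(d)), 0.05)
  }
})
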