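test_that("allele-sharing dissimilarities match hand computation", {
  g <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), c = c(2, 1, 0, 1))
  asd <- asd_matrix(g)
  expect_equal(asd["a", "b"], 0)
  expect_equal(asd["a", "c"], (2 + 0 + 2 + 0) / 8)
  expect_true(isSymmetric(asd))
  expect_equal(diag(asd), c(a = 0, b = 0, c = 0))

  expect_equal(asd_matrix(rbind(rep(0, 5), rep(2, 5)))[1, 2], 1)

  set.seed(1)
  g2 <- random_genotypes(6, 12)
  expect_equal(unname(asd_matrix(g2)), oracle_asd(g2), tolerance = 1e-12)
})

test_that("missing genotypes are handled pairwise-complete", {
  g <- rbind(c(0, 1, NA, 2), c(0, NA, 1, 0), c(2, 2, 2, 2))
  asd <- asd_matrix(g)
  expect_equal(asd[1, 2], (0 + 2 / 2) / 2)  # sites 1 and 4 only
  g_bad <- rbind(c(NA, 1), c(0, NA))
  expect_error(asd_matrix(g_bad), "no non-missing")
})

test_that("packed and genotype-level ASD agree exactly", {
  set.seed(2)
  L <- 90; n <- 8
  h1 <- matrix(rbinom(L * n, 1, 0.5), L, n)
  h2 <- matrix(rbinom(L * n, 1, 0.5), L, n)
  geno <- t(h1 + h2)
  a_plain <- unname(asd_matrix(geno))
  a_packed <- admixabc:::asd_packed_cpp(admixabc:::pack_columns_cpp(h1),
                                        admixabc:::pack_columns_cpp(h2), L)
  expect_equal(a_plain, a_packed, tolerance = 1e-12)
})

test_that("classical MDS recovers planar configurations", {
  set.seed(3)
  pts <- cbind(runif(15), runif(15))
  d <- as.matrix(dist(pts))
  emb <- classical_mds(d, k = 2)
  expect_equal(as.matrix(dist(emb$points)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(colMeans(emb$points), c(0, 0), tolerance = 1e-10)

  # collinear points have a null second axis
  line <- as.matrix(dist(cbind(1:8, 0)))
  emb_line <- classical_mds(line, k = 2)
  expect_lt(max(abs(emb_line$points[, 2])), 1e-6)

  # three mutually equidistant points form an equilateral triangle
  eq <- matrix(1, 3, 3) - diag(3)
  emb_eq <- classical_mds(eq, k = 2)
  side <- dist(emb_eq$points)
  expect_equal(max(side) - min(side), 0, tolerance = 1e-10)

  expect_error(classical_mds(d, k = 1), "k must be")
  expect_error(classical_mds(d[1:2, 1:2], k = 2), "k \\+ 1")
  expect_error(classical_mds(matrix(0, 4, 4), k = 2), "positive eigenvalue")
})

test_that("admixture projection has the documented geometry", {
  # hand-built embedding: AFR centroid (1,0), EUR centroid (-1,0)
  pts <- rbind(c(1, 0.1), c(1, -0.1), c(-1, 0.1), c(-1, -0.1),
               c(1, 0), c(0, 0), c(0, 1))
  emb <- structure(list(points = pts, eig = c(1, 1),
                        labels = c("AFR", "AFR", "EUR", "EUR",
                                   "ADM", "ADM", "ADM")),
                   class = "mds_embedding")
  expect_warning(proj <- project_admixture(emb), "centroid")
  alpha <- proj$projection$alpha
  theta <- proj$projection$theta
  expect_equal(alpha[1], 1)                 # at the African centroid
  expect_equal(alpha[2], 0.5)               # midpoint
  expect_equal(theta[2], pi)                # between the centroids
  expect_equal(alpha[3], 0.5)
  expect_equal(theta[3], pi / 2)            # right angle at unit height
  expect_true(is.na(theta[1]))              # angle undefined at a centroid

  emb_bad <- emb
  emb_bad$points[1:4, ] <- 0
  expect_error(project_admixture(emb_bad), "coincide")
})

test_that("heterozygosity uses the unbiased per-SNP gene diversity", {
  # one site, p = 0.5, n = 10: 0.5 * 20/19
  g <- matrix(c(rep(0, 5), rep(2, 5)), ncol = 1)
  expect_equal(heterozygosity_stats(g)[["mean"]], 0.5 * 20 / 19)

  mono <- matrix(0L, 6, 4)
  expect_equal(unname(heterozygosity_stats(mono)), c(0, 0))

  set.seed(4)
  g2 <- random_genotypes(8, 30)
  expect_equal(unname(heterozygosity_stats(g2)),
               oracle_het(g2), tolerance = 1e-12)
  expect_equal(heterozygosity_stats(g2[sample(8), ]),
               heterozygosity_stats(g2))
})

test_that("inbreeding F is centred at Hardy-Weinberg and unit at fixation", {
  set.seed(5)
  p <- runif(400, 0.2, 0.8)
  hw <- t(replicate(150, rbinom(400, 1, p) + rbinom(400, 1, p)))
  expect_equal(inbreeding_stats(hw)[["mean"]], 0, tolerance = 0.05)

  # every individual fully homozygous: F = 1 identically
  hom <- t(replicate(20, 2 * rbinom(100, 1, 0.5)))
  expect_equal(inbreeding_stats(hom)[["mean"]], 1, tolerance = 1e-12)
  expect_equal(inbreeding_stats(hom)[["variance"]], 0, tolerance = 1e-12)

  set.seed(6)
  g <- random_genotypes(5, 20)
  expect_equal(unname(inbreeding_stats(g)),
               oracle_inbreeding(g), tolerance = 1e-10)

  expect_error(inbreeding_stats(matrix(0L, 4, 6)), "polymorphic")
})

test_that("Weir-Cockerham Fst behaves at its anchors and matches the oracle", {
  # two independent samples of one population: Fst indistinguishable from 0
  set.seed(7)
  p <- runif(1000, 0.1, 0.9)
  A <- t(replicate(60, rbinom(1000, 2, p)))
  B <- t(replicate(60, rbinom(1000, 2, p)))
  expect_lt(abs(wc_fst(A, B)), 0.01)

  fixedA <- matrix(0L, 10, 50); fixedB <- matrix(2L, 10, 50)
  expect_equal(wc_fst(fixedA, fixedB), 1, tolerance = 1e-12)

  set.seed(8)
  gA <- random_genotypes(5, 20); gB <- random_genotypes(6, 20)
  expect_equal(wc_fst(gA, gB), oracle_wc_fst(gA, gB), tolerance = 1e-10)

  expect_error(wc_fst(matrix(0L, 3, 4), matrix(0L, 3, 4)), "monomorphic")
})

test_that("f3 is near zero for one population and negative for mixtures", {
  set.seed(9)
  p <- runif(8000, 0.1, 0.9)
  draw <- function(n) t(replicate(n, rbinom(8000, 2, p)))
  expect_equal(f3_statistic(draw(30), draw(30), draw(30)), 0,
               tolerance = 0.002)

  # H pooled 50/50 from two diverged sources: negative f3
  fr <- generate_source_frequencies(8000, divergence = 0.2)
  srcA <- t(replicate(30, rbinom(8000, 2, fr$afr)))
  srcE <- t(replicate(30, rbinom(8000, 2, fr$eur)))
  H <- rbind(srcA[1:15, ], srcE[1:15, ])
  expect_lt(f3_statistic(H, srcE[16:30, ], srcA[16:30, ]), 0)

  set.seed(10)
  g1 <- random_genotypes(5, 20); g2 <- random_genotypes(5, 20)
  g3 <- random_genotypes(5, 20)
  expect_equal(f3_statistic(g1, g2, g3), oracle_f3(g1, g2, g3),
               tolerance = 1e-10)
})

test_that("the f3 small-sample correction vanishes with sample size", {
  set.seed(11)
  fr <- generate_source_frequencies(4000, divergence = 0.15)
  src1 <- t(replicate(40, rbinom(4000, 2, fr$afr)))
  src2 <- t(replicate(40, rbinom(4000, 2, fr$eur)))
  raw_minus_corrected <- function(n) {
    H <- t(replicate(n, rbinom(4000, 2, (fr$afr + fr$eur) / 2)))
    pH <- colMeans(H) / 2
    mean(pH * (1 - pH) / (2 * n - 1))
  }
  expect_gt(raw_minus_corrected(5), 10 * raw_minus_corrected(100))
})

test_that("distribution summaries follow the documented conventions", {
  cst <- distribution_stats(rep(3.5, 12))
  expect_equal(unname(cst[c("mode", "mean", "min", "max", "d50")]),
               rep(3.5, 5))
  expect_equal(unname(cst[c("variance", "skewness")]), c(0, 0))

  ds <- distribution_stats(1:100)
  expect_equal(unname(ds[paste0("d", seq(10, 90, 10))]),
               c(10.9, 20.8, 30.7, 40.6, 50.5, 60.4, 70.3, 80.2, 90.1))
  expect_equal(ds[["mean"]], 50.5)
  expect_equal(ds[["min"]], 1); expect_equal(ds[["max"]], 100)

  set.seed(12)
  sym <- c(rnorm(4000, -2), rnorm(4000, 2))
  expect_lt(abs(distribution_stats(sym)[["skewness"]]), 0.05)

  # mode of a clearly unimodal sample sits near the density peak
  set.seed(13)
  expect_equal(distribution_stats(rnorm(4000, 7, 0.5))[["mode"]], 7,
               tolerance = 0.15)

  expect_error(distribution_stats(c(1, 2)), "10 values")
})

test_that("the summary vector has 42 named statistics in fixed order", {
  nm <- summary_stat_names()
  expect_length(nm, 42)
  expect_length(grep("^alpha_", nm), 16)
  expect_length(grep("^theta_", nm), 16)
  expect_length(grep("_d[1-9]0$", nm), 18)

  set.seed(14)
  res <- build_reservoir_pair(generate_source_frequencies(500, 0.2), R = 400)
  pv <- make_params("Afr2Pulses-Eur2Pulses", 0.5,
                    make_pulse("African", 15, 6, 0.2, 0.1),
                    make_pulse("European", 12, 3, 0.2, 0.1),
                    N0 = 150, N20 = 300, uN = 0.3)
  ss <- draw_sample_set(run_simulation(pv, res), res, 15)
  sv <- compute_summary_vector(ss)
  expect_identical(names(sv), nm)
  expect_true(all(is.finite(sv)))

  # an admixed sample drawn from the African reservoir itself
  afr_as_H <- list(admixed = sample_source(res$afr, 20),
                   afr = sample_source(res$afr, 30),
                   eur = sample_source(res$eur, 30))
  sv2 <- compute_summary_vector(afr_as_H)
  expect_equal(sv2[["alpha_mean"]], 1, tolerance = 0.1)
  expect_lt(sv2[["fst_afr_H"]], 0.01)
  expect_gt(sv2[["fst_eur_H"]], 0.05)
})

test_that("projected admixture tracks the instrumented truth", {
  set.seed(15)
  res <- build_reservoir_pair(generate_source_frequencies(4000, 0.15),
                              R = 1000)
  pv <- make_params("Afr2Pulses-Eur2Pulses", 0.5,
                    make_pulse("African", 19, 16, 0.3, 0.3),
                    make_pulse("European", 18, 10, 0.2, 0.2),
                    N0 = 400, N20 = 400, uN = 0.3)
  po <- generate_pseudo_observed(pv, res, 40, seed = 99, track = TRUE)
  asd <- asd_matrix(rbind(po$samples$admixed, po$samples$afr,
                          po$samples$eur))
  emb <- classical_mds(asd, 2, labels = c(rep("ADM", 40), rep("AFR", 60),
                                          rep("EUR", 60)))
  proj <- project_admixture(emb)
  rho <- cor(proj$projection$alpha, po$samples$true_afr_fraction,
             method = "spearman")
  expect_gt(rho, 0.9)
})
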