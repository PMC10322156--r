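res_pair <- function(L = 400, R = 300, div = 0.2, seed = 5) {
  set.seed(seed)
  build_reservoir_pair(generate_source_frequencies(L, div), R = R)
}

test_that("reservoirs match their target frequency spectra", {
  set.seed(1)
  freq <- runif(300, 0.05, 0.95)
  res <- build_reservoir(freq, R = 2000, label = "African")
  emp <- rowMeans(reservoir_haplotypes(res))
  # binomial sampling error at R = 2000: |emp - freq| < 4 sd
  expect_true(all(abs(emp - freq) < 4 * sqrt(freq * (1 - freq) / 2000)))

  expect_warning(build_reservoir(c(0.5, 1), R = 50), "monomorphic")
  expect_error(build_reservoir(c(0.5, 1.2), R = 50), "0, 1")

  set.seed(9); r1 <- build_reservoir(freq, R = 100)
  set.seed(9); r2 <- build_reservoir(freq, R = 100)
  expect_identical(r1$haplotypes, r2$haplotypes)
})

test_that("bit packing round-trips haplotypes exactly", {
  set.seed(2)
  h <- matrix(rbinom(71 * 9, 1, 0.4), nrow = 71)
  packed <- admixabc:::pack_columns_cpp(h)
  expect_identical(admixabc:::unpack_columns_cpp(packed, 1:9, 71L), h)
})

test_that("single-source replacement reproduces reservoir frequencies", {
  res <- res_pair(L = 2000, R = 1000)
  set.seed(3)
  pop <- advance_generation(NULL, c(1, 0, 0), res, 400)
  emp <- colMeans(genotypes_of(pop)) / 2
  expect_lt(mean(abs(emp - res$afr$frequencies)), 0.02)
  expect_gt(cor(emp, res$afr$frequencies), 0.98)
})

test_that("pure drift decays gene diversity at the Wright-Fisher rate", {
  res <- res_pair(L = 4000, R = 500)
  set.seed(4)
  N <- 25
  gene_div <- function(pop) {
    p <- colMeans(genotypes_of(pop)) / 2
    mean(2 * p * (1 - p))
  }
  pop <- advance_generation(NULL, c(1, 0, 0), res, N)
  h0 <- gene_div(pop)
  for (g in 1:20) pop <- advance_generation(pop, c(0, 0, 1), res, N)
  # per-generation decay factor fitted over 20 drift generations
  rate <- (gene_div(pop) / h0)^(1 / 20)
  expect_equal(rate, 1 - 1 / (2 * N), tolerance = 0.012)
})

test_that("selfing is impossible: degenerate parental pools error", {
  res <- res_pair()
  set.seed(5)
  one <- advance_generation(NULL, c(1, 0, 0), res, 1)
  expect_error(advance_generation(one, c(0, 0, 1), res, 5),
               "distinct parents|single individual")
})

test_that("instrumented runs track true ancestry through the pedigree", {
  res <- res_pair(L = 800, R = 600)

  # all-African founding, no later gene flow: ancestry identically 1
  pv <- make_params("Afr2Pulses-Eur2Pulses", 1,
                    make_pulse("African", 15, 6, 0, 0),
                    make_pulse("European", 12, 3, 0, 0),
                    N0 = 200, N20 = 200, uN = 0.3)
  set.seed(6)
  pop <- run_simulation(pv, res, track = TRUE)
  expect_equal(unname(true_ancestry_fraction(pop)), rep(1, pop$N))

  # 60/40 founding drifts around 0.6
  pv$s_Afr_0 <- 0.6
  pv$demography <- list(N0 = 600L, N20 = 600L, uN = 0.3)
  set.seed(7)
  pop <- run_simulation(pv, res, track = TRUE)
  expect_equal(mean(true_ancestry_fraction(pop)), 0.6, tolerance = 0.15)

  # one European pulse of 0.5 at g = 10 on an all-African founding
  pv2 <- make_params("Afr2Pulses-Eur2Pulses", 1,
                     make_pulse("African", 15, 6, 0, 0),
                     make_pulse("European", 10, 3, 0.5, 0),
                     N0 = 600, N20 = 600, uN = 0.3)
  set.seed(8)
  pop2 <- run_simulation(pv2, res, track = TRUE)
  expect_equal(mean(true_ancestry_fraction(pop2)), 0.5, tolerance = 0.15)
})

test_that("ancestry-fraction variance narrows over the generations", {
  res <- res_pair(L = 600, R = 600)
  pv <- make_params("Afr2Pulses-Eur2Pulses", 0.5,
                    make_pulse("African", 15, 6, 0, 0),
                    make_pulse("European", 12, 3, 0, 0),
                    N0 = 300, N20 = 300, uN = 0.3)
  sched <- build_schedule(pv)
  set.seed(9)
  g1 <- advance_generation(advance_generation(NULL, sched[1, ], res, 300, TRUE),
                           sched[2, ], res, 300, TRUE)
  set.seed(9)
  g20 <- run_simulation(pv, res, track = TRUE)
  expect_lt(var(true_ancestry_fraction(g20)),
            var(true_ancestry_fraction(g1)))
})

test_that("unrelated sampling excludes any shared grandparent", {
  res <- res_pair()
  pv <- make_params("Afr2Pulses-Eur2Pulses", 0.5,
                    make_pulse("African", 15, 6, 0.1, 0.1),
                    make_pulse("European", 12, 3, 0.1, 0.1),
                    N0 = 250, N20 = 400, uN = 0.3)
  set.seed(10)
  pop <- run_simulation(pv, res)
  idx <- sample_unrelated(pop, 30)
  expect_length(idx, 30)
  gp <- pop$grandparents[idx, ]
  for (i in seq_len(29)) {
    for (j in (i + 1):30) {
      expect_length(intersect(gp[i, ], gp[j, ]), 0)
    }
  }
  expect_length(sample_unrelated(pop, 1), 1)

  # two full siblings can never yield an unrelated pair
  sibs <- pop
  sibs$N <- 2L
  sibs$grandparents <- matrix(c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L),
                              nrow = 2, byrow = TRUE)
  expect_error(sample_unrelated(sibs, 2),
               class = "admixabc_insufficient_unrelated")
})

test_that("source sampling pairs distinct reservoir gametes", {
  res <- res_pair(L = 1000, R = 800)
  set.seed(11)
  g <- sample_source(res$afr, 60)
  expect_equal(dim(g), c(60, 1000))
  expect_true(all(g %in% 0:2))
  expect_lt(mean(abs(colMeans(g) / 2 - res$afr$frequencies)), 0.04)
  expect_equal(nrow(sample_source(res$afr, 0)), 0)
  expect_error(sample_source(res$afr, 500), "2n distinct")
})

test_that("identical seeds give bit-identical simulated samples", {
  res <- res_pair()
  pv <- make_params("AfrRecurring-EurRecurring", 0.5,
                    make_recurring("African", 3, 9, 0.2, 0.1, 0.3),
                    make_recurring("European", 5, 12, 0.2, 0.1, 0.3),
                    N0 = 150, N20 = 300, uN = 0.3)
  set.seed(12)
  s1 <- draw_sample_set(run_simulation(pv, res), res, 20)
  set.seed(12)
  s2 <- draw_sample_set(run_simulation(pv, res), res, 20)
  expect_identical(s1$admixed, s2$admixed)
  expect_identical(s1$afr, s2$afr)
  expect_identical(compute_summary_vector(s1), compute_summary_vector(s2))
})
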