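# compact builders for hand-written tracks (identical haplotypes unless
# hap2 differs)
seg_df <- function(id, chrom, start, end, ancestry, haplotype) {
  data.frame(id = id, haplotype = haplotype, chrom = chrom,
             start = start, end = end, ancestry = ancestry,
             stringsAsFactors = FALSE)
}

both_haps <- function(id, chrom, start, end, ancestry) {
  rbind(seg_df(id, chrom, start, end, ancestry, 1L),
        seg_df(id, chrom, start, end, ancestry, 2L))
}

test_that("ROH length maps to coalescence time as g = 100 / (2 l)", {
  expect_equal(tmrca_from_length(1), 50)
  expect_equal(tmrca_from_length(0.25), 200)
  expect_equal(tmrca_from_length(100), 0.5)
  ls <- seq(0.05, 20, length.out = 50)
  expect_true(all(diff(tmrca_from_length(ls)) < 0))
  expect_error(tmrca_from_length(0), "positive")
})

test_that("length classes put the boundary values in the longer class", {
  expect_identical(roh_size_class(c(0.1, 0.249, 0.25, 0.6, 0.999, 1, 4)),
                   c("short", "short", "medium", "medium", "medium",
                     "long", "long"))
})

test_that("ROH ancestry content partitions length with the midpoint rule", {
  map <- data.frame(chrom = 1, length = 10)

  # fully inside homozygous AFR
  tr <- ancestry_roh_track(
    rbind(both_haps(1, 1, 0, 6, "AFR"), both_haps(1, 1, 6, 10, "EUR")),
    data.frame(id = 1, chrom = 1, start = 1, end = 3), map)
  ct <- roh_ancestry_content(tr)
  expect_equal(ct$afr, 2); expect_equal(ct$eur, 0)
  expect_false(ct$spanning); expect_false(ct$heterozygous)

  # length-2 ROH centred on the homozygous AFR -> EUR switch
  tr2 <- ancestry_roh_track(
    rbind(both_haps(2, 1, 0, 5, "AFR"), both_haps(2, 1, 5, 10, "EUR")),
    data.frame(id = 2, chrom = 1, start = 4, end = 6), map)
  ct2 <- roh_ancestry_content(tr2)
  expect_equal(ct2$afr, 1); expect_equal(ct2$eur, 1)
  expect_true(ct2$spanning)

  # gap between informative segments: each side receives half the gap
  tr3 <- ancestry_roh_track(
    rbind(both_haps(3, 1, 0, 4, "AFR"), both_haps(3, 1, 6, 10, "EUR")),
    data.frame(id = 3, chrom = 1, start = 3, end = 7), map)
  ct3 <- roh_ancestry_content(tr3)
  expect_equal(ct3$afr, 2); expect_equal(ct3$eur, 2)

  # haplotypes disagreeing over part of the ROH -> heterozygous flag
  tr4 <- ancestry_roh_track(
    rbind(seg_df(4, 1, 0, 10, "AFR", 1L),
          seg_df(4, 1, 0, 5, "AFR", 2L), seg_df(4, 1, 5, 10, "EUR", 2L)),
    data.frame(id = 4, chrom = 1, start = 4, end = 6), map)
  ct4 <- roh_ancestry_content(tr4)
  expect_true(ct4$heterozygous)
  expect_equal(ct4$het, 1)

  expect_error(ancestry_roh_track(
    both_haps(1, 1, 0, 10, "AFR"),
    data.frame(id = 1, chrom = 1, start = 2, end = 12), map), "bounds")
})

test_that("per-ancestry contents always sum to the ROH length", {
  set.seed(41)
  for (k in 1:15) {
    tr <- generate_roh_fixture(3, association = runif(1),
                               identical_haplotypes = k %% 2 == 0)
    ct <- roh_ancestry_content(tr)
    expect_lt(max(abs(ct$afr + ct$eur + ct$asn + ct$het - ct$length)), 1e-9)
  }
})

test_that("ancestry excess measures long-ROH enrichment over the genome", {
  map <- data.frame(chrom = 1, length = 10)
  # global AFR fraction 0.6; both long ROH fully inside AFR
  tr <- ancestry_roh_track(
    rbind(both_haps(1, 1, 0, 6, "AFR"), both_haps(1, 1, 6, 10, "EUR")),
    data.frame(id = c(1, 1), chrom = 1, start = c(0.5, 3), end = c(2, 4.5)),
    map)
  expect_equal(unname(ancestry_excess(tr)), 0.4)

  # an ROH spanning the whole map reproduces the global fraction exactly
  tr2 <- ancestry_roh_track(
    rbind(both_haps(2, 1, 0, 6, "AFR"), both_haps(2, 1, 6, 10, "EUR")),
    data.frame(id = 2, chrom = 1, start = 0, end = 10), map)
  expect_equal(unname(ancestry_excess(tr2)), 0)

  # individuals without qualifying long ROH are dropped with a warning
  tr3 <- ancestry_roh_track(
    rbind(both_haps(1, 1, 0, 10, "AFR"), both_haps(2, 1, 0, 10, "AFR")),
    data.frame(id = c(1, 2), chrom = 1, start = c(0, 0), end = c(3, 0.1)),
    map)
  expect_warning(ex <- ancestry_excess(tr3), "dropped")
  expect_identical(names(ex), "1")
})

test_that("permuted placements preserve the length multiset", {
  set.seed(42)
  map <- data.frame(chrom = c(1, 2), length = c(60, 40))
  lengths <- c(5, 3, 2, 1.5)
  pl <- admixabc:::permute_roh_once(lengths, c(1, 1, 2, 2), map,
                                    within_chromosome = FALSE,
                                    max_tries = 500)
  expect_equal(sort(pl$end - pl$start), sort(lengths))
  for (cc in unique(pl$chrom)) {
    on_c <- which(pl$chrom == cc)
    if (length(on_c) > 1) {
      iv <- cbind(pl$start[on_c], pl$end[on_c])
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      expect_true(all(iv[-1, 1] >= iv[-nrow(iv), 2]))
    }
  }
  pl_w <- admixabc:::permute_roh_once(lengths, c(1, 1, 2, 2), map,
                                      within_chromosome = TRUE,
                                      max_tries = 500)
  expect_equal(pl_w$chrom, c(1, 1, 2, 2))
})

test_that("the permutation test finds forced ancestry enrichment", {
  set.seed(43)
  alt <- generate_roh_fixture(15, association = 1, afr_fraction = 0.5)
  pt <- roh_permutation_test(alt, n_perm = 1000)
  expect_lte(pt$p_value, 0.01)
  expect_gt(pt$observed, 0.2)
  expect_length(pt$null, 1000)

  # a single whole-map ROH has identically zero excess and p = 1
  map <- data.frame(chrom = 1, length = 10)
  tr <- ancestry_roh_track(
    rbind(both_haps(1, 1, 0, 4, "AFR"), both_haps(1, 1, 4, 10, "EUR")),
    data.frame(id = 1, chrom = 1, start = 0, end = 10), map)
  pt2 <- roh_permutation_test(tr, n_perm = 200)
  expect_equal(pt2$observed, 0)
  expect_equal(pt2$p_value, 1)

  expect_error(roh_permutation_test(alt, n_perm = 50), "100")
})

test_that("null fixtures give unremarkable p-values", {
  set.seed(44)
  null_tr <- generate_roh_fixture(15, association = 0, afr_fraction = 0.5)
  pt <- roh_permutation_test(null_tr, n_perm = 300)
  expect_gt(pt$p_value, 0.001)
  # the observed statistic sits inside the null spread
  expect_lt(abs(pt$observed), max(abs(pt$null)) + 1e-12)
})

test_that("within-chromosome permutation mode runs and calibrates", {
  set.seed(45)
  tr <- generate_roh_fixture(8, association = 0)
  pt <- roh_permutation_test(tr, n_perm = 200, within_chromosome = TRUE)
  expect_true(pt$p_value > 0 && pt$p_value <= 1)
})
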