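#' Pairwise allele-sharing dissimilarity matrix
#'
#' For each pair of individuals, ASD is the mean over sites non-missing in
#' both of `1 - IBS/2`, where IBS in 0/1/2 is the number of shared alleles;
#' equivalently `|g_i - g_j| / 2` averaged over shared sites.
#'
#' @param genotypes Integer matrix, individuals x SNPs, values 0/1/2 (NA for
#'   missing).
#' @return Symmetric numeric matrix in \[0, 1\] with zero diagonal.
#' @export
asd_matrix <- function(genotypes) {
  if (nrow(genotypes) < 2) stop("need at least 2 individuals", call. = FALSE)
  g <- t(genotypes)
  storage.mode(g) <- "integer"
  g[is.na(g)] <- -9L
  out <- asd_pairwise_cpp(g, -9L)
  dimnames(out) <- list(rownames(genotypes), rownames(genotypes))
  out
}

#' Metric (Torgerson) multidimensional scaling of a dissimilarity matrix
#'
#' Double-centers the squared dissimilarities and extracts the top-k
#' eigenpairs; coordinates are eigenvectors scaled by the square root of
#' their eigenvalues (the classical MDS of `stats::cmdscale`).
#'
#' @param asd Symmetric dissimilarity matrix.
#' @param k Number of axes (default 2).
#' @param labels Optional per-row population labels, kept with the result.
#' @return Object of class `mds_embedding`: `points` (n x k), `eig`
#'   (all eigenvalues, decreasing), `labels`.
#' @export
classical_mds <- function(asd, k = 2L, labels = NULL) {
  n <- nrow(asd)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k + 1) stop("need at least k + 1 points", call. = FALSE)
  fit <- suppressWarnings(cmdscale(asd, k = k, eig = TRUE))
  n_pos <- sum(fit$eig > max(fit$eig) * 1e-12)
  if (n_pos < 1) {
    stop("no positive eigenvalue in the MDS decomposition", call. = FALSE)
  }
  pts <- fit$points
  if (ncol(pts) < k) {
    # degenerate (low-rank) configurations: pad the missing axes with zeros
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  }
  structure(list(points = pts, eig = fit$eig, labels = labels),
            class = "mds_embedding")
}

#' MDS admixture fractions and source-source angles
#'
#' Projects each admixed individual orthogonally onto the line joining the
#' centroids of the two source-population samples in MDS space. The
#' admixture fraction is the signed position of the projection measured from
#' the European centroid and scaled by the centroid distance (1 at the
#' African centroid; unclipped, so overshoot beyond \[0, 1\] is visible).
#' The angle theta is measured at the individual's point between the
#' directions towards the African and the European centroid (pi for a point
#' between the centroids on their line; pi/2 on the circle having the
#' centroid segment as diameter).
#'
#' @param embedding An `mds_embedding` whose `labels` mark rows as
#'   `"AFR"`, `"EUR"` or `"ADM"`.
#' @return Object of class `admixture_projection`: data frame with columns
#'   `alpha` and `theta` (radians; NA where the individual coincides with a
#'   centroid) for the admixed rows, plus the two centroids.
#' @export
project_admixture <- function(embedding) {
  lab <- embedding$labels
  if (is.null(lab)) stop("embedding carries no population labels", call. = FALSE)
  if (sum(lab == "AFR") < 2 || sum(lab == "EUR") < 2) {
    stop("need at least 2 individuals per source population", call. = FALSE)
  }
  X <- embedding$points
  c_afr <- colMeans(X[lab == "AFR", , drop = FALSE])
  c_eur <- colMeans(X[lab == "EUR", , drop = FALSE])
  axis <- c_afr - c_eur
  d2 <- sum(axis^2)
  if (d2 < 1e-300) stop("source centroids coincide", call. = FALSE)
  adm <- X[lab == "ADM", , drop = FALSE]
  alpha <- as.numeric((adm - matrix(c_eur, nrow(adm), ncol(adm), byrow = TRUE)) %*% axis) / d2
  va <- matrix(c_afr, nrow(adm), ncol(adm), byrow = TRUE) - adm
  ve <- matrix(c_eur, nrow(adm), ncol(adm), byrow = TRUE) - adm
  na_ <- sqrt(rowSums(va^2)); ne_ <- sqrt(rowSums(ve^2))
  at_centroid <- na_ < 1e-12 | ne_ < 1e-12
  cosang <- rowSums(va * ve) / (na_ * ne_)
  theta <- acos(pmin(1, pmax(-1, cosang)))
  theta[at_centroid] <- NA_real_
  if (any(at_centroid)) {
    warning(sum(at_centroid),
            " individual(s) coincide with a source centroid; angle undefined, excluded",
            call. = FALSE)
  }
  structure(list(
    projection = data.frame(alpha = alpha, theta = theta,
                            row.names = rownames(adm)),
    centroid_afr = c_afr, centroid_eur = c_eur
  ), class = "admixture_projection")
}

#' Per-SNP heterozygosity summary within a population
#'
#' Unbiased gene diversity per SNP, `2 p (1-p) * 2n / (2n - 1)` with `p` the
#' sample allele frequency over `n` diploid individuals; returns its mean
#' and variance across SNPs.
#'
#' @param genotypes Individuals x SNPs matrix, values 0/1/2.
#' @return Named numeric `c(mean, variance)`.
#' @export
heterozygosity_stats <- function(genotypes) {
  n <- nrow(genotypes)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  p <- colMeans(genotypes) / 2
  het <- 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
  c(mean = mean(het), variance = var(het))
}

#' Per-individual inbreeding coefficient summary
#'
#' Method-of-moments F per individual over the sites polymorphic in the
#' sample: `F_i = (O_hom_i - E_hom) / (L_poly - E_hom)` where `O_hom_i` is
#' the individual's observed homozygous-site count and `E_hom` the expected
#' count under Hardy-Weinberg from sample allele frequencies with the
#' small-sample correction `2p(1-p) * 2n/(2n-1)` on heterozygosity.
#'
#' @param genotypes Individuals x SNPs matrix, values 0/1/2.
#' @return Named numeric `c(mean, variance)` of F over individuals.
#' @export
inbreeding_stats <- function(genotypes) {
  n <- nrow(genotypes)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  p <- colMeans(genotypes) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic site", call. = FALSE)
  g <- genotypes[, poly, drop = FALSE]
  pp <- p[poly]
  L_poly <- sum(poly)
  exp_het <- 2 * pp * (1 - pp) * (2 * n) / (2 * n - 1)
  E_hom <- L_poly - sum(exp_het)
  if (abs(L_poly - E_hom) < 1e-12) {
    stop("expected homozygosity equals the site count: F undefined", call. = FALSE)
  }
  O_hom <- rowSums(g != 1L)
  f <- (O_hom - E_hom) / (L_poly - E_hom)
  c(mean = mean(f), variance = var(f))
}

#' Weir and Cockerham (1984) Fst between two populations
#'
#' Two-population theta-hat, ratio of the summed among-population variance
#' component to the summed total over SNPs.
#'
#' @param popA,popB Individuals x SNPs genotype matrices (0/1/2).
#' @return Fst estimate (single number).
#' @export
wc_fst <- function(popA, popB) {
  if (nrow(popA) < 2 || nrow(popB) < 2) {
    stop("need at least 2 individuals per population", call. = FALSE)
  }
  n1 <- nrow(popA); n2 <- nrow(popB); r <- 2
  p1 <- colMeans(popA) / 2; p2 <- colMeans(popB) / 2
  h1 <- colMeans(popA == 1L); h2 <- colMeans(popB == 1L)
  keep <- !(p1 == 0 & p2 == 0) & !(p1 == 1 & p2 == 1)
  if (!any(keep)) stop("all sites monomorphic overall: Fst undefined", call. = FALSE)
  p1 <- p1[keep]; p2 <- p2[keep]; h1 <- h1[keep]; h2 <- h2[keep]
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  sum(a) / sum(a + b + cc)
}

#' f3-admixture statistic f3(H; src1, src2)
#'
#' Mean over SNPs of `(p_H - p_1)(p_H - p_2)` minus the finite-sample
#' heterozygosity correction `p_H (1 - p_H) / (2 n_H - 1)` for the target
#' sample H. A significantly negative value indicates that H is admixed
#' between populations related to the two sources.
#'
#' @param H,src1,src2 Individuals x SNPs genotype matrices (0/1/2).
#' @return f3 estimate (single number).
#' @export
f3_statistic <- function(H, src1, src2) {
  if (nrow(H) < 2) stop("need at least 2 individuals in H", call. = FALSE)
  nH <- nrow(H)
  pH <- colMeans(H) / 2
  p1 <- colMeans(src1) / 2
  p2 <- colMeans(src2) / 2
  keep <- !((pH == 0 & p1 == 0 & p2 == 0) | (pH == 1 & p1 == 1 & p2 == 1))
  if (!any(keep)) stop("no polymorphic site", call. = FALSE)
  mean(((pH - p1) * (pH - p2) - pH * (1 - pH) / (2 * nH - 1))[keep])
}

#' Distributional summary: 7 shape statistics plus 9 deciles
#'
#' Mode (Gaussian kernel density with Silverman bandwidth, maximised over a
#' 512-point grid spanning the sample range), mean, variance, Fisher moment
#' skewness, Pearson (non-excess) kurtosis, min, max, and the 10% ... 90%
#' empirical quantiles (type-7 linear interpolation). Zero-variance samples
#' return 0 for skewness and kurtosis.
#'
#' @param values Numeric vector (>= 10 values for the deciles).
#' @return Named numeric vector of length 16.
#' @export
distribution_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (length(values) < 10) stop("need at least 10 values for deciles", call. = FALSE)
  m <- mean(values)
  v <- var(values)
  m2 <- mean((values - m)^2)
  if (m2 > 0) {
    skew <- mean((values - m)^3) / m2^1.5
    kurt <- mean((values - m)^4) / m2^2
  } else {
    skew <- 0; kurt <- 0
  }
  if (max(values) > min(values)) {
    dd <- density(values, bw = "nrd0", n = 512,
                  from = min(values), to = max(values))
    mode_ <- dd$x[which.max(dd$y)]
  } else {
    mode_ <- values[1]
  }
  dec <- quantile(values, probs = seq(0.1, 0.9, by = 0.1), type = 7,
                  names = FALSE)
  c(mode = mode_, mean = m, variance = v, skewness = skew, kurtosis = kurt,
    min = min(values), max = max(values),
    stats::setNames(dec, paste0("d", seq(10, 90, by = 10))))
}

#' Names of the 42 summary statistics, in their fixed order
#'
#' Grouping: 5 within-population statistics of the admixed sample H, 16
#' statistics of the MDS admixture-fraction distribution, 16 of the MDS
#' source-source angle distribution, 5 between-population statistics.
#'
#' @return Character vector of length 42.
#' @export
summary_stat_names <- function() {
  block <- c("mode", "mean", "var", "skew", "kurt", "min", "max",
             paste0("d", seq(10, 90, by = 10)))
  c("asd_mean_H", "het_mean_H", "het_var_H", "F_mean_H", "F_var_H",
    paste0("alpha_", block), paste0("theta_", block),
    "fst_afr_H", "fst_eur_H", "asd_afr_H", "asd_eur_H", "f3_H_eur_afr")
}

#' Compute the 42 summary statistics of a sample set
#'
#' ASD is computed on the pooled admixed + African + European samples; the
#' MDS projection, admixture fractions and angles are derived from the
#' pooled embedding; heterozygosity, inbreeding, Fst and f3 use the
#' individual sample matrices.
#'
#' @param samples A `sample_set` (see [draw_sample_set()]), or any list with
#'   matrices `admixed`, `afr`, `eur`.
#' @param k Number of MDS axes for the projection (default 2).
#' @return Named numeric vector of length 42 in [summary_stat_names()]
#'   order.
#' @export
compute_summary_vector <- function(samples, k = 2L) {
  H <- samples$admixed; A <- samples$afr; E <- samples$eur
  nH <- nrow(H); nA <- nrow(A); nE <- nrow(E)
  pooled <- rbind(H, A, E)
  lab <- c(rep("ADM", nH), rep("AFR", nA), rep("EUR", nE))
  asd <- if (!is.null(samples$hap1)) {
    asd_packed_cpp(samples$hap1, samples$hap2, samples$L)
  } else {
    asd_matrix(pooled)
  }
  iH <- seq_len(nH); iA <- nH + seq_len(nA); iE <- nH + nA + seq_len(nE)
  asd_H <- mean(asd[iH, iH][upper.tri(asd[iH, iH])])
  asd_AH <- mean(asd[iA, iH])
  asd_EH <- mean(asd[iE, iH])
  emb <- classical_mds(asd, k = k, labels = lab)
  proj <- project_admixture(emb)
  alpha <- proj$projection$alpha
  theta <- proj$projection$theta[!is.na(proj$projection$theta)]
  het <- heterozygosity_stats(H)
  inb <- inbreeding_stats(H)
  out <- c(asd_H, het[["mean"]], het[["variance"]],
           inb[["mean"]], inb[["variance"]],
           distribution_stats(alpha), distribution_stats(theta),
           wc_fst(A, H), wc_fst(E, H), asd_AH, asd_EH,
           f3_statistic(H, E, A))
  names(out) <- summary_stat_names()
  out
}
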