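# Independent brute-force implementations used as oracles: plain loops,
# no shared code with the package internals.

oracle_asd <- function(geno) {
  n <- nrow(geno)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0; den <- 0
    for (s in seq_len(ncol(geno))) {
      a <- geno[i, s]; b <- geno[j, s]
      if (is.na(a) || is.na(b)) next
      ibs <- 2 - abs(a - b)
      num <- num + (1 - ibs / 2)
      den <- den + 1
    }
    out[i, j] <- num / den
  }
  out
}

oracle_het <- function(geno) {
  n <- nrow(geno)
  hets <- numeric(ncol(geno))
  for (s in seq_len(ncol(geno))) {
    p <- sum(geno[, s]) / (2 * n)
    hets[s] <- 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
  }
  c(mean(hets), var(hets))
}

oracle_inbreeding <- function(geno) {
  n <- nrow(geno)
  p <- colSums(geno) / (2 * n)
  poly <- which(p > 0 & p < 1)
  exp_hom <- 0
  for (s in poly) {
    exp_hom <- exp_hom + 1 - 2 * p[s] * (1 - p[s]) * (2 * n) / (2 * n - 1)
  }
  f <- numeric(n)
  for (i in seq_len(n)) {
    obs_hom <- sum(geno[i, poly] != 1)
    f[i] <- (obs_hom - exp_hom) / (length(poly) - exp_hom)
  }
  c(mean(f), var(f))
}

oracle_wc_fst <- function(gA, gB) {
  n1 <- nrow(gA); n2 <- nrow(gB); r <- 2
  num <- 0; den <- 0
  for (s in seq_len(ncol(gA))) {
    p1 <- sum(gA[, s]) / (2 * n1); p2 <- sum(gB[, s]) / (2 * n2)
    if ((p1 == 0 && p2 == 0) || (p1 == 1 && p2 == 1)) next
    h1 <- sum(gA[, s] == 1) / n1; h2 <- sum(gB[, s] == 1) / n2
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
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

oracle_f3 <- function(H, s1, s2) {
  nH <- nrow(H)
  vals <- c()
  for (s in seq_len(ncol(H))) {
    pH <- sum(H[, s]) / (2 * nH)
    p1 <- sum(s1[, s]) / (2 * nrow(s1))
    p2 <- sum(s2[, s]) / (2 * nrow(s2))
    if ((pH == 0 && p1 == 0 && p2 == 0) || (pH == 1 && p1 == 1 && p2 == 1)) next
    vals <- c(vals, (pH - p1) * (pH - p2) - pH * (1 - pH) / (2 * nH - 1))
  }
  mean(vals)
}

random_genotypes <- function(n, L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(0:2, n * L, replace = TRUE), nrow = n,
         dimnames = list(paste0("i", seq_len(n)), paste0("snp", seq_len(L))))
}
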