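#' Build a fixed gamete reservoir matching a frequency spectrum
#'
#' A reservoir is a pool of `R` haploid genomes at `L` independent biallelic
#' sites whose alleles are drawn i.i.d. Bernoulli from the supplied per-site
#' allele frequencies. It stands in for a large source population at
#' drift-mutation equilibrium: it is built once and stays fixed for the
#' whole admixture process, while diploid source parents are assembled from
#' it anew each generation. Haplotypes are stored bit-packed (32 sites per
#' machine word); use [reservoir_haplotypes()] for a plain 0/1 view.
#'
#' @param frequencies Numeric vector of per-site allele frequencies,
#'   strictly inside (0, 1); values exactly 0 or 1 are accepted with a
#'   warning (monomorphic site).
#' @param R Reservoir size (haploid genomes). The full-scale configuration
#'   uses 20000; the desk-scale profile uses 2000.
#' @param label Source label, `"African"` or `"European"`.
#' @return An object of class `gamete_reservoir` with fields `label`,
#'   `haplotypes` (packed `W x R` matrix), `frequencies`, `L`, `R`.
#' @export
build_reservoir <- function(frequencies, R = 20000L, label = "African") {
  if (length(frequencies) < 1) stop("need at least one site", call. = FALSE)
  if (anyNA(frequencies) || any(frequencies < 0 | frequencies > 1)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (any(frequencies == 0 | frequencies == 1)) {
    warning("monomorphic site(s): frequency exactly 0 or 1", call. = FALSE)
  }
  L <- length(frequencies)
  haps <- matrix(rbinom(L * R, 1L, frequencies), nrow = L, ncol = R)
  structure(list(label = label, haplotypes = pack_columns_cpp(haps),
                 frequencies = frequencies, L = L, R = as.integer(R)),
            class = "gamete_reservoir")
}

#' Unpacked 0/1 view of reservoir haplotypes
#'
#' @param reservoir A `gamete_reservoir`.
#' @param idx Gamete indices (default all).
#' @return Integer matrix, sites x gametes, values 0/1.
#' @export
reservoir_haplotypes <- function(reservoir, idx = seq_len(reservoir$R)) {
  unpack_columns_cpp(reservoir$haplotypes, as.integer(idx), reservoir$L)
}

new_population <- function(g, kernel_out, L, track) {
  structure(list(
    g = g, L = L,
    hapA = kernel_out$hapA, hapB = kernel_out$hapB,
    ids = kernel_out$ids,
    parents = kernel_out$parents,
    grandparents = kernel_out$grandparents,
    ancA = if (track) kernel_out$ancA else NULL,
    ancB = if (track) kernel_out$ancB else NULL,
    id_next = kernel_out$id_next,
    N = ncol(kernel_out$hapA)
  ), class = "admixed_population")
}

#' Advance the admixed population by one generation
#'
#' Builds the parental pool of `2 * n_offspring` parents in the proportions
#' of the contribution-schedule row (African source, European source,
#' previous admixed generation; largest-remainder apportionment with ties to
#' the admixed class), then produces `n_offspring` diploid offspring, each
#' from a Mendelian gamete of two distinct parents (no selfing; parents are
#' returned to the pool after each draw). Source parents pair two different
#' reservoir gametes and are rebuilt anew every generation.
#'
#' @param pop Previous `admixed_population`, or NULL at founding.
#' @param row Numeric `c(s_afr, s_eur, h)` contribution proportions.
#' @param reservoirs List with `afr` and `eur` gamete reservoirs.
#' @param n_offspring Number of diploid offspring to produce.
#' @param track Carry per-allele ancestry labels (instrumented mode).
#' @return The next-generation `admixed_population`.
#' @export
advance_generation <- function(pop, row, reservoirs, n_offspring,
                               track = FALSE) {
  stopifnot(length(row) == 3, all(row >= 0), abs(sum(row) - 1) < 1e-9)
  if (row[3] > 0 && (is.null(pop) || pop$N < 1)) {
    stop("h_g > 0 but there is no previous admixed generation", call. = FALSE)
  }
  counts <- apportion_counts(2L * n_offspring, row, tie_to = 3L)
  g <- if (is.null(pop)) 0L else pop$g + 1L
  out <- wf_generation_cpp(
    reservoirs$afr$haplotypes, reservoirs$eur$haplotypes,
    reservoirs$afr$L,
    if (is.null(pop)) NULL else pop$hapA,
    if (is.null(pop)) NULL else pop$hapB,
    if (is.null(pop)) NULL else pop$ids,
    if (is.null(pop)) NULL else pop$parents,
    counts[1], counts[2], counts[3],
    n_offspring,
    if (is.null(pop)) 1L else pop$id_next,
    track,
    if (is.null(pop) || !track) NULL else pop$ancA,
    if (is.null(pop) || !track) NULL else pop$ancB)
  new_population(g, out, reservoirs$afr$L, track)
}

#' Run the 21-generation forward admixture simulation
#'
#' Founds the admixed population at generation 0 from the two gamete
#' reservoirs in proportions `s_Afr_0` / `1 - s_Afr_0`, then applies
#' [advance_generation()] for generations 1 ... 20 following the
#' contribution schedule and the demographic trajectory implied by the
#' parameter vector. Genealogical ids of the last two generations (parents
#' and grandparents) are retained for unrelated sampling.
#'
#' @param params An `admix_params` vector (see [draw_parameters()]).
#' @param reservoirs List with `afr` and `eur` gamete reservoirs.
#' @param track Instrumented mode: carry per-allele source labels
#'   (African/European origin). Off by default; the summary statistics
#'   never use it.
#' @return The generation-20 `admixed_population`.
#' @export
run_simulation <- function(params, reservoirs, track = FALSE) {
  if (reservoirs$afr$L != reservoirs$eur$L) {
    stop("reservoirs must cover the same sites", call. = FALSE)
  }
  sched <- build_schedule(params)
  N <- population_size_at(params$demography, 0:20)
  pop <- advance_generation(NULL, sched[1, ], reservoirs, N[1], track)
  for (g in 1:20) {
    pop <- advance_generation(pop, sched[g + 1, ], reservoirs, N[g + 1], track)
  }
  pop
}

#' Diploid genotypes of selected individuals
#'
#' @param pop An `admixed_population`.
#' @param idx Individual indices (default all).
#' @return Integer matrix, individuals x SNPs, values 0/1/2.
#' @export
genotypes_of <- function(pop, idx = seq_len(pop$N)) {
  idx <- as.integer(idx)
  g <- t(unpack_columns_cpp(pop$hapA, idx, pop$L) +
           unpack_columns_cpp(pop$hapB, idx, pop$L))
  rownames(g) <- paste0("H", idx)
  colnames(g) <- paste0("snp", seq_len(pop$L))
  g
}

#' True per-individual African ancestry fraction (instrumented runs only)
#'
#' @param pop An `admixed_population` simulated with `track = TRUE`.
#' @param idx Individual indices (default all).
#' @return Numeric vector: fraction of alleles of African origin.
#' @export
true_ancestry_fraction <- function(pop, idx = seq_len(pop$N)) {
  if (is.null(pop$ancA)) {
    stop("population was not simulated with track = TRUE", call. = FALSE)
  }
  idx <- as.integer(idx)
  (popcount_columns_cpp(pop$ancA[, idx, drop = FALSE]) +
     popcount_columns_cpp(pop$ancB[, idx, drop = FALSE])) / (2 * pop$L)
}

#' Sample individuals with no grandparent in common
#'
#' Greedy search over random orderings of the final generation, accepting an
#' individual only if none of its four grandparent ids occurs among the
#' grandparents of already-accepted individuals; mimics a family-unrelated
#' observed dataset.
#'
#' @param pop An `admixed_population`.
#' @param n Sample size.
#' @param max_restarts Number of random orderings to try.
#' @return Integer vector of `n` individual indices.
#' @export
sample_unrelated <- function(pop, n, max_restarts = 100L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (n > pop$N) {
    stop(insufficient_unrelated_error(n, pop$N))
  }
  gp <- pop$grandparents
  for (r in seq_len(max_restarts)) {
    ord <- sample.int(pop$N)
    chosen <- integer(0)
    seen <- integer(0)
    for (i in ord) {
      g4 <- gp[i, ]
      if (!any(g4 %in% seen)) {
        chosen <- c(chosen, i)
        seen <- c(seen, g4)
        if (length(chosen) == n) return(chosen)
      }
    }
  }
  stop(insufficient_unrelated_error(n, pop$N))
}

insufficient_unrelated_error <- function(n, N) {
  structure(
    class = c("admixabc_insufficient_unrelated", "error", "condition"),
    list(message = sprintf(
      "could not find %d individuals without shared grandparents in a population of %d",
      n, N), call = NULL))
}

sample_source_packed <- function(reservoir, n) {
  idx <- sample.int(reservoir$R, 2L * n)
  i1 <- as.integer(idx[seq_len(n)]); i2 <- as.integer(idx[n + seq_len(n)])
  g <- t(unpack_columns_cpp(reservoir$haplotypes, i1, reservoir$L) +
           unpack_columns_cpp(reservoir$haplotypes, i2, reservoir$L))
  rownames(g) <- paste0(toupper(substr(reservoir$label, 1, 3)), seq_len(n))
  colnames(g) <- paste0("snp", seq_len(reservoir$L))
  list(geno = g,
       hap1 = reservoir$haplotypes[, i1, drop = FALSE],
       hap2 = reservoir$haplotypes[, i2, drop = FALSE])
}

#' Sample diploid individuals from a gamete reservoir
#'
#' Forms `n` diploid genotypes from `2n` distinct reservoir gametes,
#' mirroring the sampling of source-population reference panels.
#'
#' @param reservoir A `gamete_reservoir`.
#' @param n Number of individuals (default 60).
#' @return Integer matrix `n x L`, values 0/1/2.
#' @export
sample_source <- function(reservoir, n = 60L) {
  if (2L * n > reservoir$R) {
    stop("reservoir too small: need 2n distinct gametes", call. = FALSE)
  }
  if (n == 0L) {
    return(matrix(integer(0), nrow = 0, ncol = reservoir$L,
                  dimnames = list(NULL, paste0("snp", seq_len(reservoir$L)))))
  }
  sample_source_packed(reservoir, n)$geno
}

#' Draw a full sample set from a simulated population
#'
#' Bundles an unrelated admixed sample with reference samples from each
#' source reservoir; this is the unit on which the 42 summary statistics are
#' computed. The packed haplotypes of all sampled individuals are kept
#' alongside the genotype matrices so that the pooled ASD matrix can be
#' computed by bit-level popcounts.
#'
#' @param pop A generation-20 `admixed_population`.
#' @param reservoirs List with `afr` and `eur` gamete reservoirs.
#' @param n_admixed Admixed sample size.
#' @param n_source Per-source sample size (default 60).
#' @return An object of class `sample_set`: matrices `admixed`, `afr`,
#'   `eur`, packed haplotypes `hap1`/`hap2` of the pooled sample (admixed
#'   first, then African, then European), the admixed indices, and
#'   (instrumented runs) the true African ancestry fractions of the sampled
#'   individuals.
#' @export
draw_sample_set <- function(pop, reservoirs, n_admixed, n_source = 60L) {
  if (2L * n_source > reservoirs$afr$R || 2L * n_source > reservoirs$eur$R) {
    stop("reservoir too small: need 2n distinct gametes", call. = FALSE)
  }
  idx <- sample_unrelated(pop, n_admixed)
  truth <- if (!is.null(pop$ancA)) true_ancestry_fraction(pop, idx) else NULL
  afr <- sample_source_packed(reservoirs$afr, n_source)
  eur <- sample_source_packed(reservoirs$eur, n_source)
  structure(list(
    admixed = genotypes_of(pop, idx),
    afr = afr$geno,
    eur = eur$geno,
    hap1 = cbind(pop$hapA[, idx, drop = FALSE], afr$hap1, eur$hap1),
    hap2 = cbind(pop$hapB[, idx, drop = FALSE], afr$hap2, eur$hap2),
    L = pop$L,
    admixed_idx = idx,
    true_afr_fraction = truth
  ), class = "sample_set")
}
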