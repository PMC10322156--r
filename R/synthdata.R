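#' Generate allele-frequency spectra for a diverged source pair
#'
#' Balding-Nichols construction: per site, an ancestral frequency is drawn
#' from `Beta(anc_shape1, anc_shape2)` truncated to the minor-allele-
#' frequency floor, and each source population's frequency is drawn from
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)` with `F = divergence`, independently for
#' the two populations; under this model the expected pairwise
#' Weir-Cockerham Fst between the two sources is close to `divergence`.
#' Output frequencies are clipped to `[maf, 1 - maf]` (no singletons or
#' fixed sites, mirroring frequency panels drawn from genotype data while
#' avoiding singletons).
#'
#' @param L Number of SNPs.
#' @param divergence Fst-like divergence parameter in (0, 1); values very
#'   close to 0 give identical spectra.
#' @param maf Minor-allele-frequency floor (> 0).
#' @param anc_shape1,anc_shape2 Beta parameters of the ancestral-frequency
#'   law (default uniform).
#' @return List with numeric vectors `afr` and `eur` of length `L`, and the
#'   `ancestral` frequencies.
#' @export
generate_source_frequencies <- function(L, divergence = 0.15, maf = 0.01,
                                        anc_shape1 = 1, anc_shape2 = 1) {
  stopifnot(L >= 1, divergence > 0, divergence < 1, maf > 0, maf < 0.5)
  p <- rbeta(L, anc_shape1, anc_shape2)
  p <- pmin(pmax(p, maf), 1 - maf)
  draw_pop <- function() {
    if (divergence < 1e-8) return(p)
    a <- p * (1 - divergence) / divergence
    b <- (1 - p) * (1 - divergence) / divergence
    q <- rbeta(L, a, b)
    pmin(pmax(q, maf), 1 - maf)
  }
  list(afr = draw_pop(), eur = draw_pop(), ancestral = p)
}

#' Build both gamete reservoirs from a source frequency pair
#'
#' @param freqs List with `afr` and `eur` frequency vectors (as produced by
#'   [generate_source_frequencies()] or read from TSV tables).
#' @param R Reservoir size (haploid genomes per source).
#' @return List with `afr` and `eur` gamete reservoirs.
#' @export
build_reservoir_pair <- function(freqs, R = 2000L) {
  list(afr = build_reservoir(freqs$afr, R = R, label = "African"),
       eur = build_reservoir(freqs$eur, R = R, label = "European"))
}

#' Generate a pseudo-observed dataset with known ground truth
#'
#' Runs the full forward simulation under a given parameter vector, draws an
#' unrelated admixed sample and the two source samples, and retains the
#' generating parameters (and, in instrumented mode, the true ancestry
#' fractions). Bit-identical under the same seed.
#'
#' @param params An `admix_params` vector.
#' @param reservoirs List with `afr` and `eur` gamete reservoirs.
#' @param n_admixed Admixed sample size.
#' @param seed Integer seed; the draw is regenerable from it.
#' @param track Instrumented ancestry tracking.
#' @param n_source Per-source sample size.
#' @return A `pseudo_observed` object: the `sample_set`, `params`, `seed`.
#' @export
generate_pseudo_observed <- function(params, reservoirs, n_admixed, seed,
                                     track = FALSE, n_source = 60L) {
  set.seed(seed)
  pop <- run_simulation(params, reservoirs, track = track)
  samples <- draw_sample_set(pop, reservoirs, n_admixed, n_source = n_source)
  structure(list(samples = samples, params = params, seed = seed),
            class = "pseudo_observed")
}

#' Generate an ancestry/ROH fixture set
#'
#' Builds, for `n` individuals, two per-haplotype local-ancestry tracks
#' partitioned into AFR/EUR segments (segment lengths exponential with mean
#' `segment_mean` cM, labels i.i.d. AFR with probability `afr_fraction`) and
#' a set of ROH intervals in the three length classes. By default the two
#' haplotypes of an individual carry identical tracks, so every ROH has
#' homozygous diploid ancestry; set `identical_haplotypes = FALSE` for
#' independent tracks (which produces heterozygous-ancestry ROH that the
#' excess statistic excludes).
#'
#' Long-ROH placement is governed by `association`: with probability
#' `association` a long ROH is placed uniformly among the homozygous-AFR
#' stretches able to contain it, otherwise (and for all short/medium ROH)
#' uniformly on the map; `association = 0` is the null construction,
#' `association = 1` forces every long ROH fully inside AFR segments.
#'
#' @param n Number of individuals.
#' @param map Data frame with columns `chrom`, `length` (cM). Default: 10
#'   chromosomes of 150 cM.
#' @param afr_fraction Expected global AFR ancestry fraction.
#' @param association Ancestry-ROH association strength in \[0, 1\] (long
#'   ROH only).
#' @param n_roh Named integer vector: ROH counts per individual per class,
#'   default `c(short = 8, medium = 4, long = 3)`.
#' @param segment_mean Mean ancestry-segment length, cM.
#' @param long_mean Mean excess length of long ROH above 1 cM (exponential).
#' @param identical_haplotypes Use one shared diploid ancestry track.
#' @return An `ancestry_roh_track` object (see [ancestry_roh_track()]) with
#'   attribute `truth` recording the generator settings.
#' @export
generate_roh_fixture <- function(n, map = data.frame(chrom = 1:10, length = 150),
                                 afr_fraction = 0.5, association = 0,
                                 n_roh = c(short = 8, medium = 4, long = 3),
                                 segment_mean = 25, long_mean = 1.5,
                                 identical_haplotypes = TRUE) {
  stopifnot(association >= 0, association <= 1)
  seg_list <- vector("list", n)
  roh_list <- vector("list", n)
  for (id in seq_len(n)) {
    segs1 <- do.call(rbind, lapply(seq_len(nrow(map)), function(ci) {
      sim_ancestry_chrom(map$chrom[ci], map$length[ci], afr_fraction, segment_mean)
    }))
    segs2 <- if (identical_haplotypes) segs1 else
      do.call(rbind, lapply(seq_len(nrow(map)), function(ci) {
        sim_ancestry_chrom(map$chrom[ci], map$length[ci], afr_fraction, segment_mean)
      }))
    segs1$haplotype <- 1L; segs2$haplotype <- 2L
    segs <- rbind(segs1, segs2)
    segs$id <- id
    lengths <- c(runif(n_roh[["short"]], 0.05, 0.249),
                 runif(n_roh[["medium"]], 0.25, 0.999),
                 1 + stats::rexp(n_roh[["long"]], rate = 1 / long_mean))
    classes <- rep(c("short", "medium", "long"),
                   times = c(n_roh[["short"]], n_roh[["medium"]], n_roh[["long"]]))
    if (sum(lengths) > sum(map$length)) {
      stop("requested total ROH length exceeds the map length", call. = FALSE)
    }
    afr_iv <- diploid_label_intervals(segs, "AFR")
    roh <- place_roh_set(lengths, classes, map, afr_iv, association)
    roh$id <- id
    seg_list[[id]] <- segs
    roh_list[[id]] <- roh
  }
  track <- ancestry_roh_track(do.call(rbind, seg_list),
                              do.call(rbind, roh_list), map)
  attr(track, "truth") <- list(afr_fraction = afr_fraction,
                               association = association, n_roh = n_roh)
  track
}

sim_ancestry_chrom <- function(chrom, len, afr_fraction, segment_mean) {
  pos <- 0
  starts <- c(); ends <- c(); labs <- c()
  while (pos < len) {
    l <- stats::rexp(1, rate = 1 / segment_mean)
    end <- min(pos + l, len)
    starts <- c(starts, pos); ends <- c(ends, end)
    labs <- c(labs, if (runif(1) < afr_fraction) "AFR" else "EUR")
    pos <- end
  }
  data.frame(chrom = chrom, start = starts, end = ends, ancestry = labs,
             stringsAsFactors = FALSE)
}

## homozygous-diploid intervals of a given label (both haplotypes agree)
diploid_label_intervals <- function(segs, label) {
  out <- lapply(unique(segs$chrom), function(cc) {
    s1 <- segs[segs$chrom == cc & segs$haplotype == 1L, , drop = FALSE]
    s2 <- segs[segs$chrom == cc & segs$haplotype == 2L, , drop = FALSE]
    bp <- sort(unique(c(s1$start, s1$end, s2$start, s2$end)))
    if (length(bp) < 2) return(NULL)
    lo <- bp[-length(bp)]; hi <- bp[-1]
    mid <- (lo + hi) / 2
    lab1 <- s1$ancestry[findInterval(mid, s1$start)]
    lab2 <- s2$ancestry[findInterval(mid, s2$start)]
    keep <- !is.na(lab1) & !is.na(lab2) & lab1 == label & lab2 == label
    if (!any(keep)) return(NULL)
    df <- data.frame(chrom = cc, start = lo[keep], end = hi[keep])
    # merge touching runs
    run <- cumsum(c(TRUE, df$start[-1] > df$end[-nrow(df)] + 1e-12))
    data.frame(chrom = cc,
               start = tapply(df$start, run, min),
               end = tapply(df$end, run, max), row.names = NULL)
  })
  do.call(rbind, out)
}

place_roh_set <- function(lengths, classes, map, afr_iv, association,
                          max_tries = 2000L) {
  ord <- order(lengths, decreasing = TRUE)
  placed <- data.frame(chrom = numeric(0), start = numeric(0), end = numeric(0))
  for (j in ord) {
    l <- lengths[j]
    in_afr <- classes[j] == "long" && runif(1) < association
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      if (in_afr) {
        fit <- afr_iv[!is.na(afr_iv$end) & afr_iv$end - afr_iv$start >= l, , drop = FALSE]
        if (is.null(fit) || nrow(fit) == 0) {
          stop("cannot place a long ROH inside AFR ancestry: no stretch long enough",
               call. = FALSE)
        }
        w <- (fit$end - fit$start - l)
        k <- sample.int(nrow(fit), 1, prob = w + 1e-9)
        a <- runif(1, fit$start[k], fit$end[k] - l)
        cc <- fit$chrom[k]
      } else {
        fits <- map$length >= l
        if (!any(fits)) stop("ROH longer than every chromosome", call. = FALSE)
        k <- sample(which(fits), 1, prob = map$length[fits] - l + 1e-9)
        cc <- map$chrom[k]
        a <- runif(1, 0, map$length[k] - l)
      }
      b <- a + l
      same <- placed[placed$chrom == cc, , drop = FALSE]
      if (nrow(same) == 0 || all(b <= same$start | a >= same$end)) {
        placed <- rbind(placed, data.frame(chrom = cc, start = a, end = b))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place ROH without overlap", call. = FALSE)
  }
  placed
}
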