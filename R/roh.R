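#' Bundle local-ancestry segments and ROH intervals for a set of individuals
#'
#' Coordinates are centimorgans, 0-based half-open intervals. Ancestry
#' segments carry one row per (individual, haplotype, chromosome, segment)
#' with labels from the collapsed three-way continental scheme (AFR, EUR,
#' ASN); ROH intervals carry one row per (individual, chromosome, interval).
#'
#' @param segments Data frame: `id`, `haplotype` (1/2), `chrom`, `start`,
#'   `end`, `ancestry`.
#' @param roh Data frame: `id`, `chrom`, `start`, `end`.
#' @param map Data frame: `chrom`, `length` (cM).
#' @return An object of class `ancestry_roh_track`.
#' @export
ancestry_roh_track <- function(segments, roh, map) {
  stopifnot(all(c("id", "haplotype", "chrom", "start", "end", "ancestry")
                %in% names(segments)),
            all(c("id", "chrom", "start", "end") %in% names(roh)),
            all(c("chrom", "length") %in% names(map)))
  if (any(segments$start >= segments$end)) {
    stop("ancestry segments must satisfy start < end", call. = FALSE)
  }
  if (!all(segments$ancestry %in% c("AFR", "EUR", "ASN"))) {
    stop("ancestry labels must be AFR, EUR or ASN", call. = FALSE)
  }
  maxlen <- map$length[match(roh$chrom, map$chrom)]
  if (anyNA(maxlen) || any(roh$start < 0 | roh$end > maxlen + 1e-9)) {
    stop("ROH outside the map bounds", call. = FALSE)
  }
  structure(list(segments = segments, roh = roh, map = map),
            class = "ancestry_roh_track")
}

#' Generations to the most recent common ancestor implied by an ROH length
#'
#' `g = 100 / (2 l)` with `l` the ROH length in centimorgans: a 1-cM ROH
#' coalesces about 50 generations ago, a 0.25-cM ROH about 200.
#'
#' @param l ROH length(s) in cM, > 0.
#' @return Generations to the most recent common ancestor.
#' @export
tmrca_from_length <- function(l) {
  if (any(l <= 0)) stop("ROH length must be positive", call. = FALSE)
  100 / (2 * l)
}

#' ROH length classes
#'
#' Short: l < 0.25 cM; medium: 0.25 <= l < 1 cM; long: l >= 1 cM. The
#' boundary values 0.25 and 1 are assigned to the longer class.
#'
#' @param l ROH length(s) in cM.
#' @return Character vector of classes.
#' @export
roh_size_class <- function(l) {
  ifelse(l >= 1, "long", ifelse(l >= 0.25, "medium", "short"))
}

## Extend the per-haplotype segments of one individual so that consecutive
## segments meet at the midpoint of any uncovered gap (ancestry switches
## between two informative positions get half the gap on each side), and
## cover the chromosome ends.
close_segment_gaps <- function(segments, map) {
  pieces <- split(segments,
                  interaction(segments$id, segments$haplotype, segments$chrom,
                              drop = TRUE))
  out <- lapply(pieces, function(df) {
    df <- df[order(df$start), , drop = FALSE]
    n <- nrow(df)
    if (n > 1) {
      mid <- (df$end[-n] + df$start[-1]) / 2
      df$end[-n] <- pmax(df$end[-n], mid)
      df$start[-1] <- pmin(df$start[-1], mid)
    }
    df$start[1] <- 0
    df$end[n] <- map$length[match(df$chrom[1], map$chrom)]
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Per-individual, per-chromosome diploid elementary intervals with a
## combined label: the ancestry pair where both haplotypes agree, "HET"
## where they differ.
diploid_profile <- function(segments, map) {
  segs <- close_segment_gaps(segments, map)
  out <- list()
  for (id in unique(segs$id)) {
    for (cc in unique(segs$chrom[segs$id == id])) {
      s1 <- segs[segs$id == id & segs$chrom == cc & segs$haplotype == 1L, ]
      s2 <- segs[segs$id == id & segs$chrom == cc & segs$haplotype == 2L, ]
      s1 <- s1[order(s1$start), ]; s2 <- s2[order(s2$start), ]
      bp <- sort(unique(c(s1$start, s1$end, s2$start, s2$end)))
      lo <- bp[-length(bp)]; hi <- bp[-1]
      mid <- (lo + hi) / 2
      l1 <- s1$ancestry[findInterval(mid, s1$start)]
      l2 <- s2$ancestry[findInterval(mid, s2$start)]
      lab <- ifelse(l1 == l2, l1, "HET")
      out[[length(out) + 1]] <- data.frame(
        id = id, chrom = cc, start = lo, end = hi, label = lab,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

overlap_length <- function(iv, a, b) {
  if (is.null(iv) || nrow(iv) == 0) return(0)
  sum(pmax(0, pmin(iv$end, b) - pmax(iv$start, a)))
}

#' Ancestry content of ROH intervals
#'
#' Partitions each ROH's length among AFR, EUR and ASN diploid ancestry
#' (haplotype tracks extended to meet at gap midpoints), flags ROH that
#' overlap any stretch of unequal haplotype labels (heterozygous ancestry;
#' excluded from the excess statistic) and ROH that cross at least one
#' ancestry breakpoint (spanning).
#'
#' @param track An `ancestry_roh_track`.
#' @return Data frame with one row per ROH: `id`, `chrom`, `start`, `end`,
#'   `length`, `class`, `afr`, `eur`, `asn`, `het`, `heterozygous`,
#'   `spanning`.
#' @export
roh_ancestry_content <- function(track) {
  prof <- diploid_profile(track$segments, track$map)
  roh <- track$roh
  n <- nrow(roh)
  res <- data.frame(roh, length = roh$end - roh$start,
                    class = roh_size_class(roh$end - roh$start),
                    afr = 0, eur = 0, asn = 0, het = 0,
                    heterozygous = FALSE, spanning = FALSE)
  for (i in seq_len(n)) {
    p <- prof[prof$id == roh$id[i] & prof$chrom == roh$chrom[i], ]
    a <- roh$start[i]; b <- roh$end[i]
    for (lb in c("AFR", "EUR", "ASN", "HET")) {
      len <- overlap_length(p[p$label == lb, ], a, b)
      res[[tolower(sub("HET", "het", lb))]][i] <- len
    }
    res$heterozygous[i] <- res$het[i] > 1e-12
    inner <- p$start > a + 1e-12 & p$start < b - 1e-12
    if (any(inner)) {
      # a breakpoint counts when the diploid label actually changes there
      ix <- which(inner)
      res$spanning[i] <- any(p$label[ix] != p$label[ix - 1])
    }
  }
  res
}

#' Per-individual ancestry excess in long ROH
#'
#' For each individual: the proportion of a given ancestry within their long
#' ROH (heterozygous-ancestry ROH excluded, ASN content excluded from
#' numerator and denominator) minus their global diploid proportion of that
#' ancestry over the map. Positive values mean the ancestry is
#' over-represented in long ROH relative to the genome-wide level.
#' Individuals with no qualifying long ROH are dropped with a warning.
#'
#' @param track An `ancestry_roh_track`.
#' @param ancestry `"AFR"` (default) or `"EUR"`.
#' @return Named numeric vector of per-individual excesses.
#' @export
ancestry_excess <- function(track, ancestry = "AFR") {
  content <- roh_ancestry_content(track)
  excess_from_content(content, track, ancestry)
}

excess_from_content <- function(content, track, ancestry = "AFR") {
  prof <- diploid_profile(track$segments, track$map)
  ids <- sort(unique(track$roh$id))
  out <- numeric(0)
  dropped <- 0
  col <- tolower(ancestry)
  for (id in ids) {
    rr <- content[content$id == id & content$class == "long" &
                    !content$heterozygous, , drop = FALSE]
    denom <- sum(rr$afr + rr$eur)
    if (nrow(rr) == 0 || denom <= 0) { dropped <- dropped + 1; next }
    p <- prof[prof$id == id, ]
    glob_num <- sum((p$end - p$start)[p$label == ancestry])
    glob_den <- sum((p$end - p$start)[p$label %in% c("AFR", "EUR")])
    out[as.character(id)] <- sum(rr[[col]]) / denom - glob_num / glob_den
  }
  if (dropped > 0) {
    warning(dropped, " individual(s) without qualifying long ROH dropped",
            call. = FALSE)
  }
  out
}

#' Permutation test for ancestry excess in long ROH
#'
#' The observed statistic is the mean over individuals of
#' [ancestry_excess()]. For each permutation replicate, every individual's
#' long ROH are re-placed uniformly at random on that individual's own map
#' (lengths preserved, non-overlap enforced by rejection; by default ROH
#' may move across chromosomes), the local ancestry proportion within the
#' permuted ROH is recomputed and the global proportion subtracted, and the
#' per-individual differences are averaged. The two-sided p-value is
#' `(1 + #(|null| >= |observed|)) / (n_perm + 1)`.
#'
#' @param track An `ancestry_roh_track`.
#' @param ancestry `"AFR"` (default) or `"EUR"`.
#' @param n_perm Number of permutations (>= 100; default 10000).
#' @param within_chromosome Keep each ROH on its original chromosome.
#' @param max_tries Placement rejection budget per ROH.
#' @return List: `observed`, `p_value`, `null` (numeric vector of length
#'   `n_perm`), `excess` (per-individual observed excesses).
#' @export
roh_permutation_test <- function(track, ancestry = "AFR", n_perm = 10000L,
                                 within_chromosome = FALSE,
                                 max_tries = 1000L) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  content <- roh_ancestry_content(track)
  obs_excess <- excess_from_content(content, track, ancestry)
  if (length(obs_excess) == 0) stop("no individual with long ROH", call. = FALSE)
  observed <- mean(obs_excess)
  prof <- diploid_profile(track$segments, track$map)
  map <- track$map

  ids <- as.integer(names(obs_excess))
  other <- setdiff(c("AFR", "EUR"), ancestry)
  props <- matrix(NA_real_, n_perm, length(ids))
  globals <- numeric(length(ids))
  for (j in seq_along(ids)) {
    id <- ids[j]
    rr <- content[content$id == id & content$class == "long" &
                    !content$heterozygous, , drop = FALSE]
    p <- prof[prof$id == id, ]
    globals[j] <- sum((p$end - p$start)[p$label == ancestry]) /
      sum((p$end - p$start)[p$label %in% c("AFR", "EUR")])
    ord <- order(rr$length, decreasing = TRUE)
    iv_by_chrom <- function(lab) {
      lapply(map$chrom, function(cc) {
        sub <- p[p$label == lab & p$chrom == cc, c("start", "end"),
                 drop = FALSE]
        as.matrix(sub)
      })
    }
    props[, j] <- roh_perm_props_cpp(
      rr$length[ord], map$length,
      iv_by_chrom(ancestry), iv_by_chrom(other),
      as.integer(n_perm), within_chromosome,
      match(rr$chrom[ord], map$chrom), as.integer(max_tries))
  }
  null <- rowMeans(sweep(props, 2, globals), na.rm = TRUE)
  p <- (1 + sum(abs(null) >= abs(observed) - 1e-15)) / (n_perm + 1)
  list(observed = observed, p_value = p, null = null, excess = obs_excess)
}

permute_roh_once <- function(lengths, orig_chrom, map, within_chromosome,
                             max_tries) {
  k <- length(lengths)
  chrom <- numeric(k); start <- numeric(k); end <- numeric(k)
  for (j in seq_len(k)) {
    l <- lengths[j]
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      if (within_chromosome) {
        cc <- orig_chrom[j]
        clen <- map$length[match(cc, map$chrom)]
        if (clen < l) stop("ROH does not fit on its chromosome", call. = FALSE)
      } else {
        fits <- which(map$length >= l)
        if (length(fits) == 0) stop("ROH longer than every chromosome", call. = FALSE)
        ci <- if (length(fits) == 1) fits else
          sample(fits, 1, prob = map$length[fits] - l + 1e-9)
        cc <- map$chrom[ci]
        clen <- map$length[ci]
      }
      a <- runif(1, 0, clen - l)
      b <- a + l
      prev <- which(chrom[seq_len(j - 1)] == cc)
      if (length(prev) == 0 ||
          all(b <= start[prev] | a >= end[prev])) {
        chrom[j] <- cc; start[j] <- a; end[j] <- b
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not re-place ROH without overlap", call. = FALSE)
  }
  list(chrom = chrom, start = start, end = end)
}
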