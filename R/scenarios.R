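#' @useDynLib admixabc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rbinom rbeta quantile density sd var median mad
#'   cmdscale prcomp predict ecdf aggregate
#' @importFrom utils head read.table write.table
#' @importFrom randomForest randomForest
#' @importFrom nnet nnet
#' @importFrom MASS lda
"_PACKAGE"

#' Scenario labels for the four competing admixture histories
#'
#' Each label combines the African and the European gene-flow regime after
#' the founding admixture pulse: either two discrete pulses ("2Pulses") or a
#' period of monotonically non-increasing recurring contribution
#' ("Recurring").
#'
#' @return Character vector of the four scenario labels.
#' @export
admix_scenarios <- function() {
  c("Afr2Pulses-Eur2Pulses", "Afr2Pulses-EurRecurring",
    "AfrRecurring-Eur2Pulses", "AfrRecurring-EurRecurring")
}

#' Prior specification for scenario parameters
#'
#' Uniform prior ranges for every scenario parameter: admixture times are
#' discrete uniform on \[1, 20\] generations, intensities uniform on \[0, 1\],
#' steepness parameters uniform on \[0, 0.5\], the founding size N0 uniform on
#' \[10, 1000\] diploid individuals and the final size N20 uniform on
#' \[100, 100000\] with N0 <= N20. The admixture process spans 21 generations
#' (g = 0 ... 20).
#'
#' The `"desk"` profile keeps every range identical except N20, scaled to
#' \[100, 1000\] so that reference tables of thousands of simulations are
#' tractable on a single workstation; it is the profile used throughout the
#' package's own analyses and tests.
#'
#' @param profile `"paper"` (full ranges) or `"desk"` (scaled N20).
#' @param overrides Named list of range overrides, e.g.
#'   `list(N20_range = c(100, 5000))`.
#' @return An object of class `prior_spec`.
#' @export
default_priors <- function(profile = c("paper", "desk"), overrides = list()) {
  profile <- match.arg(profile)
  spec <- list(
    generations = 21L,
    t_range  = c(1L, 20L),
    s_range  = c(0, 1),
    u_range  = c(0, 0.5),
    N0_range = c(10L, 1000L),
    N20_range = if (profile == "desk") c(100L, 1000L) else c(100L, 100000L),
    profile = profile
  )
  for (nm in names(overrides)) spec[[nm]] <- overrides[[nm]]
  structure(spec, class = "prior_spec")
}

#' Reproductive population size at a generation
#'
#' Deterministic size trajectory of the admixed population between the
#' founding size `N0` (generation 0) and the final size `N20`
#' (generation 20): the discrete solutions of an increasing rectangular
#' hyperbola with steepness parameter `uN` in \[0, 0.5\].
#' `N(g) = N0 + (N20 - N0) * (g * k) / (20 k + 20 - g)` with
#' `k = uN / (0.5 - uN)`. At `uN = 0.5` the trajectory is the linear
#' interpolation between `N0` and `N20`; as `uN -> 0` it stays at `N0` until
#' a sharp final increase to `N20`. Values are rounded half-up to integers.
#'
#' @param demography List with fields `N0`, `N20`, `uN`.
#' @param g Generation index (vectorised), in 0 ... 20.
#' @return Integer vector of diploid population sizes.
#' @export
population_size_at <- function(demography, g) {
  N0 <- demography$N0; N20 <- demography$N20; uN <- demography$uN
  if (is.null(N0) || is.null(N20) || is.null(uN) ||
      N0 < 10 || N0 > 1000 || N20 < 100 || N20 > 100000 || N0 > N20 ||
      uN < 0 || uN > 0.5) {
    stop("invalid demography parameters (need 10<=N0<=1000, 100<=N20<=100000, N0<=N20, 0<=uN<=0.5)",
         call. = FALSE)
  }
  if (any(g < 0 | g > 20 | g != floor(g))) {
    stop("generation index must be an integer in [0, 20]", call. = FALSE)
  }
  frac <- hyperbola_fraction(g, total = 20, u = uN)
  as.integer(floor(N0 + (N20 - N0) * frac + 0.5))
}

## Increasing rectangular hyperbola on [0, total], f(0)=0, f(total)=1.
## u = 0.5 -> linear; u -> 0 -> stays near 0 until x = total.
hyperbola_fraction <- function(x, total, u) {
  out <- numeric(length(x))
  at_end <- x >= total
  out[at_end] <- 1
  mid <- !at_end
  if (any(mid)) {
    if (u >= 0.5) {
      out[mid] <- x[mid] / total
    } else {
      k <- u / (0.5 - u)
      out[mid] <- (x[mid] * k) / (total * k + total - x[mid])
    }
  }
  out
}

#' Recurring admixture intensity at a generation
#'
#' During a recurring admixture period \[`t_t1`, `t_t2`\] the contribution of
#' a source decreases monotonically from `s_t1` to `s_t2` following the
#' decreasing mirror of the rectangular hyperbola with steepness `u`:
#' at `u = 0.5` the decrease is linear; as `u -> 0` the period is a sharp
#' pulse of intensity `s_t1` at `t_t1` followed by constant contribution
#' `s_t2` from the next generation on.
#'
#' @param process List with fields `t_t1`, `t_t2`, `s_t1`, `s_t2`, `u`.
#' @param g Generation (vectorised), must lie within the period.
#' @return Numeric contribution proportion(s) in `[s_t2, s_t1]`.
#' @export
recurring_intensity_at <- function(process, g) {
  t1 <- process$t_t1; t2 <- process$t_t2
  s1 <- process$s_t1; s2 <- process$s_t2; u <- process$u
  if (t2 < t1 + 1) stop("recurring period must satisfy t_t2 >= t_t1 + 1", call. = FALSE)
  if (s1 < s2) stop("recurring intensities must satisfy s_t1 >= s_t2", call. = FALSE)
  if (u < 0 || u > 0.5) stop("u must be in [0, 0.5]", call. = FALSE)
  if (any(g < t1 | g > t2)) {
    stop("generation outside the recurring admixture period", call. = FALSE)
  }
  Tt <- t2 - t1
  s2 + (s1 - s2) * hyperbola_fraction(Tt - (g - t1), total = Tt, u = u)
}

#' Per-generation contribution schedule implied by a parameter vector
#'
#' Expands a scenario parameter vector into the 21 rows
#' (`s_afr`, `s_eur`, `h`) of per-generation parental contributions from the
#' African source, the European source and the admixed population itself.
#' Row g = 0 holds the founding proportions (`h = 0`); each later row
#' satisfies `s_afr + s_eur + h = 1`.
#'
#' @param params An `admix_params` object (see [draw_parameters()]).
#' @return A 21 x 3 numeric matrix with columns `s_afr`, `s_eur`, `h` and
#'   rows named by generation `0:20`.
#' @export
build_schedule <- function(params) {
  sched <- matrix(0, nrow = 21, ncol = 3,
                  dimnames = list(0:20, c("s_afr", "s_eur", "h")))
  sched[1, ] <- c(params$s_Afr_0, 1 - params$s_Afr_0, 0)
  afr <- process_contributions(params$african)
  eur <- process_contributions(params$european)
  h <- 1 - afr - eur
  if (any(h < -1e-12)) {
    stop(structure(
      class = c("admixabc_constraint_error", "error", "condition"),
      list(message = "s_afr + s_eur exceeds 1 at some generation; redraw the parameter vector",
           call = NULL)))
  }
  sched[2:21, "s_afr"] <- afr
  sched[2:21, "s_eur"] <- eur
  sched[2:21, "h"] <- pmax(h, 0)
  sched
}

## contributions of one source process for generations 1..20
process_contributions <- function(proc) {
  contrib <- numeric(20)
  if (proc$kind == "pulse") {
    contrib[proc$t_p1] <- proc$s_p1
    contrib[proc$t_p2] <- proc$s_p2
  } else {
    gg <- proc$t_t1:proc$t_t2
    contrib[gg] <- recurring_intensity_at(proc, gg)
  }
  contrib
}

#' Draw a scenario parameter vector from the priors
#'
#' Draws every parameter of the requested scenario uniformly from the prior
#' ranges, honouring the ordering conditions (pulse times distinct with
#' `t_p1 > t_p2`, recurring period `t_t2 >= t_t1 + 1` with
#' `s_t1 >= s_t2`, `N0 <= N20`). Vectors whose contribution schedule would
#' push `s_afr + s_eur` above 1 in any generation are rejected and redrawn,
#' preserving the uniform prior on the feasible region.
#'
#' @param prior A `prior_spec` from [default_priors()].
#' @param scenario One of [admix_scenarios()].
#' @param max_attempts Rejection-sampling guard.
#' @return An object of class `admix_params`: fields `scenario`, `s_Afr_0`,
#'   `african`, `european` (each a pulse or recurring process list) and
#'   `demography` (`N0`, `N20`, `uN`).
#' @export
draw_parameters <- function(prior = default_priors(), scenario,
                            max_attempts = 1000L) {
  scenario <- match.arg(scenario, admix_scenarios())
  afr_recurring <- grepl("^AfrRecurring", scenario)
  eur_recurring <- grepl("EurRecurring$", scenario)
  for (attempt in seq_len(max_attempts)) {
    params <- structure(list(
      scenario = scenario,
      s_Afr_0 = runif(1, prior$s_range[1], prior$s_range[2]),
      african = draw_process("African", afr_recurring, prior),
      european = draw_process("European", eur_recurring, prior),
      demography = draw_demography(prior)
    ), class = "admix_params")
    ok <- tryCatch({ build_schedule(params); TRUE },
                   admixabc_constraint_error = function(e) FALSE)
    if (ok) return(params)
  }
  stop("failed to draw a feasible parameter vector after ", max_attempts,
       " attempts", call. = FALSE)
}

draw_process <- function(source, recurring, prior) {
  tt <- sort(sample(prior$t_range[1]:prior$t_range[2], 2L, replace = FALSE))
  ss <- runif(2, prior$s_range[1], prior$s_range[2])
  if (recurring) {
    list(kind = "recurring", source = source,
         t_t1 = tt[1], t_t2 = tt[2],
         s_t1 = max(ss), s_t2 = min(ss),
         u = runif(1, prior$u_range[1], prior$u_range[2]))
  } else {
    # Table-2 ordering: the first-labelled pulse is the more recent one
    list(kind = "pulse", source = source,
         t_p1 = tt[2], t_p2 = tt[1],
         s_p1 = ss[1], s_p2 = ss[2])
  }
}

draw_demography <- function(prior, max_attempts = 10000L) {
  for (i in seq_len(max_attempts)) {
    N0 <- sample(prior$N0_range[1]:prior$N0_range[2], 1L)
    N20 <- sample(prior$N20_range[1]:prior$N20_range[2], 1L)
    if (N0 <= N20) return(list(N0 = N0, N20 = N20, uN = runif(1, prior$u_range[1], prior$u_range[2])))
  }
  stop("could not draw demography with N0 <= N20", call. = FALSE)
}

#' Fixed column order for serialised parameter vectors
#'
#' @return Character vector: the documented TSV column order; parameters a
#'   scenario lacks are written as NA.
#' @export
param_columns <- function() {
  c("scenario", "s_Afr_0",
    "t_Afr_p1", "t_Afr_p2", "s_Afr_p1", "s_Afr_p2",
    "t_Afr_t1", "t_Afr_t2", "s_Afr_t1", "s_Afr_t2", "u_Afr",
    "t_Eur_p1", "t_Eur_p2", "s_Eur_p1", "s_Eur_p2",
    "t_Eur_t1", "t_Eur_t2", "s_Eur_t1", "s_Eur_t2", "u_Eur",
    "N0", "N20", "uN")
}

#' Flatten a parameter vector to a one-row data frame
#'
#' @param params An `admix_params` object.
#' @return A one-row data frame in [param_columns()] order.
#' @export
params_to_row <- function(params) {
  row <- as.list(rep(NA_real_, length(param_columns())))
  names(row) <- param_columns()
  row$scenario <- params$scenario
  row$s_Afr_0 <- params$s_Afr_0
  fill <- function(row, proc, pre) {
    if (proc$kind == "pulse") {
      row[paste0(pre, c("_p1", "_p2"))] <- c(proc$t_p1, proc$t_p2)
      row[paste0(sub("t_", "s_", pre), c("_p1", "_p2"))] <- c(proc$s_p1, proc$s_p2)
    } else {
      row[paste0(pre, c("_t1", "_t2"))] <- c(proc$t_t1, proc$t_t2)
      row[paste0(sub("t_", "s_", pre), c("_t1", "_t2"))] <- c(proc$s_t1, proc$s_t2)
      row[[paste0("u_", sub("t_", "", pre))]] <- proc$u
    }
    row
  }
  row <- fill(row, params$african, "t_Afr")
  row <- fill(row, params$european, "t_Eur")
  row$N0 <- params$demography$N0
  row$N20 <- params$demography$N20
  row$uN <- params$demography$uN
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Rebuild a parameter vector from a serialised row
#'
#' @param row One-row data frame (or named list) in [param_columns()] order.
#' @return An `admix_params` object.
#' @export
row_to_params <- function(row) {
  scenario <- as.character(row[["scenario"]])
  afr_recurring <- grepl("^AfrRecurring", scenario)
  eur_recurring <- grepl("EurRecurring$", scenario)
  get_proc <- function(recurring, source, pre) {
    if (recurring) {
      list(kind = "recurring", source = source,
           t_t1 = as.integer(row[[paste0("t_", pre, "_t1")]]),
           t_t2 = as.integer(row[[paste0("t_", pre, "_t2")]]),
           s_t1 = as.numeric(row[[paste0("s_", pre, "_t1")]]),
           s_t2 = as.numeric(row[[paste0("s_", pre, "_t2")]]),
           u = as.numeric(row[[paste0("u_", pre)]]))
    } else {
      list(kind = "pulse", source = source,
           t_p1 = as.integer(row[[paste0("t_", pre, "_p1")]]),
           t_p2 = as.integer(row[[paste0("t_", pre, "_p2")]]),
           s_p1 = as.numeric(row[[paste0("s_", pre, "_p1")]]),
           s_p2 = as.numeric(row[[paste0("s_", pre, "_p2")]]))
    }
  }
  structure(list(
    scenario = scenario,
    s_Afr_0 = as.numeric(row[["s_Afr_0"]]),
    african = get_proc(afr_recurring, "African", "Afr"),
    european = get_proc(eur_recurring, "European", "Eur"),
    demography = list(N0 = as.integer(row[["N0"]]),
                      N20 = as.integer(row[["N20"]]),
                      uN = as.numeric(row[["uN"]]))
  ), class = "admix_params")
}

## Largest-remainder apportionment of `total` among shares; ties and the
## leftover go to the class named by `tie_to` (index).
apportion_counts <- function(total, shares, tie_to = length(shares)) {
  raw <- shares * total
  base <- floor(raw)
  rem <- raw - base
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(rem, seq_along(rem) == tie_to, decreasing = TRUE)
    take <- ord[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}
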