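## Reference-table accessors: a reference table is a data.frame with a
## `scenario` column, the param_columns() (NA where a scenario lacks a
## parameter) and the 42 summary_stat_names() columns.

ref_stats <- function(table) {
  as.matrix(table[, summary_stat_names(), drop = FALSE])
}

#' Parameter names applicable to a scenario
#'
#' @param scenario One of [admix_scenarios()].
#' @return Character vector of parameter column names.
#' @export
scenario_params <- function(scenario) {
  scenario <- match.arg(scenario, admix_scenarios())
  afr <- if (grepl("^AfrRecurring", scenario)) {
    c("t_Afr_t1", "t_Afr_t2", "s_Afr_t1", "s_Afr_t2", "u_Afr")
  } else c("t_Afr_p1", "t_Afr_p2", "s_Afr_p1", "s_Afr_p2")
  eur <- if (grepl("EurRecurring$", scenario)) {
    c("t_Eur_t1", "t_Eur_t2", "s_Eur_t1", "s_Eur_t2", "u_Eur")
  } else c("t_Eur_p1", "t_Eur_p2", "s_Eur_p1", "s_Eur_p2")
  c("s_Afr_0", afr, eur, "N0", "N20", "uN")
}

#' Prior bounds used for the bounded parameter transform
#'
#' Discrete time parameters get half-open padding (\[0.5, 20.5\]) so the
#' logit-type transform is finite at the boundary values.
#'
#' @param prior A `prior_spec`.
#' @param scenario One of [admix_scenarios()].
#' @return Named list of `c(lower, upper)` per parameter.
#' @export
param_bounds <- function(prior, scenario) {
  nm <- scenario_params(scenario)
  out <- lapply(nm, function(p) {
    if (grepl("^t_", p)) c(prior$t_range[1] - 0.5, prior$t_range[2] + 0.5)
    else if (p == "N0") as.numeric(prior$N0_range) + c(-0.5, 0.5)
    else if (p == "N20") as.numeric(prior$N20_range) + c(-0.5, 0.5)
    else if (p %in% c("u_Afr", "u_Eur", "uN")) prior$u_range
    else prior$s_range
  })
  names(out) <- nm
  out
}

#' Goodness-of-fit prior check of an observed summary vector
#'
#' Standardizes every statistic to zero mean and unit variance over the
#' reference table, measures the mean Euclidean distance from the observed
#' vector to its `tau` nearest simulations, and compares it with the same
#' quantity for `n_null` simulations treated in turn as pseudo-observed
#' (leaving each out of its own neighbourhood). Also reports the
#' per-statistic percentile of the observed value within the simulated
#' distributions and a PCA projection of observed against simulated.
#'
#' @param observed Named numeric vector of the 42 statistics.
#' @param table Reference table.
#' @param n_null Null replicates (warning below 100).
#' @param tau Neighbourhood size (default 1% of the table, at least 10).
#' @return List: `p_value`, `gof_observed`, `gof_null`, `percentiles`,
#'   `pca` (list with `simulated`, `observed` coordinates).
#' @export
prior_check <- function(observed, table, n_null = 1000L, tau = NULL) {
  if (nrow(table) < 2) stop("reference table is empty", call. = FALSE)
  if (n_null < 100) warning("n_null < 100: the null p-value is coarse", call. = FALSE)
  S <- ref_stats(table)
  mu <- colMeans(S)
  sdev <- apply(S, 2, sd)
  sdev[sdev == 0] <- 1
  Z <- sweep(sweep(S, 2, mu), 2, sdev, "/")
  zo <- (observed[colnames(S)] - mu) / sdev
  if (is.null(tau)) tau <- max(10L, round(0.01 * nrow(Z)))
  tau <- min(tau, nrow(Z) - 1L)
  gof_of <- function(z, exclude = 0L) {
    d <- sqrt(rowSums(sweep(Z, 2, z)^2))
    if (exclude > 0) d <- d[-exclude]
    mean(sort(d, partial = tau)[seq_len(tau)])
  }
  gof_obs <- gof_of(zo)
  idx <- sample.int(nrow(Z), n_null, replace = n_null > nrow(Z))
  gof_null <- vapply(seq_along(idx),
                     function(i) gof_of(Z[idx[i], ], exclude = idx[i]),
                     numeric(1))
  pvalue <- mean(gof_null >= gof_obs)
  percentiles <- vapply(colnames(S),
                        function(cn) 100 * ecdf(S[, cn])(observed[cn]),
                        numeric(1))
  pca <- prcomp(Z, center = FALSE, scale. = FALSE, rank. = 2)
  list(p_value = pvalue, gof_observed = gof_obs, gof_null = gof_null,
       percentiles = percentiles,
       pca = list(simulated = pca$x,
                  observed = drop(matrix(zo, 1) %*% pca$rotation)))
}

rf_design <- function(table, add_lda) {
  X <- ref_stats(table)
  y <- factor(table$scenario)
  lda_fit <- NULL
  if (add_lda && nlevels(y) > 1) {
    keep <- apply(X, 2, sd) > 0
    lda_fit <- MASS::lda(X[, keep, drop = FALSE], grouping = y)
    X <- cbind(X, X[, keep, drop = FALSE] %*% lda_fit$scaling)
    attr(lda_fit, "keep") <- keep
  }
  list(X = X, y = y, lda = lda_fit)
}

rf_augment_obs <- function(observed, design) {
  obs <- matrix(observed[summary_stat_names()], nrow = 1,
                dimnames = list(NULL, summary_stat_names()))
  if (!is.null(design$lda)) {
    keep <- attr(design$lda, "keep")
    obs <- cbind(obs, obs[, keep, drop = FALSE] %*% design$lda$scaling)
  }
  colnames(obs) <- colnames(design$X)
  obs
}

#' Fit the Random-Forest ABC scenario classifier once
#'
#' Trains a classification forest on the 42 summary statistics of the
#' reference table (by default augmented with the linear-discriminant axes
#' of the scenario classes) plus a second regression forest on the
#' out-of-bag misclassification indicators, used to estimate the posterior
#' probability of a selected scenario. The fit can then score any number of
#' observed vectors via [rf_scenario_choice()].
#'
#' @param table Reference table covering at least two scenarios.
#' @param ntree Forest size (default 500).
#' @param add_lda Augment the statistic space with LDA axes (default TRUE).
#' @return `rf_scenario_fit` object.
#' @export
rf_scenario_fit <- function(table, ntree = 500L, add_lda = TRUE) {
  if (length(unique(table$scenario)) < 2) {
    stop("reference table covers a single scenario", call. = FALSE)
  }
  design <- rf_design(table, add_lda)
  rf <- randomForest::randomForest(design$X, design$y, ntree = ntree)
  err <- as.numeric(rf$predicted != design$y)
  # regression forest on the 0/1 out-of-bag error indicator
  rf_err <- suppressWarnings(
    randomForest::randomForest(design$X, err, ntree = ntree))
  structure(list(
    rf = rf, rf_err = rf_err, design = design, ntree = ntree,
    prior_error = mean(err),
    confusion = rf$confusion[, levels(design$y), drop = FALSE],
    importance = rf$importance[, 1],
    add_lda = add_lda
  ), class = "rf_scenario_fit")
}

#' Random-Forest ABC scenario choice
#'
#' Reads off the forest votes for an observed summary vector, selects the
#' winning scenario, and estimates the posterior probability of that choice
#' with the error-regression forest evaluated at the observed vector.
#'
#' @param table Reference table, or an [rf_scenario_fit()] object (reusing
#'   a fit avoids retraining when scoring many observed vectors).
#' @param observed Named numeric vector of the 42 statistics.
#' @param ntree,add_lda Forest settings (ignored when a fit is supplied).
#' @return `scenario_choice` object: `votes`, `selected`,
#'   `posterior_probability`, `prior_error` (out-of-bag), `confusion`,
#'   `importance`, `add_lda`.
#' @export
rf_scenario_choice <- function(table, observed, ntree = 500L,
                               add_lda = TRUE) {
  fit <- if (inherits(table, "rf_scenario_fit")) table
         else rf_scenario_fit(table, ntree = ntree, add_lda = add_lda)
  obs <- rf_augment_obs(observed, fit$design)
  votes <- predict(fit$rf, obs, type = "vote")[1, ] * fit$ntree
  selected <- names(votes)[which.max(votes)]
  post <- 1 - predict(fit$rf_err, obs)[[1]]
  structure(list(
    votes = votes, selected = selected,
    posterior_probability = min(1, max(0, post)),
    prior_error = fit$prior_error,
    confusion = fit$confusion,
    importance = fit$importance,
    add_lda = fit$add_lda
  ), class = "scenario_choice")
}

#' Out-of-bag cross-validation of the RF scenario choice
#'
#' Every reference-table row is classified out-of-bag; reports the
#' confusion matrix, per-scenario error rates and the global prior error.
#'
#' @inheritParams rf_scenario_choice
#' @return List: `confusion`, `per_scenario_error`, `prior_error`.
#' @export
rf_cross_validate <- function(table, ntree = 500L, add_lda = TRUE) {
  design <- rf_design(table, add_lda)
  rf <- randomForest::randomForest(design$X, design$y, ntree = ntree)
  conf <- rf$confusion[, levels(design$y), drop = FALSE]
  per <- rf$confusion[, "class.error"]
  list(confusion = conf, per_scenario_error = per,
       prior_error = mean(rf$predicted != design$y))
}

#' @export
print.scenario_choice <- function(x, ...) {
  cat("RF-ABC scenario choice\n")
  cat("  selected:", x$selected,
      sprintf("(%d/%d votes, posterior probability %.3f)\n",
              round(x$votes[x$selected]), round(sum(x$votes)),
              x$posterior_probability))
  cat("  out-of-bag prior error:", round(x$prior_error, 3), "\n")
  invisible(x)
}

bounded_to_real <- function(x, lo, hi) {
  eps <- 1e-6 * (hi - lo)
  x <- pmin(pmax(x, lo + eps), hi - eps)
  log((x - lo) / (hi - x))
}

real_to_bounded <- function(z, lo, hi) {
  lo + (hi - lo) / (1 + exp(-z))
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Neural-Network ABC joint posterior parameter estimation
#'
#' Retains the `tolerance` fraction of reference-table simulations nearest
#' to the observed vector (Euclidean distance on statistics standardized by
#' their median absolute deviation over the table), maps every parameter to
#' the real line by a bounded logit transform over its prior range, fits an
#' ensemble of single-hidden-layer feed-forward regressions of the
#' transformed parameters on the standardized statistics, applies the
#' regression adjustment `theta* = m(s_obs) + (theta - m(s))` with the
#' ensemble-averaged conditional mean `m`, and back-transforms. Posterior
#' summaries use Epanechnikov weights on the retained distances.
#'
#' @param table Reference table (restricted to one scenario, or carrying a
#'   `scenario` column from which the rows of `scenario` are taken).
#' @param observed Named numeric vector of the 42 statistics.
#' @param prior The `prior_spec` the table was drawn from.
#' @param scenario Scenario whose parameters are estimated.
#' @param tolerance Retained fraction of simulations (default 0.01).
#' @param n_networks Ensemble size (default 10).
#' @param hidden Hidden-layer size (default 5; small relative to the
#'   retained set so the conditional-mean network cannot memorise it).
#' @param decay,maxit `nnet` regularisation and iteration cap.
#' @return `posterior_estimate` object: `posterior` (retained x parameters,
#'   adjusted, on the parameter scale), `weights`, and `summary` (per
#'   parameter: median, 50% and 95% credibility intervals).
#' @export
nn_estimate <- function(table, observed, prior, scenario,
                        tolerance = 0.01, n_networks = 10L, hidden = NULL,
                        decay = 0.1, maxit = 500L) {
  stopifnot(tolerance > 0, tolerance <= 1)
  tab <- table[table$scenario == scenario, , drop = FALSE]
  if (nrow(tab) < 1 / tolerance) {
    stop("reference table smaller than 1/tolerance rows", call. = FALSE)
  }
  pnames <- scenario_params(scenario)
  bounds <- param_bounds(prior, scenario)
  S <- ref_stats(tab)
  scl <- apply(S, 2, mad)
  fallback <- apply(S, 2, sd)
  scl[scl == 0] <- fallback[scl == 0]
  scl[scl == 0] <- 1
  Z <- sweep(S, 2, scl, "/")
  zo <- observed[colnames(S)] / scl
  d <- sqrt(rowSums(sweep(Z, 2, zo)^2))
  n_keep <- max(2L, floor(tolerance * nrow(tab)))
  keep <- order(d)[seq_len(n_keep)]
  dmax <- d[keep[n_keep]]
  if (!is.finite(dmax) || dmax == 0) {
    stop("degenerate retained set: all retained simulations coincide with the observed vector",
         call. = FALSE)
  }
  w <- 1 - (d[keep] / dmax)^2
  w[w <= 0] <- min(w[w > 0]) / 2
  theta <- as.matrix(tab[keep, pnames, drop = FALSE])
  zth <- sapply(pnames, function(p) {
    bounded_to_real(theta[, p], bounds[[p]][1], bounds[[p]][2])
  })
  Xk <- Z[keep, , drop = FALSE]
  if (is.null(hidden)) hidden <- 5L
  const <- apply(zth, 2, sd) == 0
  m_obs <- matrix(0, 1, ncol(zth))
  m_fit <- matrix(0, nrow(zth), ncol(zth))
  if (any(!const)) {
    y <- zth[, !const, drop = FALSE]
    ysc <- apply(y, 2, sd)
    ymu <- colMeans(y)
    yz <- sweep(sweep(y, 2, ymu), 2, ysc, "/")
    preds_obs <- 0; preds_fit <- 0
    for (net in seq_len(n_networks)) {
      fit <- nnet::nnet(Xk, yz, size = hidden, linout = TRUE, decay = decay,
                        maxit = maxit, trace = FALSE, MaxNWts = 100000)
      preds_obs <- preds_obs + predict(fit, matrix(zo, 1, dimnames = list(NULL, colnames(Z))))
      preds_fit <- preds_fit + predict(fit, Xk)
    }
    mo <- sweep(sweep(preds_obs / n_networks, 2, ysc, "*"), 2, ymu, "+")
    mf <- sweep(sweep(preds_fit / n_networks, 2, ysc, "*"), 2, ymu, "+")
    m_obs[, !const] <- mo
    m_fit[, !const] <- mf
  }
  zadj <- sweep(zth - m_fit, 2, m_obs[1, ], "+")
  zadj[, const] <- zth[, const]
  post <- sapply(pnames, function(p) {
    j <- match(p, pnames)
    real_to_bounded(zadj[, j], bounds[[p]][1], bounds[[p]][2])
  })
  colnames(post) <- pnames
  summ <- t(apply(post, 2, function(x) {
    q <- weighted_quantile(x, w, c(0.5, 0.25, 0.75, 0.025, 0.975))
    c(median = q[1], ci50_lo = q[2], ci50_hi = q[3],
      ci95_lo = q[4], ci95_hi = q[5])
  }))
  colnames(summ) <- c("median", "ci50_lo", "ci50_hi", "ci95_lo", "ci95_hi")
  structure(list(posterior = post, weights = w,
                 summary = as.data.frame(summ), scenario = scenario,
                 tolerance = tolerance, n_retained = n_keep),
            class = "posterior_estimate")
}

#' Leave-out cross-validation of the NN posterior estimates
#'
#' Treats `n_cv` reference-table rows in turn as pseudo-observed, estimates
#' their parameters from the remaining rows, and reports the per-parameter
#' scaled prediction error: mean squared error of the posterior median
#' divided by the prior variance (the variance of the parameter over the
#' table), so 0 is perfect and 1 is prior-level information.
#'
#' @inheritParams nn_estimate
#' @param n_cv Number of left-out rows (default 20).
#' @return Named numeric vector of per-parameter scaled errors.
#' @export
nn_cross_validate <- function(table, prior, scenario, tolerance = 0.01,
                              n_cv = 20L, n_networks = 5L, hidden = NULL,
                              decay = 0.1, maxit = 500L) {
  tab <- table[table$scenario == scenario, , drop = FALSE]
  pnames <- scenario_params(scenario)
  idx <- sample.int(nrow(tab), min(n_cv, nrow(tab)))
  err2 <- matrix(NA_real_, length(idx), length(pnames),
                 dimnames = list(NULL, pnames))
  for (i in seq_along(idx)) {
    obs <- ref_stats(tab[idx[i], , drop = FALSE])[1, ]
    est <- nn_estimate(tab[-idx[i], , drop = FALSE], obs, prior, scenario,
                       tolerance = tolerance, n_networks = n_networks,
                       hidden = hidden, decay = decay, maxit = maxit)
    truth <- as.numeric(tab[idx[i], pnames])
    err2[i, ] <- (est$summary$median - truth)^2
  }
  prior_var <- apply(as.matrix(tab[, pnames]), 2, var)
  colMeans(err2) / prior_var
}
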