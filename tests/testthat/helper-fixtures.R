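# Shared fixtures: parameter constructors, fake ABC tables, and the
# memoised desk-scale context used by the heavier end-to-end checks.

make_pulse <- function(source, t_p1, t_p2, s_p1, s_p2) {
  list(kind = "pulse", source = source,
       t_p1 = as.integer(t_p1), t_p2 = as.integer(t_p2),
       s_p1 = s_p1, s_p2 = s_p2)
}

make_recurring <- function(source, t_t1, t_t2, s_t1, s_t2, u) {
  list(kind = "recurring", source = source,
       t_t1 = as.integer(t_t1), t_t2 = as.integer(t_t2),
       s_t1 = s_t1, s_t2 = s_t2, u = u)
}

make_params <- function(scenario, s_Afr_0, african, european,
                        N0 = 300L, N20 = 700L, uN = 0.25) {
  structure(list(scenario = scenario, s_Afr_0 = s_Afr_0,
                 african = african, european = european,
                 demography = list(N0 = as.integer(N0),
                                   N20 = as.integer(N20), uN = uN)),
            class = "admix_params")
}

# Strong-signal configurations per scenario: fixed points in the regions
# where the competing gene-flow regimes are distinguishable in principle
# (chosen by a pre-registered design study; see the methods vignette).
strong_signal_params <- function(scenario) {
  switch(scenario,
    "Afr2Pulses-Eur2Pulses" = make_params(
      scenario, 0.63,
      make_pulse("African", 7, 2, 0.85, 0.10),
      make_pulse("European", 20, 12, 0.50, 0.10),
      N0 = 1000L, N20 = 1000L, uN = 0.3),
    "Afr2Pulses-EurRecurring" = make_params(
      scenario, 0.60,
      make_pulse("African", 16, 3, 0.70, 0.50),
      make_recurring("European", 6, 13, 0.80, 0.45, 0.25),
      N0 = 1000L, N20 = 1000L, uN = 0.3),
    "AfrRecurring-Eur2Pulses" = make_params(
      scenario, 0.50,
      make_recurring("African", 9, 18, 0.50, 0.25, 0.15),
      make_pulse("European", 20, 4, 0.85, 0.60),
      N0 = 1000L, N20 = 1000L, uN = 0.3),
    "AfrRecurring-EurRecurring" = make_params(
      scenario, 0.55,
      make_recurring("African", 2, 8, 0.75, 0.40, 0.25),
      make_recurring("European", 10, 17, 0.75, 0.45, 0.25),
      N0 = 700L, N20 = 1000L, uN = 0.3),
    stop("unknown scenario"))
}

# Fake reference tables for exercising the ABC machinery without
# simulations: parameters drawn from the real priors, statistics built to
# order (pure noise, or informative columns).
fake_reference_table <- function(n_per_scenario = 200L,
                                 scenarios = admix_scenarios(),
                                 informative = c("none", "scenario", "s_Afr_0"),
                                 noise_sd = 0.1, seed = 1) {
  informative <- match.arg(informative)
  set.seed(seed)
  prior <- default_priors("desk")
  rows <- list()
  for (sc in scenarios) {
    for (k in seq_len(n_per_scenario)) {
      rows[[length(rows) + 1]] <- params_to_row(draw_parameters(prior, sc))
    }
  }
  tab <- do.call(rbind, rows)
  stats <- matrix(rnorm(nrow(tab) * 42), nrow(tab), 42,
                  dimnames = list(NULL, summary_stat_names()))
  if (informative == "scenario") {
    stats[, 1] <- match(tab$scenario, admix_scenarios()) +
      rnorm(nrow(tab), sd = noise_sd)
  } else if (informative == "s_Afr_0") {
    stats[, 1] <- tab$s_Afr_0 + rnorm(nrow(tab), sd = noise_sd)
  }
  cbind(tab, as.data.frame(stats))
}

# Memoised desk-scale context shared by the end-to-end checks: source
# frequency panels, reservoirs, a 4 x 500 reference table (L = 5000 SNPs,
# n = 30 admixed per simulation) and the fitted scenario classifier.
.ctx_env <- new.env(parent = emptyenv())

desk_context <- function() {
  if (!is.null(.ctx_env$ctx)) return(.ctx_env$ctx)
  set.seed(2026)
  freqs <- generate_source_frequencies(5000, divergence = 0.15)
  reservoirs <- build_reservoir_pair(freqs, R = 2000L)
  table <- simulate_reference_table(
    freqs, prior = default_priors("desk"), n_per_scenario = 500L,
    n_admixed = 30L, seed = 20260930L, reservoirs = reservoirs)
  fit <- rf_scenario_fit(table, ntree = 500L)
  .ctx_env$ctx <- list(freqs = freqs, reservoirs = reservoirs,
                       table = table, fit = fit,
                       prior = default_priors("desk"))
  .ctx_env$ctx
}
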