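#' Simulate a reference table of parameter draws and summary statistics
#'
#' For each requested scenario, draws `n_per_scenario` parameter vectors
#' from the priors, runs the forward simulation, samples an unrelated
#' admixed set plus both source panels, and computes the 42 summary
#' statistics. The result is the ABC training object: one row per
#' simulation with the scenario label, the full parameter column set and
#' the statistics. Deterministic given `seed`.
#'
#' @param freqs List with `afr` and `eur` source allele-frequency vectors.
#' @param prior A `prior_spec`.
#' @param scenarios Scenario labels to simulate (default all four).
#' @param n_per_scenario Simulations per scenario.
#' @param n_admixed Admixed sample size per simulation (default 30).
#' @param reservoir_size Haploid genomes per source reservoir (default
#'   2000, the desk-scale profile; the full-scale configuration uses
#'   20000).
#' @param n_source Source sample size per simulation (default 60).
#' @param seed Optional integer seed.
#' @param progress Log a line per 100 simulations to stderr.
#' @param reservoirs Optional pre-built reservoir pair; supply the same
#'   pair used for any pseudo-observed data so that table and observations
#'   share the fixed gamete reservoirs (as the inference design assumes).
#' @return Reference-table data frame with attribute `config`.
#' @export
simulate_reference_table <- function(freqs, prior = default_priors("desk"),
                                     scenarios = admix_scenarios(),
                                     n_per_scenario = 500L,
                                     n_admixed = 30L,
                                     reservoir_size = 2000L,
                                     n_source = 60L,
                                     seed = NULL, progress = FALSE,
                                     reservoirs = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scenarios <- match.arg(scenarios, admix_scenarios(), several.ok = TRUE)
  if (is.null(reservoirs)) {
    reservoirs <- build_reservoir_pair(freqs, R = reservoir_size)
  }
  total <- length(scenarios) * n_per_scenario
  rows <- vector("list", total)
  stats <- matrix(NA_real_, total, 42,
                  dimnames = list(NULL, summary_stat_names()))
  i <- 0L
  n_redrawn <- 0L
  for (sc in scenarios) {
    for (k in seq_len(n_per_scenario)) {
      i <- i + 1L
      for (attempt in 1:50) {
        params <- draw_parameters(prior, sc)
        sv <- tryCatch({
          pop <- run_simulation(params, reservoirs)
          samples <- draw_sample_set(pop, reservoirs, n_admixed,
                                     n_source = n_source)
          compute_summary_vector(samples)
        }, admixabc_insufficient_unrelated = function(e) NULL)
        if (!is.null(sv)) break
        # demographies that stay tiny until the final generation cannot
        # yield n_admixed unrelated individuals; redraw the vector
        n_redrawn <- n_redrawn + 1L
      }
      if (is.null(sv)) {
        stop("simulation ", i, " (", sc, "): no feasible parameter draw ",
             "yielded ", n_admixed, " unrelated individuals", call. = FALSE)
      }
      rows[[i]] <- params_to_row(params)
      stats[i, ] <- sv
      if (progress && i %% 100 == 0) {
        message("simulated ", i, "/", total)
      }
    }
  }
  out <- cbind(do.call(rbind, rows), as.data.frame(stats))
  attr(out, "n_redrawn") <- n_redrawn
  attr(out, "config") <- list(
    prior = unclass(prior), scenarios = scenarios,
    n_per_scenario = n_per_scenario, n_admixed = n_admixed,
    reservoir_size = reservoir_size, n_source = n_source, seed = seed)
  out
}

#' Full ABC inference on an observed summary vector
#'
#' Runs the check-then-infer pipeline: prior check (a failing check is
#' prominently warned about but the run continues), RF-ABC scenario choice
#' with out-of-bag cross-validation, then NN-ABC joint posterior parameter
#' estimation (with leave-out cross-validation errors) under the winning
#' scenario.
#'
#' @param table Reference table covering every scenario in `scenarios`.
#' @param observed Named numeric vector of the 42 statistics (or a
#'   `sample_set`, whose statistics are computed first).
#' @param prior The `prior_spec` the table was drawn from.
#' @param scenarios Scenarios the table must cover (default all four).
#' @param ntree,add_lda RF settings (see [rf_scenario_choice()]).
#' @param tolerance,n_networks,hidden NN settings (see [nn_estimate()]).
#' @param n_null Prior-check null replicates.
#' @param nn_cv Rows for NN cross-validation (0 to skip).
#' @param out_dir Optional directory for JSON/TSV results.
#' @param seed Optional integer seed.
#' @return List: `prior_check`, `scenario_choice`, `rf_cv`, `posterior`,
#'   `nn_cv`, `config`.
#' @export
run_inference <- function(table, observed, prior,
                          scenarios = admix_scenarios(),
                          ntree = 500L, add_lda = TRUE,
                          tolerance = 0.2, n_networks = 10L, hidden = NULL,
                          n_null = 500L, nn_cv = 0L,
                          out_dir = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(observed, "sample_set")) {
    observed <- compute_summary_vector(observed)
  }
  if (length(observed) != 42 ||
      !all(summary_stat_names() %in% names(observed))) {
    stop("observed statistics must be a named vector of the 42 summary statistics",
         call. = FALSE)
  }
  missing_sc <- setdiff(scenarios, unique(table$scenario))
  if (length(missing_sc) > 0) {
    stop("reference table misses scenario(s): ",
         paste(missing_sc, collapse = ", "), call. = FALSE)
  }
  pc <- prior_check(observed, table, n_null = n_null)
  if (pc$p_value < 0.05) {
    warning("PRIOR CHECK FAILED (p = ", signif(pc$p_value, 3),
            "): observed statistics sit outside the simulated space; ",
            "inference continues but should be interpreted with caution",
            call. = FALSE)
  }
  choice <- rf_scenario_choice(table, observed, ntree = ntree,
                               add_lda = add_lda)
  rf_cv <- rf_cross_validate(table, ntree = ntree, add_lda = add_lda)
  post <- nn_estimate(table, observed, prior, choice$selected,
                      tolerance = tolerance, n_networks = n_networks,
                      hidden = hidden)
  nncv <- if (nn_cv > 0) {
    nn_cross_validate(table, prior, choice$selected, tolerance = tolerance,
                      n_cv = nn_cv, n_networks = max(2L, n_networks %/% 2L),
                      hidden = hidden)
  } else NULL
  config <- list(ntree = ntree, add_lda = add_lda, tolerance = tolerance,
                 n_networks = n_networks, n_null = n_null, seed = seed)
  res <- list(prior_check = pc, scenario_choice = choice, rf_cv = rf_cv,
              posterior = post, nn_cv = nncv,
              config = c(config, hash = config_hash(config)))
  if (!is.null(out_dir)) write_inference_results(res, out_dir)
  res
}

#' Write an inference results bundle to a directory
#'
#' JSON for the structured results (votes, probabilities, credibility
#' intervals, errors, config hash), TSV for the posterior sample.
#'
#' @param res Result of [run_inference()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_inference_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summ <- res$posterior$summary
  jsonlite::write_json(list(
    prior_check = list(p_value = res$prior_check$p_value,
                       percentiles = as.list(res$prior_check$percentiles)),
    scenario_choice = list(
      votes = as.list(res$scenario_choice$votes),
      selected = res$scenario_choice$selected,
      posterior_probability = res$scenario_choice$posterior_probability,
      prior_error = res$scenario_choice$prior_error),
    rf_cv = list(prior_error = res$rf_cv$prior_error,
                 per_scenario_error = as.list(res$rf_cv$per_scenario_error)),
    posterior = lapply(seq_len(nrow(summ)), function(i) as.list(summ[i, ])),
    posterior_parameters = rownames(summ),
    nn_cv = if (!is.null(res$nn_cv)) as.list(res$nn_cv) else NULL,
    config = res$config
  ), file.path(out_dir, "inference.json"), auto_unbox = TRUE, digits = NA)
  write.table(data.frame(res$posterior$posterior,
                         weight = res$posterior$weights),
              file.path(out_dir, "posterior_sample.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Ancestry-excess permutation test with a serialisable result
#'
#' Thin orchestration over [roh_permutation_test()]: runs the test and
#' optionally writes a JSON result file.
#'
#' @param track An `ancestry_roh_track`.
#' @param ancestry `"AFR"` (default) or `"EUR"`.
#' @param n_perm Number of permutations.
#' @param out_file Optional JSON output path.
#' @param seed Optional integer seed.
#' @param ... Passed to [roh_permutation_test()].
#' @return The [roh_permutation_test()] result list.
#' @export
roh_excess_test <- function(track, ancestry = "AFR", n_perm = 10000L,
                            out_file = NULL, seed = NULL, ...) {
  if (nrow(track$roh) == 0) stop("empty track set", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- roh_permutation_test(track, ancestry = ancestry, n_perm = n_perm, ...)
  if (!is.null(out_file)) {
    jsonlite::write_json(list(
      ancestry = ancestry, observed = res$observed, p_value = res$p_value,
      n_perm = n_perm, seed = seed,
      excess = as.list(res$excess)
    ), out_file, auto_unbox = TRUE, digits = NA)
  }
  res
}
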