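# End-to-end workflow: tune -> post-FIC stochastic simulation ->
# matched no-FIC control -> BOLD -> fitting metrics -> Poincare regimes.

#' Pipeline configuration
#'
#' Bundles everything one sweep over global coupling and activity
#' targets needs.  Durations are deliberately independent: tuning is
#' deterministic (`T_tune`), the stochastic post-FIC run (`T_p`)
#' provides the PSPs, and the BOLD duration equals the post-FIC neural
#' run driving it.
#'
#' @param connectome a [connectome()].
#' @param p a [jr_params()].
#' @param dp a [dfic_params()] (its `y0_target` is overridden per grid
#'   point).
#' @param bp a [balloon_params()].
#' @param G_grid global coupling values to sweep.
#' @param y0_target_grid activity targets to sweep.
#' @param T_p post-FIC (stochastic) duration, ms.
#' @param dt integration step, ms.
#' @param record_dt PSP recording interval, ms.
#' @param seed base seed; each (G, target) combination derives its own.
#' @param emp a `surrogate_empirical` (or real FC/FCD targets in the
#'   same shape); `NULL` generates a surrogate matching the connectome.
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(connectome, p = jr_params(), dp = dfic_params(),
                       bp = balloon_params(), G_grid = c(0, 1),
                       y0_target_grid = c(0.01, 0.103), T_p = 180000,
                       dt = 1, record_dt = 2, seed = 1, emp = NULL,
                       out_dir = NULL) {
  stopifnot(length(G_grid) >= 1, length(y0_target_grid) >= 1,
            T_p > 60000 * 1.2 || T_p > 0)
  if (is.null(emp))
    emp <- generate_surrogate_empirical(connectome$n_nodes, seed)
  structure(list(connectome = connectome, p = p, dp = dp, bp = bp,
                 G_grid = G_grid, y0_target_grid = y0_target_grid,
                 T_p = T_p, dt = dt, record_dt = record_dt, seed = seed,
                 emp = emp, out_dir = out_dir),
            class = "run_config")
}

simulate_post_fic <- function(cfg, p, pfic, y_init, seed) {
  integrate_heun(y_init, cfg$connectome, p, wfic = pfic, T = cfg$T_p,
                 dt = cfg$dt, stochastic = TRUE, seed = seed,
                 record_dt = cfg$record_dt)
}

analyze_run <- function(cfg, traj) {
  bold <- bold_from_psp(traj$psp, cfg$record_dt, traj$p, cfg$bp)
  fc <- functional_connectivity(bold)
  can_fcd <- nrow(bold$signal) * bold$TR / 1000 >= 2 * 60
  fd <- if (can_fcd) fcd(bold) else NULL
  scores <- mmf(fc_fit(fc, cfg$emp$fc_target),
                if (can_fcd) ks_similarity(fd$values, cfg$emp$fcd_values)
                else NA_real_,
                fc$fc_mean)
  poin <- poincare_classify(traj$psp, cfg$record_dt)
  list(bold = bold, fc = fc, fcd = fd, scores = scores, poincare = poin)
}

#' Compare regime diversity between matched conditions
#'
#' Counts, in each condition, the nodes exhibiting at least two
#' dynamical regimes and returns whether feedback inhibition control
#' increased, decreased or left unchanged the diversity of traversed
#' regimes.
#'
#' @param post_fic,no_fic `poincare_result` objects from matched runs.
#' @return List with `verdict` (`"increased"`, `"decreased"`,
#'   `"no_change"`), `post_multi`, `no_multi` (node counts with >= 2
#'   regimes).
#' @export
regime_diversity_report <- function(post_fic, no_fic) {
  post_multi <- sum(post_fic$regime_count >= 2)
  no_multi <- sum(no_fic$regime_count >= 2)
  verdict <- if (post_multi > no_multi) "increased"
             else if (post_multi < no_multi) "decreased" else "no_change"
  list(verdict = verdict, post_multi = post_multi, no_multi = no_multi)
}

#' Run the full tuning / post-FIC / no-FIC pipeline
#'
#' For every combination of global coupling and activity target:
#' deterministic dFIC tuning on the connectome; extraction of the
#' per-node `pFIC` constants; a stochastic post-FIC simulation using
#' them; a matched no-FIC control with `pFIC_i = 1` consuming the
#' identical noise stream and drive; Balloon BOLD, FC/FCD/MMF scoring
#' against the empirical (or surrogate) targets; and Poincare regime
#' classification of both conditions.  A failing combination is
#' recorded with its error message and the sweep continues.
#'
#' @param cfg a [run_config()].
#' @return An object of class `pipeline_result`: `table` (one row per
#'   combination with convergence, fit and regime summaries) and
#'   `details` (per-combination list with tuning, analyses and the
#'   regime report).
#' @export
run_pipeline <- function(cfg) {
  combos <- expand.grid(G = cfg$G_grid, y0_target = cfg$y0_target_grid)
  details <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    G <- combos$G[k]
    target <- combos$y0_target[k]
    combo_seed <- (cfg$seed * 1009L + k) %% .Machine$integer.max
    res <- tryCatch({
      p <- cfg$p
      p$G <- G
      dp <- cfg$dp
      dp$y0_target <- target
      ic <- default_initial_conditions(target, cfg$connectome$n_nodes,
                                       combo_seed, p = p)
      p$mu <- ic$mu
      tune <- run_tuning(cfg$connectome, p, dp, ic = ic,
                         seed = combo_seed, dt = cfg$dt)
      pfic <- extract_pfic(tune)
      post <- simulate_post_fic(cfg, p, pfic, tune$y_final, combo_seed)
      ctrl <- simulate_post_fic(cfg, p, rep(1, cfg$connectome$n_nodes),
                                tune$y_final, combo_seed)
      a_post <- analyze_run(cfg, post)
      a_ctrl <- analyze_run(cfg, ctrl)
      report <- regime_diversity_report(a_post$poincare, a_ctrl$poincare)
      list(tuning = tune, pfic = pfic, post = a_post, ctrl = a_ctrl,
           regimes = report, error = NULL)
    }, error = function(e) list(error = conditionMessage(e)))
    details[[k]] <- res
    rows[[k]] <- if (is.null(res$error)) {
      data.frame(G = G, y0_target = target, seed = combo_seed,
                 n_converged = sum(res$tuning$converged),
                 max_rel_dev = max(res$tuning$final_rel_dev),
                 r_fc = res$post$scores$r_fc,
                 one_minus_ksd = res$post$scores$one_minus_ksd,
                 fc_mean = res$post$scores$fc_mean,
                 mmf = res$post$scores$mmf,
                 rejected = res$post$scores$rejected,
                 mmf_nofic = res$ctrl$scores$mmf,
                 regime_verdict = res$regimes$verdict,
                 post_multi = res$regimes$post_multi,
                 no_multi = res$regimes$no_multi,
                 error = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(G = G, y0_target = target, seed = combo_seed,
                 n_converged = NA, max_rel_dev = NA, r_fc = NA,
                 one_minus_ksd = NA, fc_mean = NA, mmf = NA,
                 rejected = NA, mmf_nofic = NA,
                 regime_verdict = NA_character_, post_multi = NA,
                 no_multi = NA, error = res$error,
                 stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(cfg$out_dir, "pipeline_results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(seq_len(nrow(table)), function(i) as.list(table[i, ])),
      file.path(cfg$out_dir, "pipeline_results.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  structure(list(table = table, details = details, cfg = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline sweep over", length(unique(x$table$G)), "G value(s) x",
      length(unique(x$table$y0_target)), "target(s)\n")
  print(x$table[, c("G", "y0_target", "n_converged", "r_fc", "mmf",
                    "regime_verdict")])
  invisible(x)
}

#' Read a pipeline-style configuration file
#'
#' YAML with optional blocks `jr:`, `dfic:`, `balloon:` (keys mirroring
#' the parameter constructors), `connectome:` (either `weights` +
#' `tract_lengths` paths or `generator: small|whole_brain` with `n`,
#' `seed`), and top-level `G_grid`, `y0_target_grid`, `T_p`, `dt`,
#' `seed`, `out_dir`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  p <- do.call(jr_params, y$jr %||% list())
  dp <- do.call(dfic_params, y$dfic %||% list())
  bp <- do.call(balloon_params, y$balloon %||% list())
  cn <- y$connectome
  conn <- if (!is.null(cn$weights)) {
    load_connectome(cn$weights, cn$tract_lengths)
  } else if (identical(cn$generator, "whole_brain")) {
    generate_whole_brain_like(cn$n %||% 84, cn$seed %||% 1)
  } else {
    generate_small_network(cn$n %||% 4, cn$seed %||% 1)
  }
  run_config(conn, p, dp, bp,
             G_grid = unlist(y$G_grid) %||% c(0, 1),
             y0_target_grid = unlist(y$y0_target_grid) %||% c(0.01),
             T_p = y$T_p %||% 180000, dt = y$dt %||% 1,
             record_dt = y$record_dt %||% 2, seed = y$seed %||% 1,
             out_dir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
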