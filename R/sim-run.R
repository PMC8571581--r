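#' Run one evolutionary replicate
#'
#' Executes the full generational loop -- grow groups from founders, build the
#' coordination network, resolve phenotypes, compute fecundities, then global
#' competition with mutation -- for `config$generations` generations, recording
#' the population means of `q`, `s` and the realized helper proportion `P`
#' each generation. Row `g` of the trajectory describes generation `g`: the
#' founder trait means *before* selection and the helper proportion realized
#' by those founders' groups. With `generations = 0` a single row records the
#' initial founder means (`mean_P` is `NA` since no group develops).
#'
#' The default engine is the compiled transcription of the step functions
#' (fast; used for all long runs). `engine = "r"` loops the tidy step
#' functions ([grow_groups()], [build_links()], [resolve_phenotypes()],
#' [group_fecundities()], [next_generation()]) and is intended for small
#' illustrative runs and for testing. Both engines draw from R's RNG, so each
#' is bit-reproducible given `seed` (they consume randomness in different
#' orders, so they match statistically, not draw-for-draw).
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed for the run.
#' @param engine `"cpp"` (default) or `"r"`.
#' @return A tibble of class `dol_trajectory` with columns `generation`,
#'   `mean_q`, `mean_s`, `mean_P`, and attributes `config` and `seed`.
#' @examples
#' cfg <- sim_config(dol_params(1, 10, epsilon = 1), target_pop_size = 200,
#'                   generations = 50, s_locked_at_zero = TRUE)
#' traj <- run_replicate(cfg, seed = 1)
#' tail(traj)
#' @export
run_replicate <- function(config, seed, engine = c("cpp", "r")) {
  stopifnot(inherits(config, "dol_sim_config"))
  engine <- match.arg(engine)
  set.seed(seed)
  p <- config$params
  if (engine == "cpp") {
    res <- sim_engine_cpp(
      p$l, p$m, config$n_groups, config$generations,
      p$epsilon, p$theta, config$p_mut, config$mut_sd,
      config$init_q, config$init_s, config$s_locked_at_zero,
      config$coordination_scope == "own_lineage",
      match(config$cost_shape, c("decelerating", "linear", "accelerating")) - 1L,
      config$resolution_passes
    )
    traj <- res$traj
  } else {
    gens <- max(config$generations, 1L)
    traj <- matrix(NA_real_, nrow = gens, ncol = 3)
    founders <- init_founders(config)
    if (config$generations == 0L) {
      traj[1, ] <- c(mean(founders$q), mean(founders$s), NA_real_)
    } else {
      for (g in seq_len(config$generations)) {
        cells <- grow_groups(founders, config)
        links <- if (config$s_locked_at_zero || all(cells$s == 0)) {
          tibble::tibble(group = integer(), receiver = integer(),
                         sender = integer())
        } else {
          build_links(cells, config)
        }
        cells <- resolve_phenotypes(cells, links, config)
        cells <- group_fecundities(cells, config)
        traj[g, ] <- c(mean(founders$q), mean(founders$s),
                       mean(cells$P[!duplicated(cells$group)]))
        founders <- next_generation(cells, config)
      }
    }
  }
  out <- tibble::tibble(
    generation = if (config$generations == 0L) 0L else seq_len(config$generations),
    mean_q = traj[, 1], mean_s = traj[, 2], mean_P = traj[, 3]
  )
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("dol_trajectory", class(out))
  out
}

# Deterministic per-replicate seed from a master seed: replicate i's seed does
# not depend on how many replicates are run (counter-based stream splitting).
derive_seed <- function(master_seed, i) {
  as.integer((as.double(master_seed) + as.double(i) * 1000003) %% 2147483629)
}

#' Trailing-window summary of a trajectory
#'
#' Means of `mean_q`, `mean_s`, `mean_P` over the last `window` fraction of
#' generations (at least one generation).
#'
#' @param traj A `dol_trajectory` tibble.
#' @param window Trailing fraction in `(0, 1]`.
#' @return A one-row tibble with `mean_q`, `mean_s`, `mean_P`.
#' @export
window_summary <- function(traj, window = 0.1) {
  k <- max(1L, floor(window * nrow(traj)))
  tail_rows <- traj[seq(nrow(traj) - k + 1L, nrow(traj)), ]
  tibble::tibble(
    mean_q = mean(tail_rows$mean_q),
    mean_s = mean(tail_rows$mean_s),
    mean_P = mean(tail_rows$mean_P)
  )
}

#' Run a replicated evolutionary experiment
#'
#' Runs `config$replicates` independent replicates, with each replicate's seed
#' derived deterministically from `seed` (replicate `i` always gets the same
#' stream, regardless of how many replicates are requested). Each replicate is
#' summarized by the trailing-window means of `q`, `s` and `P`
#' ([window_summary()] with `config$record_fraction`), and the across-replicate
#' mean and standard error of each trait are reported.
#'
#' @param config A [sim_config()] object.
#' @param seed Master seed.
#' @param engine Simulation engine, as in [run_replicate()].
#' @param keep_trajectories If `TRUE`, the full per-generation trajectories
#'   are kept in the result (memory permitting).
#' @return An object of class `dol_experiment`: a list with `replicates` (one
#'   row per replicate: `replicate`, `seed`, `mean_q`, `mean_s`, `mean_P`),
#'   `summary` (one row per trait: `trait`, `mean`, `se`), `config`, `seed`,
#'   and optionally `trajectories`.
#' @export
run_experiment <- function(config, seed = 1, engine = c("cpp", "r"),
                           keep_trajectories = FALSE) {
  stopifnot(inherits(config, "dol_sim_config"))
  engine <- match.arg(engine)
  reps <- seq_len(config$replicates)
  trajs <- purrr::map(reps, function(i) {
    run_replicate(config, derive_seed(seed, i), engine = engine)
  })
  replicates <- purrr::imap(trajs, function(tr, i) {
    dplyr::bind_cols(
      tibble::tibble(replicate = i, seed = derive_seed(seed, i)),
      window_summary(tr, config$record_fraction)
    )
  }) |> dplyr::bind_rows()
  summary <- replicates |>
    tidyr::pivot_longer(c("mean_q", "mean_s", "mean_P"),
                        names_to = "trait", values_to = "value") |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  out <- list(replicates = replicates, summary = summary,
              config = config, seed = seed)
  if (keep_trajectories) out$trajectories <- trajs
  class(out) <- "dol_experiment"
  out
}

#' @export
print.dol_experiment <- function(x, ...) {
  cat(sprintf("<dol_experiment> %d replicate(s), master seed %d\n",
              nrow(x$replicates), x$seed))
  print(x$summary)
  invisible(x)
}

#' Compare across-replicate variability of coordination and helping
#'
#' Computes the across-replicate variances of the trailing-window means of the
#' coordination level `s` and the helper proportion `P`, their ratio, and a
#' one-sided variance-ratio (F) p-value for the hypothesis that the
#' coordination level varies more across runs than the helper proportion
#' (weaker stabilizing selection on `s` predicts exactly this). The function
#' reports; it never asserts. A zero variance in the denominator (e.g.
#' identical replicates) is flagged as degenerate.
#'
#' @param trajectories A list of `dol_trajectory` tibbles (>= 2).
#' @param window Trailing fraction of generations summarized per replicate.
#' @return A one-row tibble: `n_replicates`, `var_s`, `var_P`, `ratio`, `df1`,
#'   `df2`, `p_value`, `degenerate`.
#' @export
variability_test <- function(trajectories, window = 0.1) {
  if (length(trajectories) < 2) {
    rlang::abort("Need at least two trajectories to compare variability.")
  }
  sums <- purrr::map(trajectories, window_summary, window = window) |>
    dplyr::bind_rows()
  var_s <- stats::var(sums$mean_s)
  var_P <- stats::var(sums$mean_P)
  df <- length(trajectories) - 1L
  degenerate <- !is.finite(var_P) || var_P == 0
  ratio <- if (degenerate) NA_real_ else var_s / var_P
  p <- if (degenerate) NA_real_ else stats::pf(ratio, df, df, lower.tail = FALSE)
  tibble::tibble(
    n_replicates = length(trajectories),
    var_s = var_s, var_P = var_P, ratio = ratio,
    df1 = df, df2 = df, p_value = p, degenerate = degenerate
  )
}

#' Simulation--theory bridge for the fully random control
#'
#' With the coordination level locked at 0 the simulator reduces to the
#' analytical random-specialization game, so the evolved mean target
#' proportion should settle at the closed-form ESS `q_FR*`. This report puts
#' the analytical prediction next to the simulated trailing-window mean and
#' their absolute deviation.
#'
#' @param params A [dol_params()] object (the game parameters of the run).
#' @param sim_summary Either a `dol_experiment` or any data frame with a
#'   `mean_q` column of per-replicate summaries.
#' @return A one-row tibble: `l`, `m`, `epsilon`, `q_fr_star`, `mean_q_sim`,
#'   `deviation` (= `abs(q_fr_star - mean_q_sim)`).
#' @export
bridge_report <- function(params, sim_summary) {
  stopifnot(inherits(params, "dol_params"))
  reps <- if (inherits(sim_summary, "dol_experiment")) {
    sim_summary$replicates
  } else {
    sim_summary
  }
  q_star <- ess_random_closed(params)$q_star
  mean_q_sim <- mean(reps$mean_q)
  tibble::tibble(
    l = params$l, m = params$m, epsilon = params$epsilon,
    q_fr_star = q_star, mean_q_sim = mean_q_sim,
    deviation = abs(q_star - mean_q_sim)
  )
}
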