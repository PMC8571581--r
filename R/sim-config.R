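#' Configuration for the individual-based simulation
#'
#' Collects the game parameters and the run-control settings of the
#' individual-based model in which the target helper proportion `q` and the
#' coordination level `s` coevolve. Defaults follow the full-scale study
#' conditions: populations of about `10^4` cells, `10^5` generations, 10
#' replicates, per-trait mutation probability 0.01 with Normal(0, 0.1) steps
#' clamped to `[0, 1]`, and summaries over the trailing 10% of generations.
#' The number of groups is derived as `floor(target_pop_size / (l * m))`, so
#' the realized population size is the nearest multiple of the group size not
#' exceeding the target.
#'
#' @param params A [dol_params()] object (`l`, `m`, `epsilon`, `theta`).
#' @param target_pop_size Desired number of cells per generation; the realized
#'   size is `n_groups * l * m` with `n_groups = floor(target_pop_size / (l*m))`.
#' @param generations Number of generations to simulate.
#' @param p_mut Per-trait mutation probability applied to each new founder.
#' @param mut_sd Standard deviation of the Normal mutation step.
#' @param replicates Number of independent replicate runs in
#'   [run_experiment()].
#' @param record_fraction Trailing fraction of generations averaged for
#'   summaries (e.g. 0.1 keeps the last 10%).
#' @param s_locked_at_zero If `TRUE`, the coordination level is held at 0 so
#'   only `q` evolves (the fully random control scenario).
#' @param coordination_scope `"whole_group"` (a cell may link to any group
#'   member) or `"own_lineage"` (links only to clone-mates).
#' @param cost_shape Shape of [coordination_cost()] in `s`: `"decelerating"`
#'   (default), `"linear"`, or `"accelerating"`.
#' @param init_q,init_s Initial trait values of every founder. The defaults
#'   (`q = 0.5`, `s = 0`) start the population uncoordinated so that any
#'   coordination must evolve de novo.
#' @param resolution_passes Number of full passes of the sequential
#'   phenotype-resolution sweep (default 1; see [resolve_phenotypes()]).
#' @return An object of class `dol_sim_config` (a list), with derived element
#'   `n_groups`.
#' @examples
#' cfg <- sim_config(dol_params(1, 20, epsilon = 1), target_pop_size = 2000,
#'                   generations = 100)
#' cfg$n_groups # 100
#' @export
sim_config <- function(params,
                       target_pop_size = 10000,
                       generations = 100000,
                       p_mut = 0.01,
                       mut_sd = 0.1,
                       replicates = 10,
                       record_fraction = 0.1,
                       s_locked_at_zero = FALSE,
                       coordination_scope = c("whole_group", "own_lineage"),
                       cost_shape = c("decelerating", "linear", "accelerating"),
                       init_q = 0.5,
                       init_s = 0,
                       resolution_passes = 1) {
  stopifnot(inherits(params, "dol_params"))
  coordination_scope <- match.arg(coordination_scope)
  cost_shape <- match.arg(cost_shape)
  n_groups <- floor(target_pop_size / (params$l * params$m))
  if (n_groups < 1) {
    rlang::abort("`target_pop_size` is smaller than one group (l * m cells).")
  }
  check_unit_interval(p_mut, "p_mut")
  check_unit_interval(record_fraction, "record_fraction")
  check_unit_interval(init_q, "init_q")
  check_unit_interval(init_s, "init_s")
  stopifnot(mut_sd >= 0, generations >= 0, replicates >= 1,
            resolution_passes >= 1)
  structure(
    list(
      params = params,
      target_pop_size = target_pop_size,
      n_groups = as.integer(n_groups),
      generations = as.integer(generations),
      p_mut = p_mut,
      mut_sd = mut_sd,
      replicates = as.integer(replicates),
      record_fraction = record_fraction,
      s_locked_at_zero = isTRUE(s_locked_at_zero),
      coordination_scope = coordination_scope,
      cost_shape = cost_shape,
      init_q = init_q,
      init_s = init_s,
      resolution_passes = as.integer(resolution_passes)
    ),
    class = "dol_sim_config"
  )
}

#' @export
print.dol_sim_config <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    paste0("<dol_sim_config> %d groups of n = %d (l = %d, m = %d), ",
           "epsilon = %g, theta = %g\n  generations = %d, p_mut = %g, ",
           "mut_sd = %g, replicates = %d, scope = %s, cost = %s%s\n"),
    x$n_groups, p$n, p$l, p$m, p$epsilon, p$theta,
    x$generations, x$p_mut, x$mut_sd, x$replicates,
    x$coordination_scope, x$cost_shape,
    if (x$s_locked_at_zero) ", s locked at 0" else ""
  ))
  invisible(x)
}

#' Metabolic cost of coordination
#'
#' The relative fecundity cost paid by a cell with coordination level `s`.
#' The default shape is `theta * (1 - exp(-5 s))`: concave (decelerating),
#' reflecting a high initial cost of building coordination machinery followed
#' by cheaper marginal increases, and approximately matching the analytical
#' model's flat cost `theta` at `s = 1`. The `"linear"` and `"accelerating"`
#' alternatives are anchored to the same endpoints, `cost(0) = 0` and
#' `cost(1) = theta * (1 - exp(-5))`, so the shapes differ only in curvature:
#' linear is `theta * (1 - exp(-5)) * s` and accelerating is
#' `theta * (1 - exp(-5)) * (exp(5 s) - 1) / (exp(5) - 1)`.
#'
#' @param s Coordination level(s) in `[0, 1]`.
#' @param theta Cost coefficient, >= 0.
#' @param shape `"decelerating"` (default), `"linear"`, or `"accelerating"`.
#' @return Numeric vector of costs in `[0, theta]`.
#' @examples
#' coordination_cost(1, theta = 0.025) # 0.0248316...
#' @export
coordination_cost <- function(s, theta,
                              shape = c("decelerating", "linear", "accelerating")) {
  shape <- match.arg(shape)
  check_unit_interval(s, "s")
  if (!is.numeric(theta) || anyNA(theta) || any(theta < 0)) {
    rlang::abort("`theta` must be nonnegative.")
  }
  top <- 1 - exp(-5)
  switch(shape,
    decelerating = theta * (1 - exp(-5 * s)),
    linear = theta * top * s,
    accelerating = theta * top * (exp(5 * s) - 1) / (exp(5) - 1)
  )
}
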