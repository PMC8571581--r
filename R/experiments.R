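#' Specify a reproducible experiment
#'
#' Describes one of the package's standard experiment layouts so it can be run
#' end-to-end by [run_spec()] and written as tidy TSV tables.
#'
#' * `"phase_figure"`: analytical invasion phase grids over essentiality and
#'   group size, one grid per value of `l`.
#' * `"heatmap_figure"`: simulated evolved coordination and helper levels over
#'   an essentiality-by-group-size grid at fixed `l`.
#' * `"relatedness_sweep"`: simulated evolved levels across values of `l`
#'   (i.e. across relatedness `1/l`) at fixed essentiality and group size.
#' * `"control_comparison"`: one parameter point run twice, with the
#'   coordination level free versus locked at 0.
#'
#' The `"desk"` preset (population about 2000 cells, 2e4 generations, 5
#' replicates) keeps full experiments tractable on a laptop; `"paper"` uses
#' the full-scale study conditions (about 1e4 cells, 1e5 generations, 10
#' replicates).
#'
#' @param kind One of `"phase_figure"`, `"heatmap_figure"`,
#'   `"relatedness_sweep"`, `"control_comparison"`.
#' @param l_values Numbers of founding lineages to sweep (default
#'   `c(1, 2, 4, 8)`).
#' @param epsilon Fixed essentiality for simulation experiments.
#' @param n Fixed group size for simulation experiments.
#' @param theta Coordination cost coefficient.
#' @param epsilon_axis,n_axis Grid axes for `"phase_figure"` and
#'   `"heatmap_figure"`.
#' @param mode Invasion mode for `"phase_figure"` (see [classify_region()]).
#' @param preset `"desk"` or `"paper"` simulation scale.
#' @param target_pop_size,generations,replicates Optional overrides of the
#'   preset's scale (useful for quick exploratory runs).
#' @param seed Master seed.
#' @param out_dir Output directory for TSV tables.
#' @return An object of class `dol_experiment_spec` (a list).
#' @export
experiment_spec <- function(kind = c("phase_figure", "heatmap_figure",
                                     "relatedness_sweep", "control_comparison"),
                            l_values = c(1, 2, 4, 8),
                            epsilon = 1, n = 24, theta = 0.025,
                            epsilon_axis = seq(0.05, 1, by = 0.05),
                            n_axis = NULL,
                            mode = c("resident_q", "mutant_optimal_q"),
                            preset = c("desk", "paper"),
                            target_pop_size = NULL,
                            generations = NULL,
                            replicates = NULL,
                            seed = 1,
                            out_dir = ".") {
  kind <- match.arg(kind)
  preset <- match.arg(preset)
  mode <- match.arg(mode)
  scale <- if (preset == "desk") {
    list(target_pop_size = 2000, generations = 20000L, replicates = 5L)
  } else {
    list(target_pop_size = 10000, generations = 100000L, replicates = 10L)
  }
  scale$target_pop_size <- target_pop_size %||% scale$target_pop_size
  scale$generations <- as.integer(generations %||% scale$generations)
  scale$replicates <- as.integer(replicates %||% scale$replicates)
  structure(
    list(kind = kind, l_values = l_values, epsilon = epsilon, n = n,
         theta = theta, epsilon_axis = epsilon_axis, n_axis = n_axis,
         mode = mode, preset = preset, scale = scale, seed = seed,
         out_dir = out_dir),
    class = "dol_experiment_spec"
  )
}

# tidy TSV with a single '#' header line echoing the provenance of the table
write_result_tsv <- function(tbl, path, header) {
  tbl <- dplyr::mutate(tbl, dplyr::across(dplyr::where(is.double),
                                          ~ signif(.x, 10)))
  writeLines(paste0("# ", header), path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

spec_header <- function(spec, extra = "") {
  paste0(
    "labordiv ", spec$kind, " preset=", spec$preset, " seed=", spec$seed,
    " theta=", spec$theta,
    " pop=", spec$scale$target_pop_size,
    " generations=", spec$scale$generations,
    " replicates=", spec$scale$replicates,
    if (nzchar(extra)) paste0(" ", extra) else ""
  )
}

#' Run an experiment specification
#'
#' Dispatches an [experiment_spec()] to the analytical or simulation layer,
#' writes one tidy TSV table per figure-analog into `spec$out_dir` (with a
#' `#` comment line echoing the full configuration and seed), and returns the
#' tables invisibly. Runs are idempotent given the seed: re-running a spec
#' reproduces the same tables byte for byte. If anything fails midway, the
#' partially written outputs are removed.
#'
#' @param spec A `dol_experiment_spec`.
#' @param engine Simulation engine, as in [run_replicate()].
#' @return (Invisibly) a named list of the tibbles written.
#' @export
run_spec <- function(spec, engine = c("cpp", "r")) {
  stopifnot(inherits(spec, "dol_experiment_spec"))
  engine <- match.arg(engine)
  dir.create(spec$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    rlang::abort(paste0("Experiment failed; partial outputs removed: ",
                        conditionMessage(e)))
  }
  tryCatch({
    out <- switch(spec$kind,
      phase_figure = run_phase_figure(spec, \(p, t) {
        written <<- c(written, p)
      }),
      heatmap_figure = run_heatmap_figure(spec, engine, \(p, t) {
        written <<- c(written, p)
      }),
      relatedness_sweep = run_relatedness_sweep(spec, engine, \(p, t) {
        written <<- c(written, p)
      }),
      control_comparison = run_control_comparison(spec, engine, \(p, t) {
        written <<- c(written, p)
      })
    )
    invisible(out)
  }, error = on_fail)
}

run_phase_figure <- function(spec, note) {
  n_axis <- spec$n_axis %||% seq(8, 160, by = 8)
  out <- list()
  for (l in spec$l_values) {
    pg <- phase_grid(l = l, theta = spec$theta,
                     epsilon_axis = spec$epsilon_axis,
                     n_axis = n_axis, mode = spec$mode)
    counts <- dplyr::count(dplyr::filter(pg, .data$valid), .data$region)
    message(sprintf("phase grid l = %d: %s", l,
                    paste0(counts$region, "=", counts$n, collapse = ", ")))
    path <- file.path(spec$out_dir, sprintf("phase_l%d.tsv", l))
    write_result_tsv(pg, path, spec_header(spec, sprintf("l=%d mode=%s",
                                                         l, spec$mode)))
    note(path, pg)
    out[[paste0("l", l)]] <- pg
  }
  out
}

run_heatmap_figure <- function(spec, engine, note) {
  l <- spec$l_values[1]
  n_axis <- spec$n_axis %||% (l * c(2, 5, 10, 20))
  cells <- tidyr::expand_grid(epsilon = spec$epsilon_axis, n = n_axis) |>
    dplyr::filter(.data$n %% l == 0)
  rows <- purrr::pmap(cells, function(epsilon, n) {
    cfg <- sim_config(dol_params(l, n %/% l, epsilon, spec$theta),
                      target_pop_size = spec$scale$target_pop_size,
                      generations = spec$scale$generations,
                      replicates = spec$scale$replicates)
    ex <- run_experiment(cfg, seed = spec$seed + round(1000 * epsilon) + n,
                         engine = engine)
    dplyr::bind_cols(tibble::tibble(l = l, n = n, epsilon = epsilon),
                     tidyr::pivot_wider(ex$summary, names_from = "trait",
                                        values_from = c("mean", "se")))
  })
  tbl <- dplyr::bind_rows(rows)
  path <- file.path(spec$out_dir, sprintf("heatmap_l%d.tsv", l))
  write_result_tsv(tbl, path, spec_header(spec, sprintf("l=%d", l)))
  note(path, tbl)
  list(heatmap = tbl)
}

run_relatedness_sweep <- function(spec, engine, note) {
  rows <- purrr::map(spec$l_values, function(l) {
    if (spec$n %% l != 0) {
      rlang::abort(sprintf("Group size n = %d is not divisible by l = %d.",
                           spec$n, l))
    }
    cfg <- sim_config(dol_params(l, spec$n %/% l, spec$epsilon, spec$theta),
                      target_pop_size = spec$scale$target_pop_size,
                      generations = spec$scale$generations,
                      replicates = spec$scale$replicates)
    ex <- run_experiment(cfg, seed = spec$seed + l, engine = engine)
    dplyr::bind_cols(
      tibble::tibble(l = l, relatedness = 1 / l, n = spec$n,
                     epsilon = spec$epsilon),
      tidyr::pivot_wider(ex$summary, names_from = "trait",
                         values_from = c("mean", "se"))
    )
  })
  tbl <- dplyr::bind_rows(rows)
  path <- file.path(spec$out_dir, "relatedness_sweep.tsv")
  write_result_tsv(tbl, path, spec_header(spec))
  note(path, tbl)
  list(relatedness_sweep = tbl)
}

run_control_comparison <- function(spec, engine, note) {
  l <- spec$l_values[1]
  if (spec$n %% l != 0) {
    rlang::abort(sprintf("Group size n = %d is not divisible by l = %d.",
                         spec$n, l))
  }
  one <- function(locked) {
    cfg <- sim_config(dol_params(l, spec$n %/% l, spec$epsilon, spec$theta),
                      target_pop_size = spec$scale$target_pop_size,
                      generations = spec$scale$generations,
                      replicates = spec$scale$replicates,
                      s_locked_at_zero = locked)
    ex <- run_experiment(cfg, seed = spec$seed, engine = engine)
    dplyr::bind_cols(
      tibble::tibble(l = l, n = spec$n, epsilon = spec$epsilon,
                     scenario = if (locked) "s_locked" else "s_free"),
      tidyr::pivot_wider(ex$summary, names_from = "trait",
                         values_from = c("mean", "se"))
    )
  }
  tbl <- dplyr::bind_rows(one(TRUE), one(FALSE))
  path <- file.path(spec$out_dir, "control_comparison.tsv")
  write_result_tsv(tbl, path, spec_header(spec))
  note(path, tbl)
  list(control_comparison = tbl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
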