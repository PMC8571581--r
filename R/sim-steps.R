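# R reference implementations of one generation's steps, operating on tidy
# tables. They define the model's semantics and are what the test suite
# exercises; run_replicate() uses a compiled transcription of the same steps
# by default (engine = "cpp") for long runs.

#' Initial founder population
#'
#' @param config A [sim_config()] object.
#' @return A tibble with one row per founder: `group`, `founder` (index within
#'   group), `q`, `s` (all founders start at `init_q`, `init_s`).
#' @export
init_founders <- function(config) {
  stopifnot(inherits(config, "dol_sim_config"))
  l <- config$params$l
  tidyr::expand_grid(group = seq_len(config$n_groups), founder = seq_len(l)) |>
    dplyr::mutate(
      q = config$init_q,
      s = if (config$s_locked_at_zero) 0 else config$init_s
    )
}

#' Grow founders into mature groups
#'
#' Each founder spawns a lineage of `m` cells that inherit its genotype, so a
#' group holds `n = l * m` cells. With one founder per group (`l = 1`) groups
#' are clonal; with `l > 1` the whole-group relatedness (probability that two
#' cells drawn with replacement share a founder) is `1/l`.
#'
#' @param founders A founder tibble as from [init_founders()] or
#'   [next_generation()]; must contain `n_groups * l` rows.
#' @param config A [sim_config()] object.
#' @return A cell tibble: `group`, `lineage`, `cell` (index within group),
#'   `q`, `s`.
#' @export
grow_groups <- function(founders, config) {
  stopifnot(inherits(config, "dol_sim_config"))
  l <- config$params$l; m <- config$params$m
  if (nrow(founders) != config$n_groups * l) {
    rlang::abort(sprintf("Expected %d founders, got %d.",
                         config$n_groups * l, nrow(founders)))
  }
  founders |>
    dplyr::rename(lineage = "founder") |>
    tidyr::uncount(m) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(cell = dplyr::row_number(), .after = "lineage") |>
    dplyr::ungroup()
}

#' Build the stochastic coordination network of each group
#'
#' Every cell (the receiver) independently establishes a one-way link to each
#' other cell in scope with probability equal to the receiver's own
#' coordination level `s`; a link lets the receiver observe that neighbor's
#' intended phenotype during resolution. Scope is the whole group by default,
#' or only clone-mates when `coordination_scope = "own_lineage"`. There are no
#' self-links.
#'
#' @param cells A cell tibble from [grow_groups()].
#' @param config A [sim_config()] object.
#' @return An edge tibble: `group`, `receiver`, `sender` (cell indices within
#'   group).
#' @export
build_links <- function(cells, config) {
  stopifnot(inherits(config, "dol_sim_config"))
  own_lineage <- config$coordination_scope == "own_lineage"
  pairs <- cells |>
    dplyr::select("group", receiver = "cell", receiver_lineage = "lineage",
                  "s") |>
    dplyr::inner_join(
      dplyr::select(cells, "group", sender = "cell",
                    sender_lineage = "lineage"),
      by = "group", relationship = "many-to-many"
    ) |>
    dplyr::filter(.data$receiver != .data$sender)
  if (own_lineage) {
    pairs <- dplyr::filter(pairs, .data$receiver_lineage == .data$sender_lineage)
  }
  pairs |>
    dplyr::filter(stats::runif(dplyr::n()) < .data$s) |>
    dplyr::select("group", "receiver", "sender")
}

#' The phenotype-switching rule
#'
#' A sampled cell compares the proportion of intended helpers it observes
#' among its linked neighbors with its own target proportion `q`: if the
#' observed fraction falls short of the target it plans to become a helper,
#' otherwise (including an exact tie) a reproductive. The tie-break keeps
#' `q = 0` free of helpers under full coordination.
#'
#' @param observed_frac Fraction of intended helpers among observed senders.
#' @param q The deciding cell's target helper proportion.
#' @return Logical: `TRUE` if the cell intends to become a helper.
#' @export
helper_decision <- function(observed_frac, q) {
  observed_frac < q
}

#' Resolve intended phenotypes by sequential sampling
#'
#' All cells start as intended reproductives. The group's cells are then
#' visited once each, in a uniformly random order (`resolution_passes` full
#' sweeps; default one). A visited cell that observes at least one sender
#' applies [helper_decision()] to the senders' *current* intended phenotypes
#' (sequential, not synchronous, updating). A cell with no in-links -- always
#' the case when its `s = 0` -- falls back to random specialization and
#' becomes a helper with probability `q`. After the final sweep the intended
#' phenotypes are the realized ones.
#'
#' @param cells A cell tibble from [grow_groups()].
#' @param links An edge tibble from [build_links()].
#' @param config A [sim_config()] object.
#' @return `cells` with a logical `helper` column appended.
#' @export
resolve_phenotypes <- function(cells, links, config) {
  stopifnot(inherits(config, "dol_sim_config"))
  n <- config$params$n
  if (nrow(links) == 0) {
    # no cell observes anyone: every cell randomizes independently
    cells$helper <- stats::runif(nrow(cells)) < cells$q
    return(cells)
  }
  out <- cells |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(gcells, key) {
      glinks <- links[links$group == key$group, , drop = FALSE]
      senders_of <- split(glinks$sender, factor(glinks$receiver, levels = 1:n))
      helper <- rep(FALSE, n)
      for (pass in seq_len(config$resolution_passes)) {
        for (i in sample.int(n)) {
          sx <- senders_of[[i]]
          helper[i] <- if (length(sx) == 0) {
            stats::runif(1) < gcells$q[i]
          } else {
            helper_decision(mean(helper[sx]), gcells$q[i])
          }
        }
      }
      gcells$helper <- helper
      gcells
    }) |>
    dplyr::ungroup()
  out
}

#' Per-cell fecundity from realized phenotypes
#'
#' A helper's fecundity is 0. A reproductive's fecundity is
#' `(1 - cost(s)) * (1 - epsilon + epsilon * P)` where `P` is the realized
#' helper proportion of its whole group (all `n` cells, across lineages) and
#' `cost(s)` is [coordination_cost()] at the cell's own coordination level.
#'
#' @param cells A cell tibble with a `helper` column, from
#'   [resolve_phenotypes()].
#' @param config A [sim_config()] object.
#' @return `cells` with `P` (group helper proportion) and `fecundity`
#'   appended.
#' @export
group_fecundities <- function(cells, config) {
  stopifnot(inherits(config, "dol_sim_config"))
  eps <- config$params$epsilon
  cells |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(P = mean(.data$helper)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      fecundity = (1 - coordination_cost(.data$s, config$params$theta,
                                         config$cost_shape)) *
        (1 - .data$helper) * (1 - eps + eps * .data$P)
    )
}

#' Apply mutation to founder genotypes
#'
#' Each trait of each founder mutates independently with probability `p_mut`;
#' a mutation perturbs the parental value by a Normal(0, `mut_sd`) deviate and
#' the result is clamped to `[0, 1]`. When `s_locked_at_zero` the coordination
#' level never mutates (the fully random control).
#'
#' @param founders A founder tibble (`group`, `founder`, `q`, `s`).
#' @param config A [sim_config()] object.
#' @return The founder tibble with mutated `q`, `s`.
#' @export
mutate_genotypes <- function(founders, config) {
  stopifnot(inherits(config, "dol_sim_config"))
  k <- nrow(founders)
  hit_q <- stats::runif(k) < config$p_mut
  founders$q <- clamp01(founders$q +
                          ifelse(hit_q, stats::rnorm(k, 0, config$mut_sd), 0))
  if (!config$s_locked_at_zero) {
    hit_s <- stats::runif(k) < config$p_mut
    founders$s <- clamp01(founders$s +
                            ifelse(hit_s, stats::rnorm(k, 0, config$mut_sd), 0))
  }
  founders
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Global competition: sample the next generation's founders
#'
#' All offspring disperse globally: the `n_groups * l` founders of the next
#' generation are drawn by multinomial sampling over every cell in the
#' population with probabilities proportional to individual fecundity
#' (helpers, with fecundity 0, are never sampled). Each founder inherits its
#' parent's genotype and is then passed through [mutate_genotypes()].
#'
#' @param cells A cell tibble with `fecundity`, from [group_fecundities()].
#' @param config A [sim_config()] object.
#' @return A founder tibble for the next generation.
#' @export
next_generation <- function(cells, config) {
  stopifnot(inherits(config, "dol_sim_config"))
  total <- sum(cells$fecundity)
  if (total <= 0) {
    rlang::abort(paste(
      "Total fecundity is zero (every cell became a helper).",
      "Check epsilon/q settings."
    ))
  }
  k <- config$n_groups * config$params$l
  idx <- sample.int(nrow(cells), size = k, replace = TRUE,
                    prob = cells$fecundity)
  founders <- tibble::tibble(
    group = rep(seq_len(config$n_groups), each = config$params$l),
    founder = rep(seq_len(config$params$l), times = config$n_groups),
    q = cells$q[idx],
    s = if (config$s_locked_at_zero) 0 else cells$s[idx]
  )
  mutate_genotypes(founders, config)
}
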