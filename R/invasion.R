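# Both invasion conditions reduce to the sign of the same quantity,
#   D(q) = theta*l*m - epsilon * (theta*l*m*(1 - q) + q),
# since w_FR(q,q) - w_FC(q,q) = (1 - q) * D(q) / (l m). Each predicate computes
# D from the closed inequality AND from the fitness functions and requires the
# two routes to agree.
#
# Boundary convention: an exact fitness tie (|D| <= tol) resolves in favor of
# random specialization -- the tied random mutant counts as able to invade, the
# tied coordinated mutant does not. Ties occur only on the boundary curve
# epsilon = theta*l*m / (theta*l*m*(1-q*) + q*) (e.g. theta*l*m = 1 with
# epsilon = 1); this convention makes "theta*l*m >= 1 implies random always
# invades and is never invaded" hold with equality included.
invasion_margin <- function(params, q_res) {
  l <- params$l; m <- params$m; eps <- params$epsilon; th <- params$theta
  closed <- th * l * m - eps * (th * l * m * (1 - q_res) + q_res)
  diff <- fitness_random(q_res, q_res, params) -
    fitness_coordinated(q_res, q_res, params)
  direct <- if (q_res < 1) diff * l * m / (1 - q_res) else closed
  list(closed = closed, direct = direct)
}

check_route_agreement <- function(margin, tol) {
  if (abs(margin$closed - margin$direct) > 1e6 * tol) {
    rlang::abort(
      "Internal consistency failure: closed invasion inequality and direct fitness comparison disagree."
    )
  }
}

#' Can a fully random mutant invade a coordinated resident population?
#'
#' Tests whether a rare fully random specializer, playing the resident's own
#' target helper proportion `q_res`, has fitness at least that of the fully
#' coordinated residents at their equilibrium. The closed condition is
#' \deqn{\epsilon \le \frac{\theta l m}{\theta l m (1 - q_{res}) + q_{res}}}
#' and it is evaluated both in this closed form and as a direct comparison of
#' [fitness_random()] with [fitness_coordinated()]; the two routes must agree.
#' Exact fitness ties count as invasion by the random mutant (see Details).
#'
#' @details When the coordination cost is large enough that
#' `theta * l * m >= 1`, the condition holds for every `epsilon` in `(0, 1]`,
#' so random specialization can always invade; the boundary product
#' `theta * l * m = 1` produces an exact fitness tie at `epsilon = 1`, which
#' this predicate resolves toward random specialization (costly coordination
#' cannot be maintained by selection when it confers no fitness advantage).
#' A resident with `q_res = 0` has no division of labor to disrupt and returns
#' `FALSE`.
#'
#' @param params A [dol_params()] object.
#' @param q_res Resident target helper proportion; defaults to the coordinated
#'   ESS [ess_coordinated_closed()].
#' @param tol Tolerance within which a fitness difference counts as a tie.
#' @return Logical scalar.
#' @export
random_invades_coordinated <- function(params, q_res = NULL, tol = 1e-9) {
  stopifnot(inherits(params, "dol_params"))
  if (is.null(q_res)) q_res <- ess_coordinated_closed(params)$q_star
  check_unit_interval(q_res, "q_res")
  if (q_res == 0) return(FALSE)
  mar <- invasion_margin(params, q_res)
  check_route_agreement(mar, tol)
  mar$closed >= -tol  # tie -> random invades
}

#' Can a fully coordinated mutant invade a random resident population?
#'
#' Tests whether a rare fully coordinated specializer, playing the resident's
#' own target helper proportion `q_res`, has strictly higher fitness than the
#' fully random residents at their equilibrium. The closed condition is
#' \deqn{\epsilon > \frac{\theta l m}{\theta l m (1 - q_{res}) + q_{res}}}
#' evaluated both in closed form and as a direct fitness comparison (the
#' routes must agree). Exact fitness ties do **not** count as invasion by the
#' coordinated mutant, the mirror of the tie convention in
#' [random_invades_coordinated()]. A resident with `q_res = 0` returns
#' `FALSE`.
#'
#' @param params A [dol_params()] object.
#' @param q_res Resident target helper proportion; defaults to the random ESS
#'   [ess_random_closed()].
#' @param tol Tolerance within which a fitness difference counts as a tie.
#' @return Logical scalar.
#' @export
coordinated_invades_random <- function(params, q_res = NULL, tol = 1e-9) {
  stopifnot(inherits(params, "dol_params"))
  if (is.null(q_res)) q_res <- ess_random_closed(params)$q_star
  check_unit_interval(q_res, "q_res")
  if (q_res == 0) return(FALSE)
  mar <- invasion_margin(params, q_res)
  check_route_agreement(mar, tol)
  -mar$closed > tol  # tie -> coordinated does not invade
}

region_label <- function(q_fr, q_fc, rand_inv, coord_inv) {
  if (q_fr == 0 && q_fc == 0) return("no_division_of_labor")
  if (rand_inv && coord_inv) return("mutual_invasion")
  if (rand_inv) return("random_wins")
  if (coord_inv) return("coordinated_wins")
  "neither_invades"
}

#' Classify the invasion outcome at one parameter combination
#'
#' Runs the two-step invasion analysis at a single `(l, m, epsilon, theta)`:
#' first the ESS target helper proportion of each mechanism when resident,
#' then whether each mechanism's rare mutant can invade the other's resident
#' equilibrium.
#'
#' In `mode = "resident_q"` the mutant plays the resident's ESS proportion, so
#' the mechanisms differ only in how helpers are produced; mutual invasion is
#' impossible in this mode. In `mode = "mutant_optimal_q"` each mutant plays
#' its own best response ([best_response()]) to the resident equilibrium,
#' which can open a region where each mechanism invades the other
#' (`mutual_invasion`). A mechanism whose resident ESS is 0 supports no
#' division of labor and is not treated as invadable; when both ESS are 0 the
#' region is `no_division_of_labor`.
#'
#' @param params A [dol_params()] object.
#' @param mode `"resident_q"` or `"mutant_optimal_q"`.
#' @param tol Tie tolerance passed to the invasion predicates.
#' @return A one-row tibble with columns `l`, `m`, `n`, `epsilon`, `theta`,
#'   `mode`, `q_fr`, `q_fc`, `random_invades`, `coordinated_invades`,
#'   `region`.
#' @examples
#' classify_region(dol_params(1, 10, epsilon = 1, theta = 0.025))
#' @export
classify_region <- function(params, mode = c("resident_q", "mutant_optimal_q"),
                            tol = 1e-9) {
  stopifnot(inherits(params, "dol_params"))
  mode <- match.arg(mode)
  q_fr <- ess_random_closed(params)$q_star
  q_fc <- ess_coordinated_closed(params)$q_star

  if (mode == "resident_q") {
    rand_inv <- random_invades_coordinated(params, q_fc, tol = tol)
    coord_inv <- coordinated_invades_random(params, q_fr, tol = tol)
  } else {
    rand_inv <- if (q_fc > 0) {
      q_mut <- best_response(q_fc, params, "random")
      fitness_random(q_mut, q_fc, params) -
        fitness_coordinated(q_fc, q_fc, params) >= -tol
    } else FALSE
    coord_inv <- if (q_fr > 0) {
      q_mut <- best_response(q_fr, params, "coordinated")
      fitness_coordinated(q_mut, q_fr, params) -
        fitness_random(q_fr, q_fr, params) > tol
    } else FALSE
  }

  tibble::tibble(
    l = params$l, m = params$m, n = params$n,
    epsilon = params$epsilon, theta = params$theta, mode = mode,
    q_fr = q_fr, q_fc = q_fc,
    random_invades = rand_inv, coordinated_invades = coord_inv,
    region = region_label(q_fr, q_fc, rand_inv, coord_inv)
  )
}

#' Invasion phase diagram over essentiality and group size
#'
#' Evaluates [classify_region()] on the Cartesian grid of `epsilon_axis` and
#' `n_axis` at fixed `l` and `theta`, the layout of the model's phase
#' diagrams (essentiality on one axis, group size `n = l m` on the other).
#' Grid cells whose `n` is not divisible by `l` cannot be realized by integer
#' lineages; they are kept in the table with `valid = FALSE` and `NA` results
#' rather than silently rounded.
#'
#' @param l Number of founding lineages.
#' @param theta Coordination cost coefficient (default 0.025).
#' @param epsilon_axis Numeric vector of essentiality values in `[0, 1]`.
#' @param n_axis Integer vector of group sizes.
#' @param mode Invasion mode, as in [classify_region()].
#' @return A tibble of class `dol_phase_grid`, one row per `(epsilon, n)`
#'   cell, with the columns of [classify_region()] plus `valid`.
#' @examples
#' pg <- phase_grid(l = 1, epsilon_axis = seq(0.1, 1, 0.1), n_axis = c(5, 10, 20))
#' dplyr::count(pg, region)
#' @export
phase_grid <- function(l, theta = 0.025,
                       epsilon_axis = seq(0.05, 1, by = 0.05),
                       n_axis = seq(5, 100, by = 5),
                       mode = c("resident_q", "mutant_optimal_q")) {
  mode <- match.arg(mode)
  if (length(epsilon_axis) == 0 || length(n_axis) == 0) {
    rlang::abort("`epsilon_axis` and `n_axis` must be non-empty.")
  }
  grid <- tidyr::expand_grid(epsilon = epsilon_axis, n = as.integer(n_axis))
  rows <- purrr::pmap(grid, function(epsilon, n) {
    if (n %% l != 0L) {
      return(tibble::tibble(
        l = as.integer(l), m = NA_integer_, n = n, epsilon = epsilon,
        theta = theta, mode = mode, q_fr = NA_real_, q_fc = NA_real_,
        random_invades = NA, coordinated_invades = NA,
        region = NA_character_, valid = FALSE
      ))
    }
    cell <- classify_region(dol_params(l, n %/% l, epsilon, theta), mode)
    cell$valid <- TRUE
    cell
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dol_phase_grid", class(out))
  out
}
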