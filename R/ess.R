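# Both fitness functions are, up to a positive constant, (1 - q)(A + B q) with
#   A = 1 - eps + eps (l-1) Q / l   (help received from the rest of the group)
#   B = eps (m-1) / (l m)           random mechanism
#   B = eps / l                     coordinated mechanism
# so each is a concave quadratic in q whenever B > 0 and the best response is
# the clipped vertex (B - A) / (2 B).
quad_coefs <- function(mechanism, Q, params) {
  l <- params$l; m <- params$m; eps <- params$epsilon
  A <- 1 - eps + eps * (l - 1) * Q / l
  B <- if (mechanism == "random") eps * (m - 1) / (l * m) else eps / l
  list(A = A, B = B)
}

#' Best-response target helper proportion to a resident population
#'
#' The value of `q` in `[0, 1]` that maximizes the focal founder's expected
#' fitness ([fitness_random()] or [fitness_coordinated()]) when the other
#' founders play `Q`. Both fitness functions are concave quadratics in `q`
#' (their second derivative `-2B` is verified to be `<= 0`), so the maximizer
#' is the stationary point clipped to the unit interval. When the quadratic
#' degenerates (`epsilon = 0`, or `m = 1` for the random mechanism) fitness is
#' nonincreasing in `q` and the best response is 0.
#'
#' @param Q Resident target helper proportion, in `[0, 1]`. Vectorized.
#' @param params A [dol_params()] object.
#' @param mechanism `"random"` or `"coordinated"`.
#' @return Best-response proportion(s) in `[0, 1]`.
#' @export
best_response <- function(Q, params, mechanism = c("random", "coordinated")) {
  stopifnot(inherits(params, "dol_params"))
  mechanism <- match.arg(mechanism)
  check_unit_interval(Q, "Q")
  co <- quad_coefs(mechanism, Q, params)
  out <- ifelse(co$B > 0, pmin(1, pmax(0, (co$B - co$A) / (2 * co$B))), 0)
  # degenerate flat case (A = B = 0 can only happen with eps = 0): stay at 0
  out[co$B <= 0] <- 0
  out
}

ess_result <- function(mechanism, q_star, method) {
  tibble::tibble(
    mechanism = mechanism,
    q_star = q_star,
    interior = q_star > 0,
    method = method
  )
}

#' ESS target helper proportion by numeric best-response fixed point
#'
#' Finds the symmetric equilibrium `q*` with `best_response(q*) = q*` by
#' root-finding on `g(q) = best_response(q) - q`, which is strictly decreasing
#' on `[0, 1]` (the unclipped best response is nonincreasing in the resident
#' `Q`), so the fixed point is unique. This is the ground-truth oracle for the
#' closed forms in [ess_random_closed()] and [ess_coordinated_closed()].
#'
#' @param params A [dol_params()] object.
#' @param mechanism `"random"` or `"coordinated"`.
#' @param tol Convergence tolerance on `q` (default `1e-12`).
#' @return A one-row tibble with columns `mechanism`, `q_star`, `interior`,
#'   `method`.
#' @export
ess_numeric <- function(params, mechanism = c("random", "coordinated"),
                        tol = 1e-12) {
  stopifnot(inherits(params, "dol_params"))
  mechanism <- match.arg(mechanism)
  g <- function(q) best_response(q, params, mechanism) - q
  q_star <- if (g(0) <= 0) {
    0
  } else if (g(1) >= 0) {
    1  # cannot occur: best_response < 1 always; kept as a guard
  } else {
    stats::uniroot(g, c(0, 1), tol = tol)$root
  }
  ess_result(mechanism, q_star, "numeric_best_response")
}

#' Closed-form ESS for fully random specialization
#'
#' The evolutionarily stable target helper proportion in a population of fully
#' random specializers:
#' \deqn{q_{FR}^* = \frac{m - 1 - l m (1-\epsilon)/\epsilon}{l m + m - 2}}
#' when `epsilon` exceeds the threshold `lm / (lm + m - 1)`, and 0 otherwise
#' (at the threshold the interior formula evaluates to exactly 0, so the
#' boundary is assigned to the no-help branch). The degenerate case
#' `l = m = 1` (a lone cell cannot profit from becoming a sterile helper) is
#' caught by the threshold, which equals 1 whenever `m = 1`.
#'
#' More essential cooperation (higher `epsilon`), smaller lineages (smaller
#' `m`) and fewer lineages (smaller `l`) all increase `q_FR*`. Agreement with
#' the numeric fixed point of [ess_numeric()] is enforced in the test suite at
#' 1e-8.
#'
#' @param params A [dol_params()] object.
#' @return A one-row tibble with columns `mechanism`, `q_star`, `interior`,
#'   `method`.
#' @export
ess_random_closed <- function(params) {
  stopifnot(inherits(params, "dol_params"))
  l <- params$l; m <- params$m; eps <- params$epsilon
  q_star <- 0
  if (!(l == 1L && m == 1L) && eps > 0 && eps > (l * m) / (l * m + m - 1)) {
    q_star <- (m - 1 - l * m * (1 - eps) / eps) / (l * m + m - 2)
  }
  ess_result("random", q_star, "closed_form")
}

#' Closed-form ESS for fully coordinated specialization
#'
#' The evolutionarily stable target helper proportion in a population of fully
#' coordinated specializers:
#' \deqn{q_{FC}^* = \frac{1 - l (1-\epsilon)/\epsilon}{l + 1}}
#' when `epsilon` exceeds the threshold `l / (l + 1)`, and 0 otherwise.
#' Because coordination realizes the target exactly, `q_FC*` is independent of
#' the lineage size `m` and of the cost `theta`, and satisfies
#' `q_FC* >= q_FR*` whenever either is interior.
#'
#' @inheritParams ess_random_closed
#' @return A one-row tibble with columns `mechanism`, `q_star`, `interior`,
#'   `method`.
#' @export
ess_coordinated_closed <- function(params) {
  stopifnot(inherits(params, "dol_params"))
  l <- params$l; eps <- params$epsilon
  q_star <- 0
  if (eps > 0 && eps > l / (l + 1)) {
    q_star <- (1 - l * (1 - eps) / eps) / (l + 1)
  }
  ess_result("coordinated", q_star, "closed_form")
}

#' ESS helper proportions for both mechanisms
#'
#' Convenience wrapper returning the closed-form ESS of both mechanisms as a
#' two-row tibble, one row per mechanism.
#'
#' @inheritParams ess_random_closed
#' @param method `"closed_form"` (default) or `"numeric"`.
#' @return A tibble with columns `mechanism`, `q_star`, `interior`, `method`.
#' @examples
#' ess_helper_proportions(dol_params(1, 10, epsilon = 1))
#' @export
ess_helper_proportions <- function(params, method = c("closed_form", "numeric")) {
  method <- match.arg(method)
  if (method == "closed_form") {
    dplyr::bind_rows(ess_random_closed(params), ess_coordinated_closed(params))
  } else {
    dplyr::bind_rows(ess_numeric(params, "random"),
                     ess_numeric(params, "coordinated"))
  }
}
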