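#' Expected fitness of a fully random specializer
#'
#' Expected fitness of a focal founder whose lineage randomizes phenotypes
#' independently (each cell becomes a helper with probability `q`) inside a
#' group whose other `l - 1` founders have target helper proportion `Q`:
#'
#' \deqn{w_{FR}(q, Q) = (1-q)\left(1-\epsilon + \epsilon q/l +
#'   \epsilon (l-1) Q / l - \epsilon q/(lm)\right)}
#'
#' The factor `1 - q` is the expected reproductive fraction of the focal
#' lineage; inside the parentheses are the baseline fecundity `1 - epsilon`,
#' the expected within- and across-lineage help, and the fecundity cost
#' `epsilon * q / (l m)` of random deviations from the target. The closed form
#' equals the exact binomial expectation computed by
#' [fitness_random_exact()]; the two are held to agree to 1e-12 in the test
#' suite.
#'
#' @param q Focal founder's target helper proportion, in `[0, 1]`. Vectorized.
#' @param Q Target helper proportion of the other founders, in `[0, 1]`.
#' @param params A [dol_params()] object.
#' @return Expected fitness (nonnegative numeric, recycled over `q`, `Q`).
#' @seealso [fitness_coordinated()], [fitness_random_exact()]
#' @examples
#' fitness_random(0.5, 0.5, dol_params(1, 2, epsilon = 1)) # 0.125
#' @export
fitness_random <- function(q, Q, params) {
  stopifnot(inherits(params, "dol_params"))
  check_unit_interval(q, "q")
  check_unit_interval(Q, "Q")
  l <- params$l; m <- params$m; eps <- params$epsilon
  (1 - q) * (1 - eps + eps * q / l + eps * (l - 1) * Q / l - eps * q / (l * m))
}

#' Exact binomial-expectation oracle for random-specializer fitness
#'
#' Computes the random specializer's expected fitness by enumerating the
#' focal lineage's helper count `k ~ Binomial(m, q)` explicitly:
#'
#' \deqn{\sum_{k=0}^{m} \binom{m}{k} q^k (1-q)^{m-k} \, (1 - k/m)
#'   \left(1 - \epsilon + \epsilon \frac{k + (l-1) Q m}{l m}\right)}
#'
#' The other lineages enter at their expected helper count `(l-1) Q m`, which
#' is exact because fecundity is linear in their contribution. This function
#' is the independent oracle against which the closed form
#' [fitness_random()] is validated; it is deliberately a direct enumeration.
#'
#' @inheritParams fitness_random
#' @return Expected fitness (recycled over `q`, `Q`).
#' @export
fitness_random_exact <- function(q, Q, params) {
  stopifnot(inherits(params, "dol_params"))
  check_unit_interval(q, "q")
  check_unit_interval(Q, "Q")
  l <- params$l; m <- params$m; eps <- params$epsilon
  k <- 0:m
  one <- function(qi, Qi) {
    pmf <- stats::dbinom(k, size = m, prob = qi)
    sum(pmf * (1 - k / m) * (1 - eps + eps * (k + (l - 1) * Qi * m) / (l * m)))
  }
  purrr::map2_dbl(rep_len(q, max(length(q), length(Q))),
                  rep_len(Q, max(length(q), length(Q))), one)
}

#' Expected fitness of a fully coordinated specializer
#'
#' Expected fitness of a focal founder whose lineage uses within-lineage
#' signaling to realize exactly a proportion `q` of helpers, paying a relative
#' coordination cost `theta`:
#'
#' \deqn{w_{FC}(q, Q) = (1-\theta)(1-q)\left(1-\epsilon + \epsilon q/l +
#'   \epsilon (l-1) Q / l\right)}
#'
#' Deterministic phenotype assignment removes the stochasticity penalty of
#' [fitness_random()], so the value does not depend on the lineage size `m`.
#'
#' @inheritParams fitness_random
#' @return Expected fitness (recycled over `q`, `Q`).
#' @examples
#' fitness_coordinated(0.5, 0.5, dol_params(1, 5, epsilon = 1, theta = 0)) # 0.25
#' @export
fitness_coordinated <- function(q, Q, params) {
  stopifnot(inherits(params, "dol_params"))
  check_unit_interval(q, "q")
  check_unit_interval(Q, "Q")
  if (params$theta > 1) rlang::abort("`theta` must be <= 1 for coordinated fitness.")
  l <- params$l; eps <- params$epsilon
  (1 - params$theta) * (1 - q) * (1 - eps + eps * q / l + eps * (l - 1) * Q / l)
}
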