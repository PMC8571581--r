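#' Model parameters for the division-of-labor game
#'
#' Bundles the four parameters of the haystack-structured public-goods game:
#' the number of founding lineages `l`, the number of cells per lineage at
#' maturity `m`, the essentiality of cooperation `epsilon`, and the
#' coordination cost coefficient `theta`. The mature group size is
#' `n = l * m` and the whole-group relatedness (including self) implied by the
#' founding structure is `1/l`.
#'
#' @param l Integer >= 1. Number of founding lineages per group.
#' @param m Integer >= 1. Cells per lineage when the group is mature.
#' @param epsilon Essentiality of cooperation, in `[0, 1]`. A reproductive's
#'   fecundity is `1 - epsilon + epsilon * P` where `P` is the realized helper
#'   proportion of its group.
#' @param theta Coordination cost coefficient, >= 0. Fully coordinated
#'   specializers pay a relative fecundity cost `theta`; in the simulator the
#'   cost scales with the coordination level `s` (see [coordination_cost()]).
#'
#' @return An object of class `dol_params`: a list with elements `l`, `m`,
#'   `epsilon`, `theta`, and the derived group size `n`.
#' @examples
#' p <- dol_params(l = 2, m = 10, epsilon = 0.9)
#' p$n            # 20
#' relatedness(p) # 0.5
#' @export
dol_params <- function(l, m, epsilon, theta = 0.025) {
  if (length(l) != 1L || length(m) != 1L || length(epsilon) != 1L ||
      length(theta) != 1L) {
    rlang::abort("`l`, `m`, `epsilon`, `theta` must be scalars.")
  }
  l <- as.integer(l)
  m <- as.integer(m)
  if (is.na(l) || l < 1L) rlang::abort("`l` must be an integer >= 1.")
  if (is.na(m) || m < 1L) rlang::abort("`m` must be an integer >= 1.")
  check_unit_interval(epsilon, "epsilon")
  if (!is.numeric(theta) || is.na(theta) || theta < 0) {
    rlang::abort("`theta` must be a nonnegative number.")
  }
  structure(
    list(l = l, m = m, epsilon = epsilon, theta = theta, n = l * m),
    class = "dol_params"
  )
}

#' @export
print.dol_params <- function(x, ...) {
  cat(sprintf(
    "<dol_params> l = %d lineages x m = %d cells (n = %d), epsilon = %g, theta = %g, relatedness = 1/%d\n",
    x$l, x$m, x$n, x$epsilon, x$theta, x$l
  ))
  invisible(x)
}

#' Whole-group relatedness implied by the founding structure
#'
#' The probability that two group members drawn at random (with replacement,
#' i.e. including self-pairing) descend from the same founder, which is `1/l`.
#'
#' @param params A [dol_params()] object.
#' @return A single number, `1 / l`.
#' @export
relatedness <- function(params) {
  stopifnot(inherits(params, "dol_params"))
  1 / params$l
}

# shared domain check for proportions/probabilities
check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    rlang::abort(sprintf("`%s` must be numeric in [0, 1].", name))
  }
  invisible(x)
}
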