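#' Probability of encountering at least one suitable patch during a dive
#'
#' Effective density \eqn{\delta} is the instantaneous rate at which a
#' foraging otter encounters suitable patches of a prey type, so the finite
#' probability of at least one encounter during a dive is
#' \eqn{\lambda = 1 - e^{-\delta}}.
#'
#' @param delta Non-negative numeric vector of effective densities
#'   (encounter rate per dive; \eqn{\delta = e^{\Delta}} on the log scale).
#' @return Numeric vector of encounter probabilities in `[0, 1)`.
#' @examples
#' encounter_probability(log(2))  # 0.5
#' @export
encounter_probability <- function(delta) {
  if (!is.numeric(delta) || any(!is.finite(delta)) || any(delta < 0))
    stop("'delta' must be finite and non-negative", call. = FALSE)
  -expm1(-delta)
}

#' Optimal-foraging effort allocation over prey types
#'
#' Computes, for each prey type, the joint probability \eqn{\pi_i} of
#' encountering a patch of type i during a dive while encountering no patch
#' of any strictly more profitable type:
#' \deqn{\pi_i = \lambda_i \prod_{j \ne i} (1 - \lambda_j W_{ij})}
#' where \eqn{W_{ij} = 1} iff \eqn{E_j > E_i} (ties count as "not better"
#' for both members, controlled by `tie_tol`). An otter making optimal patch
#' choices allocates feeding dives proportionally, so the effort allocation
#' is \eqn{\eta = \pi / \sum_i \pi_i}.
#'
#' @param E Numeric vector of patch profitabilities (expected energy intake
#'   rate, kcal/min, while feeding in a suitable patch of each type).
#' @param lambda Numeric vector of per-dive encounter probabilities,
#'   each in `[0, 1)`; same length as `E`.
#' @param tie_tol Non-negative tolerance: prey j only outranks prey i when
#'   `E[j] > E[i] + tie_tol`. Default 0 (strict inequality).
#' @return A list of class `"allocation"` with components `pi`
#'   (unnormalized joint probabilities), `eta` (normalized effort
#'   allocation on the simplex), `E` and `lambda`.
#' @examples
#' a <- allocation_probabilities(E = c(10, 5), lambda = c(0.5, 0.5))
#' a$pi   # 0.50 0.25
#' a$eta  # 2/3 1/3
#' @export
allocation_probabilities <- function(E, lambda, tie_tol = 0) {
  K <- length(E)
  if (length(lambda) != K)
    stop("'E' and 'lambda' must have the same length", call. = FALSE)
  if (K < 1L) stop("need at least one prey type", call. = FALSE)
  if (any(!is.finite(lambda)) || any(lambda < 0) || any(lambda >= 1))
    stop("'lambda' values must lie in [0, 1)", call. = FALSE)
  if (tie_tol < 0) stop("'tie_tol' must be non-negative", call. = FALSE)
  pi <- .alloc_pi(E, lambda, tie_tol)
  s <- sum(pi)
  if (s <= 0)
    stop("degenerate input: all encounter probabilities are zero, ",
         "effort allocation is undefined", call. = FALSE)
  structure(list(pi = pi, eta = pi / s, E = E, lambda = lambda),
            class = "allocation")
}

# vectorized core: lambda may be a K x T matrix; returns same shape.
# W[i, j] = 1 iff E_j > E_i + tol; pi_i = lambda_i * prod_j (1 - lambda_j W[i,j])
.alloc_pi <- function(E, lambda, tie_tol = 0) {
  W <- outer(E, E, function(a, b) as.numeric(b > a + tie_tol))
  if (is.matrix(lambda)) {
    logq <- log1p(-lambda)
    exp(log(lambda) + W %*% logq)
  } else {
    as.vector(lambda * exp(W %*% log1p(-lambda)))
  }
}

#' Mean overall rate of energy intake
#'
#' The expected energy intake rate of an optimally foraging otter,
#' \eqn{\bar{E} = \sum_i \eta_i E_i} using the normalized effort allocation
#' (the default), or \eqn{\sum_i \pi_i E_i} using unnormalized joint
#' encounter probabilities (`normalized = FALSE`), which discounts dives on
#' which no suitable patch is encountered.
#'
#' @param alloc An `"allocation"` object from [allocation_probabilities()],
#'   or a numeric vector of allocation weights.
#' @param E Patch profitabilities; required when `alloc` is a bare vector,
#'   ignored otherwise.
#' @param normalized Use the simplex-normalized allocation (default TRUE).
#' @return Scalar kcal per minute.
#' @examples
#' mean_energy_intake(c(0.5, 0.5), E = c(10, 6))  # 8
#' @export
mean_energy_intake <- function(alloc, E = NULL, normalized = TRUE) {
  if (inherits(alloc, "allocation")) {
    w <- if (normalized) alloc$eta else alloc$pi
    E <- alloc$E
  } else {
    w <- alloc
  }
  if (is.null(E)) stop("'E' must be supplied", call. = FALSE)
  if (length(w) != length(E))
    stop("allocation and 'E' have mismatched lengths", call. = FALSE)
  sum(w * E)
}

#' Per-capita predation rate on one prey type
#'
#' Expected number of items of a prey type consumed per minute of foraging:
#' effort share times intake rate divided by the energy content of one item,
#' \eqn{P_i = \eta_i E_i / G_i}.
#'
#' @param eta_i Effort allocation share for the prey type.
#' @param E_i Patch profitability (kcal/min).
#' @param G_i Mean energy content of one consumed item (kcal); must be
#'   positive.
#' @return Items per minute.
#' @examples
#' predation_rate(0.2, 10, 5)  # 0.4
#' @export
predation_rate <- function(eta_i, E_i, G_i) {
  if (any(!is.finite(G_i)) || any(G_i <= 0))
    stop("'G_i' must be positive", call. = FALSE)
  eta_i * E_i / G_i
}

#' @export
print.allocation <- function(x, digits = 3, ...) {
  cat("Optimal-foraging allocation over", length(x$E), "prey types\n")
  m <- rbind(E = x$E, lambda = x$lambda, pi = x$pi, eta = x$eta)
  print(round(m, digits))
  cat("sum(pi) =", format(sum(x$pi), digits = digits),
      "(probability of encountering any patch when profitabilities are distinct)\n")
  invisible(x)
}
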