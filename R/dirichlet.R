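# Dirichlet utilities: random draws and maximum-likelihood precision.

#' Draw from a Dirichlet distribution
#'
#' @param n Number of draws.
#' @param alpha Concentration vector (all positive).
#' @return `n x length(alpha)` matrix, rows on the simplex.
#' @export
rdirichlet <- function(n, alpha) {
  if (any(alpha <= 0)) stop("'alpha' must be positive", call. = FALSE)
  K <- length(alpha)
  g <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  g / rowSums(g)
}

#' Maximum-likelihood Dirichlet precision of a draw matrix
#'
#' Fits a Dirichlet distribution to a matrix of compositional draws (rows on
#' the simplex) by maximum likelihood and returns the precision, i.e. the sum
#' of the fitted concentration parameters. Used to pre-compute the per-year
#' precision \eqn{\tau_t} of foraging-survey effort-allocation posteriors
#' before model fitting.
#'
#' Zero (or numerically tiny) components break the Dirichlet likelihood;
#' draws are floored at `floor` and renormalized first. A degenerate matrix
#' with (near-)identical rows has unbounded ML precision; in that case the
#' returned value is capped at `cap` and flagged.
#'
#' The fixed-point iteration is Minka's:
#' \eqn{\alpha_k \leftarrow \psi^{-1}(\psi(\sum_j \alpha_j) + \overline{\log p_k})}.
#'
#' @param draws Numeric matrix, one draw per row, rows summing to 1.
#'   At least 50 rows.
#' @param floor Lower floor applied to components before fitting.
#' @param cap Upper cap for the returned precision.
#' @param tol,maxit Convergence control for the fixed-point iteration.
#' @return Numeric scalar: the ML precision \eqn{\tau}. Attributes:
#'   `alpha` (fitted concentration vector), `capped` (logical),
#'   `iterations`.
#' @examples
#' set.seed(1)
#' x <- rdirichlet(2000, 50 * c(0.2, 0.3, 0.5))
#' dirichlet_precision(x)
#' @export
dirichlet_precision <- function(draws, floor = 1e-6, cap = 1e8,
                                tol = 1e-10, maxit = 500) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 50)
    stop("need at least 50 draws to fit a Dirichlet", call. = FALSE)
  rs <- rowSums(draws)
  if (any(abs(rs - 1) > 1e-6) || any(draws < -1e-12))
    stop("rows of 'draws' must be non-negative and sum to 1", call. = FALSE)
  p <- pmax(draws, floor)
  p <- p / rowSums(p)
  if (any(apply(draws, 2, function(z) all(z < floor))))
    warning("a component is identically (near) zero; it was floored at ",
            floor, call. = FALSE)
  logp_bar <- colMeans(log(p))
  # identical rows => variance 0 => unbounded precision
  if (max(apply(p, 2, stats::var)) < 1e-14) {
    warning("draw rows are (near-)identical; ML precision is unbounded, ",
            "returning the cap", call. = FALSE)
    alpha <- cap * colMeans(p)
    return(structure(cap, alpha = alpha, capped = TRUE, iterations = 0L))
  }
  # moment-based start (Minka): uses mean/variance of the first component
  m <- colMeans(p); v <- apply(p, 2, stats::var)
  j <- which.max(v)
  s0 <- max(m[j] * (1 - m[j]) / v[j] - 1, 1e-3)
  alpha <- m * s0
  it <- 0L
  repeat {
    it <- it + 1L
    alpha_new <- .inv_digamma(digamma(sum(alpha)) + logp_bar)
    if (any(!is.finite(alpha_new))) break
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol || it >= maxit) break
    if (sum(alpha) > cap) break
  }
  tau <- sum(alpha)
  capped <- FALSE
  if (tau > cap) { tau <- cap; capped <- TRUE
    warning("ML precision exceeded the cap of ", cap, call. = FALSE) }
  structure(tau, alpha = alpha, capped = capped, iterations = it)
}

# Newton inversion of the digamma function (Minka's initialization)
.inv_digamma <- function(y, iters = 6) {
  x <- ifelse(y >= -2.22, exp(y) + 0.5, -1 / (y - digamma(1)))
  for (i in seq_len(iters))
    x <- x - (digamma(x) - y) / trigamma(x)
  x
}
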