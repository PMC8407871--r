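#' Gauss-Hermite quadrature rule for random-effect integrals
#'
#' Builds a (tensor-product) Gauss-Hermite rule used to marginalize the
#' joint likelihood over the subject-level random effects.  The standard
#' nodes/weights integrate against the weight function \eqn{e^{-|z|^2}};
#' the fitting routines recenter and rescale the rule at each subject's
#' conditional posterior mode (adaptive quadrature).
#'
#' @param Q integer, number of nodes per dimension (order).
#' @param d integer, dimension of the random-effect vector (1 or 2).
#' @return An object of class \code{"gh_rule"}: a list with \code{z} (K x d
#'   matrix of nodes), \code{logw} (log weights, length K), \code{Q},
#'   \code{d}.  \code{sum(exp(logw)) == pi^(d/2)} up to round-off, so the
#'   rule integrates a multivariate normal density to one exactly.
#' @examples
#' r <- gh_rule(9, 2)
#' # integrates N(0, I) to 1:
#' sum(exp(r$logw)) / pi   # ~ 1
#' @export
gh_rule <- function(Q = 9L, d = 2L) {
  stopifnot(Q >= 1L, d %in% c(1L, 2L))
  g <- pracma::gaussHermite(Q)
  if (d == 1L) {
    z <- matrix(g$x, ncol = 1L)
    logw <- log(g$w)
  } else {
    idx <- expand.grid(i = seq_len(Q), j = seq_len(Q))
    z <- cbind(g$x[idx$i], g$x[idx$j])
    logw <- log(g$w[idx$i]) + log(g$w[idx$j])
  }
  structure(list(z = z, logw = logw, Q = as.integer(Q), d = as.integer(d)),
            class = "gh_rule")
}

#' @export
print.gh_rule <- function(x, ...) {
  cat(sprintf("Gauss-Hermite rule: order %d, dimension %d (%d nodes)\n",
              x$Q, x$d, nrow(x$z)))
  invisible(x)
}
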