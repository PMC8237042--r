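#' Largest adjacency eigenvalue (spectral radius)
#'
#' The energy function of the well-controlling ensemble and, through its
#' inverse, the SIS epidemic threshold. For a symmetric 0/1 adjacency
#' matrix the largest eigenvalue is real and non-negative; the empty edge
#' set gives 0.
#'
#' Two backends are provided: a dense symmetric eigendecomposition
#' (`eigen`), used by default for graphs with at most 64 nodes, and an
#' iterative Lanczos method on the edge list (used by default above that,
#' and inside the MCMC sampler). The Lanczos iteration uses full
#' reorthogonalization, a strictly positive start vector (guaranteeing
#' overlap with the Perron eigenspace of every component), Sturm-count
#' bisection on the tridiagonal, and declares convergence only after an
#' explicit check of the true residual `||A v - lambda v|| <= tol`, which
#' for a symmetric matrix bounds the eigenvalue error by `tol`.
#'
#' @param g A `net_graph`.
#' @param tol Absolute accuracy of the iterative backend.
#' @param method `"auto"` (dense for `n <= 64`, else Lanczos),
#'   `"dense"`, or `"lanczos"`.
#' @param maxit Total Lanczos-step cap for the iterative method.
#' @return Non-negative scalar.
#' @examples
#' largest_eigenvalue(net_graph(4, t(combn(0:3, 2)))) # K4 -> 3
#' @export
largest_eigenvalue <- function(g, tol = 1e-8,
                               method = c("auto", "dense", "lanczos"),
                               maxit = 100000L) {
  stopifnot(inherits(g, "net_graph"), tol > 0)
  method <- match.arg(method)
  if (nrow(g$edges) == 0L) return(0)
  if (method == "auto")
    method <- if (g$n_nodes <= 64L) "dense" else "lanczos"
  if (method == "dense") {
    A <- matrix(0, g$n_nodes, g$n_nodes)
    A[g$edges + 1L] <- 1
    A[g$edges[, c(2, 1), drop = FALSE] + 1L] <- 1
    return(max(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  }
  lanczos_lambda_cpp(g$n_nodes, g$edges[, 1], g$edges[, 2], tol,
                     as.integer(maxit))$lambda
}

#' Epidemic threshold of a contact graph
#'
#' The critical infection-to-recovery ratio `beta / delta` below which an
#' SIS epidemic dies out, approximated by the inverse spectral radius
#' `1 / lambda_max` of the adjacency matrix. An edgeless graph cannot
#' sustain spreading and returns `Inf`.
#'
#' @inheritParams largest_eigenvalue
#' @param ... Passed to [largest_eigenvalue()].
#' @return Positive scalar, or `Inf` for an empty edge set.
#' @examples
#' epidemic_threshold(net_graph(2, rbind(c(0, 1)))) # single edge -> 1
#' @export
epidemic_threshold <- function(g, ...) {
  lam <- largest_eigenvalue(g, ...)
  if (lam == 0) Inf else 1 / lam
}
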