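# Gauss-Hermite quadrature adapted to N(0,1) expectations.
# Nodes/weights come from the Golub-Welsch eigen-decomposition of the Jacobi
# matrix of the Hermite polynomials, so no external table is needed; the rule
# is exact for polynomials up to degree 2k-1 against the normal weight.

#' Gauss-Hermite rule for expectations over a standard normal
#'
#' Returns nodes z_j and weights w_j such that
#' \eqn{E[f(Z)] \approx \sum_j w_j f(z_j)} for Z ~ N(0,1).
#'
#' @param k number of quadrature points (>= 1).
#' @return list with numeric vectors `nodes` and `weights` (weights sum to 1).
#' @export
gauss_hermite_normal <- function(k) {
  stopifnot(k >= 1)
  if (k == 1) return(list(nodes = 0, weights = 1))
  # Jacobi matrix for physicists' Hermite polynomials
  off <- sqrt(seq_len(k - 1) / 2)
  J <- matrix(0, k, k)
  J[cbind(seq_len(k - 1), seq_len(k - 1) + 1)] <- off
  J[cbind(seq_len(k - 1) + 1, seq_len(k - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- e$vectors[1, ]^2  # already sum to 1 for the normalized weight
  ord <- order(nodes)
  # change of variable x = z/sqrt(2) maps exp(-x^2) to the N(0,1) density
  list(nodes = sqrt(2) * nodes[ord], weights = weights[ord])
}
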