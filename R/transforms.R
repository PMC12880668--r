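#' Transforms between constrained and unconstrained latent space
#'
#' The variational guide lives on an unconstrained space; each latent is
#' mapped there by a bijection determined by its support: a scaled logit
#' for two-sided truncations, `log(z - lower)` for one-sided ones, and the
#' identity for unbounded latents (the sinusoid phases). Boundary values
#' are clamped to large finite numbers rather than mapping to infinities.
#'
#' @param z,u constrained / unconstrained values: vector or `D x K` matrix
#'   with rows following `nodes$table`.
#' @param nodes a [build_nodes()] result.
#' @return the transformed values; `log_jacobian()` returns the
#'   log-absolute-determinant per column (scalar for a vector input).
#' @export
transform_latents <- function(z, nodes) {
  z <- cbind(z); tab <- nodes$table
  u <- z
  i <- tab$transform == "logit"
  if (any(i)) {
    p <- (z[i, , drop = FALSE] - tab$lower[i]) / (tab$upper[i] - tab$lower[i])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    u[i, ] <- qlogis(p)
  }
  i <- tab$transform == "log_lb"
  if (any(i)) u[i, ] <- log(pmax(z[i, , drop = FALSE] - tab$lower[i], 1e-300))
  drop(u)
}

#' @rdname transform_latents
#' @export
untransform_latents <- function(u, nodes) {
  u <- cbind(u); tab <- nodes$table
  z <- u
  i <- tab$transform == "logit"
  if (any(i))
    z[i, ] <- tab$lower[i] + (tab$upper[i] - tab$lower[i]) *
      plogis(u[i, , drop = FALSE])
  i <- tab$transform == "log_lb"
  if (any(i)) z[i, ] <- tab$lower[i] + exp(u[i, , drop = FALSE])
  drop(z)
}

#' @rdname transform_latents
#' @export
log_jacobian <- function(u, nodes) {
  u <- cbind(u); tab <- nodes$table
  lj <- matrix(0, nrow(u), ncol(u))
  i <- tab$transform == "logit"
  if (any(i)) {
    ui <- u[i, , drop = FALSE]
    lj[i, ] <- log(tab$upper[i] - tab$lower[i]) + plogis(ui, log.p = TRUE) +
      plogis(-ui, log.p = TRUE)
  }
  i <- tab$transform == "log_lb"
  if (any(i)) lj[i, ] <- u[i, , drop = FALSE]
  drop(colSums(lj))
}

# dz/du, elementwise (vector u)
.dz_du <- function(u, nodes) {
  tab <- nodes$table
  d <- rep(1, length(u))
  i <- tab$transform == "logit"
  if (any(i)) {
    p <- plogis(u[i])
    d[i] <- (tab$upper[i] - tab$lower[i]) * p * (1 - p)
  }
  i <- tab$transform == "log_lb"
  if (any(i)) d[i] <- exp(u[i])
  d
}
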