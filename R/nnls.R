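# Lawson-Hanson active-set nonnegative least squares:
# min ||A x - b||^2 s.t. x >= 0. Small dense problems only (the target-count
# dimension of a mapping experiment), so plain R with lm.fit-style solves is
# adequate.
nnls_solve <- function(A, b, tol = 1e-10, max_iter = 10L * ncol(A)) {
  A <- as.matrix(A)
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      z[passive] <- qr.coef(qr(Ap), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) {
        x <- z
        break
      }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

# Nonnegative ridge: min ||A x - b||^2 + lambda ||x||^2, x >= 0, via the
# augmented system [A; sqrt(lambda) I].
nnls_ridge <- function(A, b, lambda = 0) {
  if (lambda > 0) {
    A <- rbind(A, sqrt(lambda) * diag(ncol(A)))
    b <- c(b, numeric(ncol(A)))
  }
  nnls_solve(A, b)
}
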