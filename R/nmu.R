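#' ADMM solver settings
#'
#' @param rho initial penalty parameter. Applied after each batch is scaled
#'   by its maximum absolute value, so the default is unit-free.
#' @param tol convergence tolerance on the relative iterate change and on the
#'   split/consensus residuals.
#' @param max_iter iteration cap; on hitting it the best iterate is returned
#'   flagged `converged = FALSE`, never an error.
#' @param adapt_rho escalate the penalty (factor 2, every 25 iterations, up
#'   to `rho_max`) while the underapproximation constraint is still violated
#'   beyond tolerance. On data that is far from rank-one a fixed small
#'   penalty leaves the fit infeasible; escalation restores feasibility
#'   without slowing the easy near-low-rank case.
#' @param rho_max penalty ceiling for the escalation.
#' @param seed seed for any randomized initialization (the default SVD
#'   initialization is deterministic; the seed is kept for reproducibility of
#'   optional randomized restarts).
#' @return object of class `admm_settings`.
#' @export
admm_settings <- function(rho = 1.0, tol = 1e-4, max_iter = 1000L,
                          adapt_rho = TRUE, rho_max = 64, seed = 1L) {
  if (!(rho > 0)) pd_stop("rho must be > 0")
  if (!(tol > 0)) pd_stop("tol must be > 0")
  if (max_iter < 1L) pd_stop("max_iter must be >= 1")
  structure(list(rho = rho, tol = tol, max_iter = as.integer(max_iter),
                 adapt_rho = isTRUE(adapt_rho), rho_max = rho_max,
                 seed = as.integer(seed)), class = "admm_settings")
}

# Leading singular pair of a nonnegative matrix, sign-fixed so the majority
# of mass in v is nonnegative, then clipped; u returned unit-norm.
svd_init <- function(Y) {
  s <- svd(Y, nu = 1L, nv = 1L)
  u <- s$u[, 1L]
  v <- s$v[, 1L] * s$d[1L]
  if (sum(pmax(v, 0)) < sum(pmax(-v, 0))) {
    u <- -u
    v <- -v
  }
  u <- pmax(u, 0)
  v <- pmax(v, 0)
  nu <- sqrt(sum(u^2))
  if (nu > 0) {
    v <- v * nu   # keep u'v' product: u d v = (u/||u||) (||u|| d v)
    u <- u / nu
  }
  list(u = u, v = v)
}

#' Rank-one nonnegative matrix underapproximation with decay constraint
#'
#' Fits a single rank-one term `u v'` to a nonnegative matrix `Y` solving
#' \deqn{\min_{u \ge 0, v \ge 0}\ \|Y - u v'\|_F^2 \quad
#'       \mathrm{s.t.}\ u v' \le Y,\ v_i \le \gamma v_{i-1}\ (i > start)}
#' by ADMM on the split `Y - u v' = R >= 0`, `q = v` with the decay
#' constraint carried by `q` via the exact pooled projection
#' ([project_gamma_decreasing()]). The underapproximation constraint keeps
#' the fitted waveform from swallowing structure (PSCs) that rides on top of
#' the artifact; the decay constraint forces the waveform to behave like a
#' relaxing photocurrent where required.
#'
#' On exit `u` is unit-norm (all scale carried in `v`), and, when a
#' constraint is active, the constrained suffix of `v` is replaced by its
#' exact projection so the decay holds exactly rather than to ADMM
#' tolerance.
#'
#' @param Y nonnegative numeric matrix (trials x samples).
#' @param u_init,v_init optional warm starts; when absent both are
#'   initialized from the leading singular pair of `Y` (sign-fixed, clipped).
#' @param constraint a [decay_constraint()] applied to `v`, or `NULL` for
#'   plain NMU with no decay constraint.
#' @param update_u if `FALSE`, `u_init` is held fixed (bit-identical on
#'   return) and only the waveform is fitted.
#' @param slack nonnegative elementwise relaxation of the
#'   underapproximation constraint, in data units: the constraint becomes
#'   `u v' <= Y + slack` while the objective still targets `Y`. With noisy
#'   recordings a hard `u v' <= Y` makes single-sample noise minima bind,
#'   biasing the shared waveform low by several noise SDs; a slack of about
#'   2 noise SDs removes that bias while still stopping the waveform from
#'   absorbing structured signal. Default 0 (the strict constraint).
#' @param settings an [admm_settings()].
#' @return object of class `rank_one_factor`: fields `u`, `v`, `q`,
#'   `R_res` (nonnegative residual split variable), `converged`, `n_iter`,
#'   `rel_residual`.
#' @export
nmu_decreasing <- function(Y, u_init = NULL, v_init = NULL,
                           constraint = NULL, update_u = TRUE,
                           slack = 0, settings = admm_settings()) {
  if (slack < 0) pd_stop("slack must be >= 0")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  T_ <- ncol(Y)
  if (any(Y < 0)) pd_stop("nmu_decreasing requires a nonnegative matrix")
  scale <- max(Y)
  zero_fac <- function() {
    structure(list(u = numeric(n) * 0, v = numeric(T_) * 0, q = numeric(T_),
                   R_res = matrix(0, n, T_), converged = TRUE, n_iter = 0L,
                   rel_residual = 0), class = "rank_one_factor")
  }
  if (scale == 0) {
    out <- zero_fac()
    if (!is.null(u_init) && !update_u) out$u <- u_init
    return(out)
  }
  Ys <- Y / scale
  if (!update_u && is.null(u_init))
    pd_stop("update_u = FALSE requires u_init")
  if (is.null(u_init) || (update_u && is.null(v_init))) {
    init <- svd_init(Ys)
    u <- if (is.null(u_init)) init$u else u_init
    v <- if (is.null(v_init)) init$v else v_init / scale
  } else {
    u <- u_init
    v <- if (is.null(v_init)) pmax(drop(crossprod(Ys, u)), 0) / max(sum(u^2), 1) else v_init / scale
  }
  if (all(u == 0)) {
    out <- zero_fac()
    out$u <- if (update_u) out$u else u_init
    return(out)
  }

  res <- nmu_admm_cpp(Ys, u, matrix(v, nrow = 1L),
                      update_u = update_u,
                      has_constraint = !is.null(constraint),
                      gamma = if (is.null(constraint)) 1 else constraint$gamma,
                      start = if (is.null(constraint)) 1L else constraint$start,
                      slack = slack / scale,
                      rho = settings$rho, tol = settings$tol,
                      max_iter = settings$max_iter,
                      adapt_rho = settings$adapt_rho,
                      rho_max = settings$rho_max)
  u <- drop(res$u)
  v <- drop(res$v)
  if (!is.null(constraint)) v <- project_gamma_decreasing(v, constraint)
  yfro <- sqrt(sum(Ys^2))
  structure(list(u = if (update_u) u else u_init,
                 v = v * scale, q = drop(res$q) * scale,
                 R_res = res$R_res * scale,
                 Gamma = res$Gamma * scale,
                 lambda_dual = drop(res$lambda) * scale,
                 converged = res$converged, n_iter = res$n_iter,
                 rel_residual = sqrt(sum((Ys - tcrossprod(u, v))^2)) / yfro),
            class = "rank_one_factor")
}

#' @export
print.rank_one_factor <- function(x, ...) {
  cat(sprintf("<rank_one_factor> %d x %d, %s in %d iterations (rel residual %.3g)\n",
              length(x$u), length(x$v),
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$rel_residual))
  invisible(x)
}

#' Unconstrained truncated SVD baseline
#'
#' Rank-`r` truncated SVD of `Y`, provided as a diagnostic baseline only: an
#' unconstrained low-rank fit freely absorbs PSCs along with the artifact,
#' which is exactly the failure the constrained model exists to avoid.
#'
#' @param Y numeric matrix.
#' @param r rank, `1 <= r <= min(dim(Y))`.
#' @return list with `u` (N x r), `d` (length r), `v` (T x r),
#'   `reconstruction`, and `residual_fro`.
#' @export
svd_rank_r <- function(Y, r = 1L) {
  Y <- as.matrix(Y)
  r <- as.integer(r)
  if (r < 1L || r > min(dim(Y)))
    pd_stop("rank r = %d outside [1, %d]", r, min(dim(Y)))
  s <- svd(Y, nu = r, nv = r)
  recon <- s$u %*% (s$d[seq_len(r)] * t(s$v))
  list(u = s$u, d = s$d[seq_len(r)], v = s$v,
       reconstruction = recon,
       residual_fro = sqrt(sum((Y - recon)^2)))
}
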