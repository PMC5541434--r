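#' Scale a response matrix into [-1, 1]
#'
#' Divides all observed responses by the maximum absolute observed
#' value, so the response range matches that of the similarity matrices
#' the factorization is regularized towards.  [srmf_fit()] applies this
#' internally and records the constant; predictions are mapped back to
#' the original scale.
#'
#' @param R a [response_matrix()].
#' @return list with `scaled` (a `response_matrix`) and `scale` (the
#'   divisor).
#' @export
scale_response <- function(R) {
  stopifnot(inherits(R, "response_matrix"))
  obs <- R$values[R$mask]
  if (length(obs) == 0L) stop("response matrix has no observed entries")
  s <- max(abs(obs))
  if (s == 0) stop("all observed responses are zero; scale undefined")
  scaled <- R
  scaled$values <- R$values / s
  list(scaled = scaled, scale = s)
}

#' Evaluate the regularized factorization objective
#'
#' The quantity the fit minimizes:
#' \deqn{||W \circ (Y - UV^T)||_F^2 + \lambda_l(||U||_F^2 + ||V||_F^2)
#'   + \lambda_d ||S_d - UU^T||_F^2 + \lambda_c ||S_c - VV^T||_F^2}
#' where `W` is the binary observed-entry mask and the Hadamard product
#' confines the reconstruction loss to assayed pairs.
#'
#' @param Y m x n response matrix (missing entries may be `NA`; they are
#'   zeroed under the mask).
#' @param W m x n binary/logical observation mask.
#' @param U m x K drug factor matrix.
#' @param V n x K cell-line factor matrix.
#' @param Sd,Sc drug / cell-line similarity matrices; may be `NULL` when
#'   the corresponding lambda is 0.
#' @param lambda_l,lambda_d,lambda_c non-negative weights.
#' @return the objective value (non-negative scalar).
#' @export
srmf_objective <- function(Y, W, U, V, Sd = NULL, Sc = NULL,
                           lambda_l = 0, lambda_d = 0, lambda_c = 0) {
  if (!all(dim(Y) == dim(W))) stop("Y and W dimensions differ")
  if (nrow(U) != nrow(Y) || nrow(V) != ncol(Y) || ncol(U) != ncol(V))
    stop("factor dimensions do not conform with Y")
  W <- W * 1
  Y0 <- Y
  Y0[W == 0] <- 0
  resid <- W * (Y0 - tcrossprod(U, V))
  obj <- sum(resid^2) + lambda_l * (sum(U^2) + sum(V^2))
  if (lambda_d > 0) {
    if (is.null(Sd)) stop("lambda_d > 0 requires Sd")
    if (!all(dim(Sd) == nrow(U))) stop("Sd dimensions do not conform")
    obj <- obj + lambda_d * sum((Sd - tcrossprod(U))^2)
  }
  if (lambda_c > 0) {
    if (is.null(Sc)) stop("lambda_c > 0 requires Sc")
    if (!all(dim(Sc) == nrow(V))) stop("Sc dimensions do not conform")
    obj <- obj + lambda_c * sum((Sc - tcrossprod(V))^2)
  }
  obj
}

# Deterministic initialization: truncated SVD of the mean-imputed scaled
# response, with each singular pair's sign fixed so the largest-magnitude
# entry of the left vector is positive.  Random-normal fallback is seeded.
init_factors <- function(Y, W, K, init, seed) {
  m <- nrow(Y); n <- ncol(Y)
  if (init == "random") {
    return(withr::with_seed(seed, list(
      U = matrix(stats::rnorm(m * K, sd = 0.1), m, K),
      V = matrix(stats::rnorm(n * K, sd = 0.1), n, K))))
  }
  Yimp <- Y
  mu <- mean(Y[W])
  Yimp[!W] <- mu
  sv <- svd(Yimp, nu = K, nv = K)
  d <- sv$d[seq_len(K)]
  flip <- vapply(seq_len(K), function(k) {
    u <- sv$u[, k]
    sign(u[which.max(abs(u))])
  }, numeric(1))
  flip[flip == 0] <- 1
  U <- sweep(sv$u, 2L, flip * sqrt(d), "*")
  V <- sweep(sv$v, 2L, flip * sqrt(d), "*")
  list(U = U, V = V)
}

# One linearized least-squares sweep for the row factors of A (drugs if
# A = U).  Solves, row by row, the normal equations of
#   ||W o (Y - A B^T)||^2 + lambda_l ||A||^2 + 2 lambda_s ||S - A A_prev^T||^2
# with A_prev frozen; the similarity surrogate has the same gradient as
# the true quartic term at A_prev.  Missing entries are handled by
# subtracting their contribution from the dense Gram matrix, which is
# cheap when most entries are observed.
solve_rows <- function(Y, W, B, A_prev, S, lambda_l, lambda_s) {
  m <- nrow(Y); K <- ncol(B)
  BtB <- crossprod(B)
  G0 <- lambda_l * diag(K)
  if (lambda_s > 0) G0 <- G0 + 2 * lambda_s * crossprod(A_prev)
  Y0 <- Y
  Y0[!W] <- 0
  RHS <- Y0 %*% B
  if (lambda_s > 0) RHS <- RHS + 2 * lambda_s * (S %*% A_prev)
  A_new <- matrix(0, m, K)
  for (i in seq_len(m)) {
    miss <- which(!W[i, ])
    Gi <- BtB + G0
    if (length(miss) > 0L)
      Gi <- Gi - crossprod(B[miss, , drop = FALSE])
    A_new[i, ] <- solve(Gi, RHS[i, ])
  }
  A_new
}

#' Fit the similarity-regularized factorization
#'
#' Alternating minimization of the objective in [srmf_objective()]: the
#' response matrix is scaled into `[-1, 1]`, the factors are initialized
#' from a truncated SVD of the mean-imputed matrix (or seeded random
#' normals), and each sweep solves regularized row-wise least-squares
#' candidates for both factor blocks from the previous iterate.  Because
#' the similarity penalties are quartic in the factors, the candidates
#' come from a local linearization; a backtracking step-halving line
#' search on the true objective then guarantees the recorded objective
#' sequence never increases.  Computing both candidates from the same
#' iterate keeps the algorithm exactly symmetric under transposing the
#' problem (drugs swapped with cell lines).  Iteration stops when the relative objective change drops
#' below `config$tol` or after `config$max_iter` sweeps.
#'
#' @param R a [response_matrix()].
#' @param Sd drug [similarity_matrix()] aligned to `R`'s drug ids;
#'   required only when `config$lambda_d > 0`.
#' @param Sc cell-line [similarity_matrix()] aligned to `R`'s cell ids;
#'   required only when `config$lambda_c > 0`.
#' @param config an [srmf_config()].
#' @return an object of class `srmf_fit`: list with factor matrices `U`
#'   (drugs x K, row-named) and `V` (cells x K), the response `scale`,
#'   the `config`, and `trace` (`objective_values`, `iterations_run`,
#'   `converged`).
#' @seealso [predict.srmf_fit()] for the completed response matrix.
#' @export
srmf_fit <- function(R, Sd = NULL, Sc = NULL, config = srmf_config()) {
  stopifnot(inherits(R, "response_matrix"), inherits(config, "srmf_config"))
  m <- nrow(R$values); n <- ncol(R$values)
  validate_config(config, m, n)
  lam_l <- config$lambda_l; lam_d <- config$lambda_d; lam_c <- config$lambda_c
  if (lam_d > 0) {
    if (is.null(Sd)) stop("lambda_d > 0 requires a drug similarity matrix")
    if (!identical(rownames(Sd), R$drug_ids))
      stop("Sd ids are not aligned with the response matrix drug ids")
  } else Sd <- NULL
  if (lam_c > 0) {
    if (is.null(Sc)) stop("lambda_c > 0 requires a cell-line similarity matrix")
    if (!identical(rownames(Sc), R$cell_ids))
      stop("Sc ids are not aligned with the response matrix cell ids")
  } else Sc <- NULL

  sc <- scale_response(R)
  Y <- sc$scaled$values
  W <- R$mask
  Sd_m <- if (is.null(Sd)) NULL else unclass(Sd)
  Sc_m <- if (is.null(Sc)) NULL else unclass(Sc)

  fac <- init_factors(Y, W, config$K, config$init, config$seed)
  U <- fac$U; V <- fac$V
  obj <- function(U, V)
    srmf_objective(Y, W, U, V, Sd_m, Sc_m, lam_l, lam_d, lam_c)
  J <- obj(U, V)
  trace <- numeric(0)
  converged <- FALSE
  iters <- 0L

  # Both candidates are computed from the previous iterate (simultaneous
  # rather than staggered updates), which makes the whole algorithm
  # exactly symmetric under transposing the problem; a shared
  # step-halving line search on the true objective then guarantees
  # monotone descent.
  for (it in seq_len(config$max_iter)) {
    U_cand <- solve_rows(Y, W, V, U, Sd_m, lam_l, lam_d)
    V_cand <- solve_rows(t(Y), t(W), U, V, Sc_m, lam_l, lam_c)
    if (any(!is.finite(U_cand)))
      stop("non-finite drug factors at iteration ", it)
    if (any(!is.finite(V_cand)))
      stop("non-finite cell-line factors at iteration ", it)
    step <- 1
    for (half in 1:30) {
      U_try <- U + step * (U_cand - U)
      V_try <- V + step * (V_cand - V)
      J_try <- obj(U_try, V_try)
      if (is.finite(J_try) && J_try <= J) {
        U <- U_try; V <- V_try; J <- J_try
        break
      }
      step <- step / 2
    }

    trace <- c(trace, J)
    iters <- it
    if (it > 1L) {
      prev <- trace[it - 1L]
      rel <- if (prev > 0) (prev - J) / prev else 0
      if (abs(rel) < config$tol) { converged <- TRUE; break }
    }
  }

  rownames(U) <- R$drug_ids
  rownames(V) <- R$cell_ids
  structure(list(U = U, V = V, scale = sc$scale, config = config,
                 response_direction = R$direction,
                 trace = list(objective_values = trace,
                              iterations_run = iters,
                              converged = converged)),
            class = "srmf_fit")
}

#' @export
print.srmf_fit <- function(x, ...) {
  cat(sprintf("srmf_fit: %d drugs x %d cell lines, K=%d\n",
              nrow(x$U), nrow(x$V), ncol(x$U)))
  cat(sprintf("  %d iterations, converged=%s, final objective %.6g\n",
              x$trace$iterations_run, x$trace$converged,
              utils::tail(x$trace$objective_values, 1)))
  invisible(x)
}

#' Predict the completed response matrix
#'
#' Returns `scale * U V'` on the original response scale — a dense
#' matrix defined for every drug/cell-line pair, observed or not.
#'
#' @param object an `srmf_fit`.
#' @param ... unused.
#' @return m x n numeric matrix with drug/cell dimnames.
#' @export
predict.srmf_fit <- function(object, ...) {
  P <- object$scale * tcrossprod(object$U, object$V)
  dimnames(P) <- list(rownames(object$U), rownames(object$V))
  P
}
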