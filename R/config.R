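#' Model configuration
#'
#' Bundles the hyperparameters of the factorization: latent
#' dimensionality `K`, the three regularization weights, and the
#' convergence controls.  `K = 45` is the default used for GDSC-sized
#' response panels; CCLE-sized panels conventionally use `K = 12`.
#' All lambdas are weights on squared-Frobenius penalty terms and must be
#' non-negative; `lambda_d = 0` (or `lambda_c = 0`) switches the
#' corresponding similarity term off entirely, in which case the matrix
#' need not be supplied to [srmf_fit()].
#'
#' @param K positive integer latent dimensionality; must not exceed
#'   `min(m, n)` of the response matrix it is used with (checked at fit
#'   time, or immediately via `dims`).
#' @param lambda_l non-negative L2 (Tikhonov) weight on `U` and `V`.
#' @param lambda_d non-negative weight on the drug-similarity term
#'   `||Sd - U U'||_F^2`.
#' @param lambda_c non-negative weight on the cell-line-similarity term
#'   `||Sc - V V'||_F^2`.
#' @param tol positive relative objective-change stopping tolerance.
#' @param max_iter positive integer cap on alternating sweeps.
#' @param seed integer seed controlling any randomized component
#'   (random initialization; deterministic SVD initialization ignores it).
#' @param init `"svd"` (deterministic, default) or `"random"`.
#' @param dims optional `c(m, n)` used to validate `K` immediately.
#' @return object of class `srmf_config`.
#' @seealso [load_config()] to read one from a key-value file.
#' @export
srmf_config <- function(K = 45L, lambda_l = 2^-3, lambda_d = 0,
                        lambda_c = 2^-3, tol = 1e-4, max_iter = 500L,
                        seed = 0L, init = c("svd", "random"),
                        dims = NULL) {
  init <- match.arg(init)
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("`K` must be a positive integer")
  for (nm in c("lambda_l", "lambda_d", "lambda_c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("`", nm, "` must be a single non-negative number")
  }
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be positive")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L)
    stop("`max_iter` must be a positive integer")
  seed <- as.integer(seed)
  cfg <- structure(list(K = K, lambda_l = lambda_l, lambda_d = lambda_d,
                        lambda_c = lambda_c, tol = tol,
                        max_iter = max_iter, seed = seed, init = init),
                   class = "srmf_config")
  if (!is.null(dims)) validate_config(cfg, dims[1], dims[2])
  cfg
}

#' @export
print.srmf_config <- function(x, ...) {
  cat(sprintf(
    "srmf_config: K=%d lambda_l=%g lambda_d=%g lambda_c=%g tol=%g max_iter=%d seed=%d init=%s\n",
    x$K, x$lambda_l, x$lambda_d, x$lambda_c, x$tol, x$max_iter, x$seed,
    x$init))
  invisible(x)
}

# K must fit inside the response matrix it is applied to.
validate_config <- function(cfg, m, n) {
  if (cfg$K > min(m, n))
    stop(sprintf("K = %d exceeds min(m, n) = %d for a %d x %d response matrix",
                 cfg$K, min(m, n), m, n))
  invisible(cfg)
}

#' Read a model configuration from a flat key-value file
#'
#' Accepts lines of the form `key = value` or `key: value`; blank lines
#' and `#` comments are ignored.  Recognized keys are the arguments of
#' [srmf_config()] (`K`, `lambda_l`, `lambda_d`, `lambda_c`, `tol`,
#' `max_iter`, `seed`, `init`); missing keys take the defaults.  Unknown
#' keys are an error so typos do not silently fall back to defaults.
#'
#' @param path path to the config file.
#' @param dims optional `c(m, n)` to validate `K` against.
#' @return an `srmf_config`.
#' @export
load_config <- function(path, dims = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L)
      stop("cannot parse config line: '", ln, "'")
    key <- m[2]; val <- trimws(m[3])
    known <- c("K", "lambda_l", "lambda_d", "lambda_c", "tol",
               "max_iter", "seed", "init")
    if (!key %in% known)
      stop("unknown config key: '", key, "'")
    args[[key]] <- if (key == "init") val else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("non-numeric value for config key '", key, "': ", val)
      num
    }
  }
  args$dims <- dims
  do.call(srmf_config, args)
}
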