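#' Configuration of a synthetic low-rank response problem
#'
#' Describes one simulated drug-response study: `m` drugs by `n` cell
#' lines with a rank-`k_true` noise-free target matrix, Gaussian
#' observation noise scaled relative to the spread of the target, and a
#' uniformly random missing pattern.  Defaults (`m = 100`, `n = 150`)
#' match the standard benchmark dimensions for this problem; `k_true`,
#' the noise range 0–0.5 and the 10% missing fraction are the package's
#' reference study conditions (see the methods vignette).
#'
#' @param m,n numbers of drugs and cell lines.
#' @param k_true latent rank of the target (`<= min(m, n)`).
#' @param noise_level Gaussian noise standard deviation as a fraction
#'   of the target entries' standard deviation, in `[0, 1]`.
#' @param missing_fraction fraction of entries masked as unobserved, in
#'   `[0, 1)`.
#' @param n_repeats repeats used by [run_noise_sweep()].
#' @param seed integer seed; every draw is reproducible from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(m = 100L, n = 150L, k_true = 10L,
                              noise_level = 0.1, missing_fraction = 0.1,
                              n_repeats = 200L, seed = 0L) {
  m <- as.integer(m); n <- as.integer(n); k_true <- as.integer(k_true)
  if (m < 2L || n < 2L) stop("`m` and `n` must be at least 2")
  if (k_true < 1L || k_true > min(m, n))
    stop("`k_true` must lie in 1..min(m, n)")
  if (!is.numeric(noise_level) || noise_level < 0 || noise_level > 1)
    stop("`noise_level` must lie in [0, 1]")
  if (!is.numeric(missing_fraction) ||
      missing_fraction < 0 || missing_fraction >= 1)
    stop("`missing_fraction` must lie in [0, 1)")
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) stop("`n_repeats` must be positive")
  structure(list(m = m, n = n, k_true = k_true,
                 noise_level = noise_level,
                 missing_fraction = missing_fraction,
                 n_repeats = n_repeats, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Draw one synthetic response problem with known ground truth
#'
#' Latent drug and cell-line coordinates are independent standard
#' normals; the noise-free target is their inner-product matrix
#' `Y* = U* V*'`.  Observed responses add independent Gaussian noise
#' with standard deviation `noise_level * sd(Y*)`, then a
#' `missing_fraction` of entries is masked uniformly at random.  The
#' drug similarity is the Pearson correlation between target drug rows
#' and the cell-line similarity between target columns, diagonals set
#' to 1 — so the similarities encode real structure about the truth, as
#' chemical and expression similarities are assumed to do for real
#' panels.
#'
#' @param cfg a [simulation_config()].
#' @return list with `response` (a [response_matrix()], noisy, masked),
#'   `target` (the noise-free m x n matrix), `Sd`, `Sc`
#'   ([similarity_matrix()] objects), and the generating factors
#'   `U_true`, `V_true`.
#' @export
simulate_instance <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(cfg$seed, {
    U <- matrix(stats::rnorm(cfg$m * cfg$k_true), cfg$m, cfg$k_true)
    V <- matrix(stats::rnorm(cfg$n * cfg$k_true), cfg$n, cfg$k_true)
    target <- tcrossprod(U, V)
    drug_ids <- sprintf("drug%03d", seq_len(cfg$m))
    cell_ids <- sprintf("cell%03d", seq_len(cfg$n))
    dimnames(target) <- list(drug_ids, cell_ids)
    sd_y <- stats::sd(as.vector(target))
    noisy <- target
    if (cfg$noise_level > 0)
      noisy <- noisy + matrix(stats::rnorm(cfg$m * cfg$n,
                                           sd = cfg$noise_level * sd_y),
                              cfg$m, cfg$n)
    n_missing <- floor(cfg$missing_fraction * cfg$m * cfg$n)
    if (n_missing > 0) {
      miss <- sample(cfg$m * cfg$n, n_missing)
      noisy[miss] <- NA_real_
    }
    Sd <- stats::cor(t(target))
    Sd <- (Sd + t(Sd)) / 2; diag(Sd) <- 1
    Sc <- stats::cor(target)
    Sc <- (Sc + t(Sc)) / 2; diag(Sc) <- 1
    list(response = response_matrix(noisy, "lower_is_sensitive"),
         target = target,
         Sd = similarity_matrix(Sd, kind = "pearson"),
         Sc = similarity_matrix(Sc, kind = "pearson"),
         U_true = U, V_true = V)
  })
}

#' Wrap a model configuration as a sweep-compatible predictor
#'
#' Returns a callable `function(response, Sd, Sc)` that fits the
#' factorization with the given configuration and returns the dense
#' prediction matrix; the shape [run_noise_sweep()] expects, so
#' external predictors can be benchmarked side by side.
#'
#' @param config an [srmf_config()].
#' @return a predictor closure.
#' @export
srmf_predictor <- function(config = srmf_config()) {
  force(config)
  function(response, Sd, Sc) {
    predict(srmf_fit(response, Sd = Sd, Sc = Sc, config = config))
  }
}

#' Benchmark predictors across noise levels
#'
#' For each noise level and repeat, draws a fresh instance
#' ([simulate_instance()]), fits every supplied predictor on the noisy
#' masked responses, and scores the predicted completed matrix against
#' the *noise-free* target (all entries) by drug-averaged PCC and RMSE.
#' Per-repeat seeds are derived deterministically from
#' `(cfg$seed, level index, repeat index)`, so results do not depend on
#' execution order.
#'
#' @param cfg base [simulation_config()]; its `noise_level` is
#'   overridden per sweep point and `n_repeats` gives the repeats.
#' @param noise_levels numeric vector of noise levels to sweep.
#' @param methods named list of predictor closures
#'   (`function(response, Sd, Sc) -> matrix`), e.g. from
#'   [srmf_predictor()].
#' @return data frame with one row per (method, noise level):
#'   `method`, `noise_level`, `n_repeats`, `pcc_mean`, `pcc_se`,
#'   `rmse_mean`, `rmse_se`.
#' @export
run_noise_sweep <- function(cfg,
                            noise_levels = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                            methods = list(srmf = srmf_predictor())) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (length(methods) == 0L || is.null(names(methods)))
    stop("`methods` must be a non-empty named list of predictors")
  if (length(noise_levels) == 0L) stop("`noise_levels` must be non-empty")
  rows <- list()
  for (li in seq_along(noise_levels)) {
    pcc <- matrix(NA_real_, cfg$n_repeats, length(methods))
    rmse <- matrix(NA_real_, cfg$n_repeats, length(methods))
    for (r in seq_len(cfg$n_repeats)) {
      icfg <- cfg
      icfg$noise_level <- noise_levels[li]
      icfg$seed <- as.integer((cfg$seed + 7919L * li + r) %% .Machine$integer.max)
      inst <- simulate_instance(icfg)
      truth <- response_matrix(inst$target, "lower_is_sensitive")
      for (mi in seq_along(methods)) {
        pred <- methods[[mi]](inst$response, inst$Sd, inst$Sc)
        rep <- evaluate_predictions(truth, pred)
        pcc[r, mi] <- rep$drug_averaged[["pcc"]]
        rmse[r, mi] <- rep$drug_averaged[["rmse"]]
      }
    }
    for (mi in seq_along(methods)) {
      rows[[length(rows) + 1L]] <- data.frame(
        method = names(methods)[mi],
        noise_level = noise_levels[li],
        n_repeats = cfg$n_repeats,
        pcc_mean = mean(pcc[, mi]),
        pcc_se = stats::sd(pcc[, mi]) / sqrt(cfg$n_repeats),
        rmse_mean = mean(rmse[, mi]),
        rmse_se = stats::sd(rmse[, mi]) / sqrt(cfg$n_repeats),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
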