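# Independent oracles and fixture builders shared across the suite.
# Every oracle is a deliberately naive re-implementation (scalar loops,
# brute-force enumeration) kept separate from the package's code paths.

# Scalar-loop evaluation of the regularized factorization objective.
naive_objective <- function(Y, W, U, V, Sd = NULL, Sc = NULL,
                            lambda_l = 0, lambda_d = 0, lambda_c = 0) {
  m <- nrow(Y); n <- ncol(Y); K <- ncol(U)
  total <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (W[i, j] != 0) {
      pred <- 0
      for (k in seq_len(K)) pred <- pred + U[i, k] * V[j, k]
      total <- total + (Y[i, j] - pred)^2
    }
  }
  for (i in seq_len(m)) for (k in seq_len(K))
    total <- total + lambda_l * U[i, k]^2
  for (j in seq_len(n)) for (k in seq_len(K))
    total <- total + lambda_l * V[j, k]^2
  if (lambda_d > 0) for (i in seq_len(m)) for (i2 in seq_len(m)) {
    ip <- 0
    for (k in seq_len(K)) ip <- ip + U[i, k] * U[i2, k]
    total <- total + lambda_d * (Sd[i, i2] - ip)^2
  }
  if (lambda_c > 0) for (j in seq_len(n)) for (j2 in seq_len(n)) {
    ip <- 0
    for (k in seq_len(K)) ip <- ip + V[j, k] * V[j2, k]
    total <- total + lambda_c * (Sc[j, j2] - ip)^2
  }
  total
}

# Set-based Jaccard over two fingerprint rows.
naive_jaccard <- function(a, b) {
  sa <- which(a == 1); sb <- which(b == 1)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

# Brute-force one-sided Mann-Whitney p-value P(U_perm >= U_obs) by
# enumerating every assignment of pooled values to the first sample.
enumerate_mw_p <- function(x, y, alternative = "greater") {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(xs, ys)
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_stat(x, y)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  if (alternative == "greater") mean(us >= u_obs - 1e-9)
  else mean(us <= u_obs + 1e-9)
}

# Naive per-drug metrics loop mirroring the documented definitions.
naive_metrics <- function(R, predicted, heldout) {
  out <- NULL
  for (i in seq_len(nrow(R$values))) {
    cols <- heldout[heldout[, 1] == i, 2]
    obs <- R$values[i, cols]; pred <- predicted[i, cols]
    pcc <- if (length(cols) >= 3 && stats::sd(obs) > 0 && stats::sd(pred) > 0)
      sum((obs - mean(obs)) * (pred - mean(pred))) /
        sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
      else NA_real_
    rmse <- if (length(cols) >= 1) sqrt(sum((obs - pred)^2) / length(cols))
      else NA_real_
    full <- R$values[i, R$mask[i, ]]
    if (length(full) >= 8) {
      q <- stats::quantile(full, c(.25, .75), names = FALSE)
      sr_cells <- names(full)[full <= q[1] | full >= q[2]]
      if (q[1] >= q[2]) sr_cells <- character(0)
    } else sr_cells <- character(0)
    keep <- R$cell_ids[cols] %in% sr_cells
    obs_sr <- obs[keep]; pred_sr <- pred[keep]
    pcc_sr <- if (sum(keep) >= 3 && stats::sd(obs_sr) > 0 &&
                  stats::sd(pred_sr) > 0) stats::cor(obs_sr, pred_sr)
      else NA_real_
    rmse_sr <- if (sum(keep) >= 1)
      sqrt(mean((obs_sr - pred_sr)^2)) else NA_real_
    out <- rbind(out, data.frame(pcc = pcc, rmse = rmse,
                                 pcc_sr = pcc_sr, rmse_sr = rmse_sr))
  }
  out
}

# Random small response fixture with ids and a controlled missing rate.
random_response <- function(m, n, missing = 0.2, seed = 1,
                            direction = "lower_is_sensitive") {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(m * n), m, n,
                   dimnames = list(sprintf("d%02d", 1:m),
                                   sprintf("c%02d", 1:n)))
    n_miss <- floor(missing * m * n)
    if (n_miss > 0) vals[sample(m * n, n_miss)] <- NA
    # keep at least one observed entry
    if (all(is.na(vals))) vals[1, 1] <- 0.5
    response_matrix(vals, direction)
  })
}

# Access the package's fold-masking helper without exporting it.
mask_fold_for_test <- function(R, folds, j) srmf:::mask_fold(R, folds, j)

# Random binary fingerprint fixture with no all-zero rows.
random_fingerprints <- function(m, bits, seed = 1) {
  withr::with_seed(seed, {
    F <- matrix(rbinom(m * bits, 1, 0.4), m, bits,
                dimnames = list(sprintf("d%02d", 1:m),
                                sprintf("b%02d", 1:bits)))
    zero <- rowSums(F) == 0
    F[zero, 1] <- 1
    F
  })
}
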