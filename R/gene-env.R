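#' Standardize population allele frequencies per SNP
#'
#' Each SNP's frequency vector is centred on its unweighted across-
#' population mean and scaled by the binomial standard deviation at that
#' mean: `y_l = (p_l - pbar) / sqrt(pbar (1 - pbar))`. SNPs fixed across
#' all populations (`pbar` of 0 or 1) are dropped.
#'
#' @param freqs L populations x m SNPs frequency matrix.
#' @return Standardized matrix (columns of dropped SNPs removed), with
#'   attribute `dropped` holding the dropped SNP names/indices.
#' @export
standardize_freqs <- function(freqs) {
  stopifnot(is.matrix(freqs))
  pbar <- colMeans(freqs)
  keep <- pbar > 0 & pbar < 1
  y <- sweep(freqs[, keep, drop = FALSE], 2L, pbar[keep], `-`)
  y <- sweep(y, 2L, sqrt(pbar[keep] * (1 - pbar[keep])), `/`)
  dropped <- if (is.null(colnames(freqs))) which(!keep)
             else colnames(freqs)[!keep]
  attr(y, "dropped") <- dropped
  y
}

#' Moment-based population covariance of standardized frequencies
#'
#' The null model for the environmental test is that standardized SNP
#' frequency vectors are draws from a multivariate normal with a shared
#' population covariance `omega`, reflecting drift and shared history.
#' `omega` is estimated as the empirical second-moment matrix over control
#' SNPs, shrunk toward its own diagonal for numerical stability:
#' `omega = (1 - shrinkage) * S + shrinkage * diag(S)`.
#'
#' @param y_controls Standardized L x m matrix of control SNPs (see
#'   [standardize_freqs()]).
#' @param shrinkage Mixing weight toward the diagonal, in `[0, 1]`
#'   (default 0.05).
#' @return A `covariance_model`: list with `populations`, `omega`,
#'   `shrinkage` and `min_eigenvalue`.
#' @export
estimate_covariance <- function(y_controls, shrinkage = 0.05) {
  stopifnot(is.matrix(y_controls), shrinkage >= 0, shrinkage <= 1)
  L <- nrow(y_controls); m <- ncol(y_controls)
  if (m < 10L * L)
    warning("fewer than 10 x n_pops control SNPs; covariance may be noisy")
  s_hat <- tcrossprod(y_controls) / m
  omega <- (1 - shrinkage) * s_hat + shrinkage * diag(diag(s_hat), L)
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("covariance not positive definite after shrinkage; smallest ",
         "eigenvalue ", format(min(ev)))
  structure(list(populations = rownames(y_controls) %||%
                   paste0("POP", seq_len(L) - 1L),
                 omega = omega, shrinkage = shrinkage,
                 min_eigenvalue = min(ev)),
            class = "covariance_model")
}

# log N(y; mu, omega) up to no constant dropping (full log density)
mvn_logdens <- function(y, mu, chol_omega) {
  L <- length(y)
  z <- backsolve(chol_omega, y - mu, transpose = TRUE)
  -0.5 * L * log(2 * pi) - sum(log(diag(chol_omega))) - 0.5 * sum(z^2)
}

#' Bayes factor for a linear environmental effect on allele frequencies
#'
#' Compares the model in which the standardized frequency vector has mean
#' `beta * env` (with `beta` uniform on `(-beta_bound, beta_bound)`,
#' integrated over an equally spaced grid) against the covariance-only
#' null (`beta = 0`), both with covariance `omega`:
#' `bf = mean_beta N(y; beta env, omega) / N(y; 0, omega)`.
#'
#' @param y Standardized frequency vector (length L).
#' @param env Environmental vector standardized to mean 0, sd 1 across the
#'   L populations.
#' @param model A `covariance_model` from [estimate_covariance()].
#' @param beta_bound Half-width of the uniform prior on beta (default 0.3).
#' @param grid_points Number of grid points (default 201).
#' @return A list with `bf`, `beta_grid` and `log_lik` (per-grid-point log
#'   likelihood, for diagnostics).
#' @export
env_bayes_factor <- function(y, env, model, beta_bound = 0.3,
                             grid_points = 201L) {
  stopifnot(inherits(model, "covariance_model"),
            length(y) == nrow(model$omega), length(env) == length(y),
            beta_bound > 0, grid_points >= 3L)
  ch <- tryCatch(chol(model$omega), error = function(e) {
    ev <- eigen(model$omega, symmetric = TRUE, only.values = TRUE)$values
    stop("singular covariance; smallest eigenvalue ", format(min(ev)))
  })
  grid <- seq(-beta_bound, beta_bound, length.out = grid_points)
  ll <- vapply(grid, function(b) mvn_logdens(y, b * env, ch), numeric(1))
  ll0 <- mvn_logdens(y, 0 * env, ch)
  bf <- mean(exp(ll - ll0))
  list(bf = bf, beta_grid = grid, log_lik = ll)
}

#' Scan SNPs for allele-frequency/environment correlation
#'
#' Standardizes the frequency matrix, fits one covariance model per scan
#' from the control SNPs, z-standardizes each environmental variable across
#' populations, and computes a Bayes factor for every (SNP, environment)
#' pair.
#'
#' @param freqs L x m population frequency matrix (rownames = population
#'   codes).
#' @param env_table An `env_table` data.frame (see [read_env_table()]);
#'   rows are matched to `rownames(freqs)`.
#' @param control_snps Character vector (or indices) of control SNP columns
#'   used for covariance estimation.
#' @param shrinkage,beta_bound,grid_points See [estimate_covariance()] and
#'   [env_bayes_factor()].
#' @param absolute_latitude If `TRUE` (default), a column named `latitude`
#'   is replaced by its absolute value before standardization, matching a
#'   sunlight-exposure reading of latitude.
#' @return A data.frame (`snp`, `env`, `bf`) sorted by `bf` descending,
#'   with the fitted `covariance_model` as attribute `model`.
#' @export
env_scan <- function(freqs, env_table, control_snps, shrinkage = 0.05,
                     beta_bound = 0.3, grid_points = 201L,
                     absolute_latitude = TRUE) {
  stopifnot(is.matrix(freqs))
  pops <- rownames(freqs)
  missing <- setdiff(pops, rownames(env_table))
  if (length(missing))
    stop("population(s) without environment data: ",
         paste(missing, collapse = ", "))
  env <- as.matrix(env_table[pops, , drop = FALSE])
  if (absolute_latitude && "latitude" %in% colnames(env))
    env[, "latitude"] <- abs(env[, "latitude"])
  y_all <- standardize_freqs(freqs)
  ctrl <- if (is.character(control_snps))
    intersect(control_snps, colnames(y_all)) else control_snps
  model <- estimate_covariance(y_all[, ctrl, drop = FALSE],
                               shrinkage = shrinkage)
  rows <- list()
  for (v in colnames(env)) {
    e <- as.numeric(scale(env[, v]))
    if (!all(is.finite(e))) stop("environment '", v, "' has zero variance")
    bf <- apply(y_all, 2L, function(y)
      env_bayes_factor(y, e, model, beta_bound, grid_points)$bf)
    rows[[v]] <- data.frame(snp = colnames(y_all), env = v, bf = bf,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(-out$bf), ]
  attr(out, "model") <- model
  out
}
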