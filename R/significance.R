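#' Estimate the measurement-noise scale in ln space
#'
#' Two routes:
#' \describe{
#'   \item{replicates}{with `replicate_groups`, the root-mean-square deviation
#'     of ln intensities from their within-group means, pooled over all sites
#'     and groups (groups of size 1 contribute nothing).}
#'   \item{residual}{without replicates, the singular-value scree of the
#'     ln-matrix is cut at its elbow (largest ratio of consecutive singular
#'     values) and the noise scale is the robust spread — `1.4826 * MAD`
#'     about zero — of the residual after reconstructing the retained
#'     components.  The median absolute deviation tolerates the sparse tail
#'     signal that a misplaced elbow can leave in the residual.}
#' }
#' A relative numerical floor of \eqn{10^{-12}\sigma_0} keeps the scale
#' strictly positive on noiseless input so that downstream thresholds sit
#' above floating-point jitter.
#'
#' @param y a `log_quant_matrix` or complete numeric ln-matrix.
#' @param replicate_groups optional vector (length = samples) assigning
#'   samples to replicate groups; at least one group must have >= 2 members.
#' @return An object of class `noise_model`: list with `sd_ln` (noise
#'   standard deviation in ln space), `method` (`"replicates"` or
#'   `"residual"`), and `details`.
#' @export
estimate_noise <- function(y, replicate_groups = NULL) {
  Y <- if (inherits(y, "log_quant_matrix")) y$log_values else as.matrix(y)
  if (any(!is.finite(Y))) stop_passs("'y' contains non-finite entries")
  if (!is.null(replicate_groups)) {
    if (length(replicate_groups) != ncol(Y))
      stop_passs("'replicate_groups' must assign every sample")
    g <- as.factor(replicate_groups)
    sizes <- table(g)
    if (!any(sizes >= 2L))
      stop_passs("at least one replicate group needs >= 2 samples")
    dev2 <- 0; n_dev <- 0L
    for (lev in levels(g)[sizes >= 2L]) {
      cols <- which(g == lev)
      sub <- Y[, cols, drop = FALSE]
      dev <- sub - rowMeans(sub)
      dev2 <- dev2 + sum(dev^2)
      n_dev <- n_dev + length(dev)
    }
    sd_ln <- sqrt(dev2 / n_dev)
    if (sd_ln == 0)
      stop_passs(paste("replicate columns are identical (sd_ln = 0);",
                       "pass an explicit noise floor instead"))
    return(structure(list(sd_ln = sd_ln, method = "replicates",
                          details = list(n_groups = sum(sizes >= 2L),
                                         n_deviations = n_dev)),
                     class = "noise_model"))
  }
  sv <- svd(Y)
  d <- sv$d[sv$d > 0]
  elbow <- if (length(d) >= 2L) which.max(d[-length(d)] / d[-1L]) else 1L
  idx <- seq_len(elbow)
  res <- Y - sv$u[, idx, drop = FALSE] %*%
    (t(sv$v[, idx, drop = FALSE]) * sv$d[idx])
  sd_ln <- stats::mad(as.vector(res), center = 0)
  floor_sd <- 1e-12 * sv$d[1L]
  structure(list(sd_ln = max(sd_ln, floor_sd), method = "residual",
                 details = list(elbow = elbow, mad = sd_ln,
                                floor = floor_sd)),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("noise_model: sd_ln = %.4g (%s)\n", x$sd_ln, x$method))
  invisible(x)
}

#' Amplitude significance threshold from a noise-floor null
#'
#' How large can a process amplitude get by measurement noise alone?  The
#' null decomposes `n_null` pure-noise matrices of the same shape as the data
#' (i.i.d. Gaussian in ln space with the estimated noise sd) and records the
#' maximum absolute amplitude each produces.  The threshold is the `level`
#' quantile of those maxima, applied identically to every process: an
#' observed \eqn{|\lambda_\alpha(k)|} above it cannot plausibly be a noise
#' artifact.  Thresholding against the common noise envelope avoids having to
#' match null components to data components.  Deterministic given `seed`.
#'
#' @param d a [surprisal()] decomposition (supplies the matrix shape).
#' @param noise a `noise_model` from [estimate_noise()], or a positive number.
#' @param n_null number of null decompositions (>= 100).
#' @param level confidence level in (0, 1).
#' @param seed integer seed for the null simulation.
#' @return single threshold `T` (>= 0); `sd_ln = 0` degenerates to `T = 0`.
#' @export
amplitude_threshold <- function(d, noise, n_null = 200L, level = 0.95,
                                seed = 1L) {
  stopifnot(inherits(d, "surprisal"))
  sd_ln <- if (inherits(noise, "noise_model")) noise$sd_ln else noise
  if (!is.numeric(sd_ln) || length(sd_ln) != 1L || !is.finite(sd_ln) || sd_ln < 0)
    stop_passs("noise sd must be a single finite number >= 0")
  if (n_null < 100L) stop_passs("'n_null' must be >= 100")
  assert_scalar_number(level, "level", lower = 1e-9, upper = 1 - 1e-9)
  if (sd_ln == 0) return(0)
  p <- nrow(d$y); k <- ncol(d$y)
  maxima <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      e <- matrix(stats::rnorm(p * k, sd = sd_ln), p, k)
      sv <- svd(e, nu = 0)
      max(abs(t(sv$v) * sv$d))             # max |lambda_alpha(k)| of the null
    }, numeric(1L))
  })
  unname(stats::quantile(maxima, probs = level, type = 7))
}

#' Choose the number of real unbalanced processes
#'
#' `n_star` is the smallest `n` for which the root-mean-square residual of
#' the `n`-process reconstruction is at or below the measurement-noise scale
#' (the truncated components are then indistinguishable from noise), capped
#' at `n_processes`; this is intersected with the significance gate: every
#' retained process must carry a significant amplitude in at least one
#' sample, so trailing processes that never rise above the noise envelope are
#' dropped.
#'
#' @param d a [surprisal()] decomposition.
#' @param noise a `noise_model` or a positive number (sd in ln space).
#' @param threshold amplitude threshold from [amplitude_threshold()].
#' @return integer `n_star >= 0` (0 = steady state alone suffices).
#' @export
select_num_processes <- function(d, noise, threshold) {
  stopifnot(inherits(d, "surprisal"))
  sd_ln <- if (inherits(noise, "noise_model")) noise$sd_ln else noise
  n_rms <- d$n_processes
  for (n in 0:d$n_processes) {
    if (rms_residual(d, n) <= sd_ln) { n_rms <- n; break }
  }
  n_star <- 0L
  for (a in seq_len(n_rms)) {
    if (any(abs(d$amplitudes[a + 1L, ]) > threshold)) n_star <- a
    else break
  }
  n_star
}

#' Per-sample significance mask for the retained processes
#'
#' @param d a [surprisal()] decomposition.
#' @param n_star retained process count from [select_num_processes()].
#' @param threshold amplitude threshold from [amplitude_threshold()].
#' @param per_sample if `TRUE` (default) each cell is gated on its own
#'   amplitude; if `FALSE` a process significant in any sample is marked
#'   active in all samples where its amplitude is nonzero (global gating).
#' @return logical matrix (`n_star` x samples): `TRUE` iff
#'   \eqn{|\lambda_\alpha(k)| > T}.
#' @export
significance_mask <- function(d, n_star, threshold, per_sample = TRUE) {
  stopifnot(inherits(d, "surprisal"))
  if (n_star > d$n_processes) stop_passs("'n_star' exceeds available processes")
  amp <- d$amplitudes[seq_len(n_star) + 1L, , drop = FALSE]
  mask <- abs(amp) > threshold
  if (!per_sample && n_star > 0L) {
    proc_sig <- rowSums(mask) > 0L
    mask <- (amp != 0) & proc_sig
  }
  dimnames(mask) <- dimnames(amp)
  mask
}
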