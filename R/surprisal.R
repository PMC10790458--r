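#' Surprisal decomposition of a ln-intensity matrix
#'
#' Factorizes the complete matrix of natural-log intensities
#' \eqn{Y_{ik} = \ln X_i(k)} as
#' \deqn{\ln X_i(k) = \sum_{\alpha=0}^{r} G_{i\alpha}\,\lambda_\alpha(k),}
#' the surprisal-analysis form: the dominant term \eqn{\alpha = 0} is the
#' steady state (the expression pattern free of constraints) and each further
#' term is an unbalanced process — a weight vector \eqn{G_{\cdot\alpha}} over
#' sites times an amplitude \eqn{\lambda_\alpha(k)} per sample.  The matrix is
#' deliberately **not** mean-centered: diagonalizing the uncentered covariance
#' lets the steady state emerge as the leading component, which is what
#' distinguishes this decomposition from PCA.
#'
#' Computationally the factorization is the singular value decomposition of
#' `Y` (equivalent to diagonalizing the sample covariance but better
#' conditioned): weights are the left singular vectors and
#' \eqn{\lambda_\alpha(k) = \sigma_\alpha v_{k\alpha}} absorbs the singular
#' value into the amplitude.  Singular vectors are only defined up to sign;
#' each weight column is oriented so that its largest-magnitude entry is
#' positive, and amplitudes flip accordingly, making all downstream signs
#' deterministic.  Components with \eqn{\sigma < 10^{-12}\sigma_0} are
#' truncated as numerical noise.
#'
#' @param y a `log_quant_matrix` (see [impute_and_log()]), or a complete
#'   finite numeric matrix of ln intensities (sites x samples).
#'
#' @return An object of class `surprisal` with components:
#'   \describe{
#'     \item{weights}{sites x (r+1) matrix `G`, orthonormal columns
#'       `alpha0..alphar`; `alpha0` is the steady-state pattern.}
#'     \item{amplitudes}{(r+1) x samples matrix, row `alpha` holding
#'       \eqn{\lambda_\alpha(k)}.}
#'     \item{sigma}{non-increasing singular values.}
#'     \item{n_processes}{number of unbalanced processes `r` (rank - 1).}
#'   }
#' @seealso [reconstruct()], [process_contribution()], [steady_state()]
#' @examples
#' y <- matrix(c(3, 1, 1, 3), 2, 2)
#' d <- surprisal(y)
#' d$sigma  # 4 and 2
#' @export
surprisal <- function(y) {
  Y <- if (inherits(y, "log_quant_matrix")) y$log_values else as.matrix(y)
  if (!is.numeric(Y)) stop_passs("'y' must be numeric")
  if (any(!is.finite(Y))) stop_passs("'y' contains non-finite entries")
  if (ncol(Y) < 2L) stop_passs("at least 2 samples are required")
  if (nrow(Y) < 2L) stop_passs("at least 2 sites are required")
  if (is.null(rownames(Y))) rownames(Y) <- paste0("site_", seq_len(nrow(Y)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("sample_", seq_len(ncol(Y)))

  sv <- svd(Y)
  d <- sv$d
  r <- max(1L, sum(d > 1e-12 * d[1L]))
  if (r > 1L) {
    rel_gap <- abs(diff(d[seq_len(r)])) / d[1L]
    if (any(rel_gap < 1e-10))
      warning("near-degenerate singular values; component order follows the factorization",
              call. = FALSE)
  }
  u <- sv$u[, seq_len(r), drop = FALSE]
  v <- sv$v[, seq_len(r), drop = FALSE]
  d <- d[seq_len(r)]
  # orientation: largest-|entry| of each weight column made positive
  for (j in seq_len(r)) {
    i_star <- which.max(abs(u[, j]))
    if (u[i_star, j] < 0) {
      u[, j] <- -u[, j]
      v[, j] <- -v[, j]
    }
  }
  amp <- t(v) * d                       # row alpha: sigma_alpha * v[, alpha]
  alpha_names <- paste0("alpha", seq_len(r) - 1L)
  dimnames(u) <- list(rownames(Y), alpha_names)
  dimnames(amp) <- list(alpha_names, colnames(Y))
  site_info <- if (inherits(y, "log_quant_matrix"))
    data.frame(site_id = rownames(Y), protein = y$protein,
               site_label = y$site_label, stringsAsFactors = FALSE)
  else {
    parts <- strsplit(rownames(Y), "|", fixed = TRUE)
    data.frame(site_id = rownames(Y),
               protein = vapply(parts, `[`, "", 1L),
               site_label = vapply(parts, function(p)
                 if (length(p) > 1L) paste(p[-1L], collapse = "|") else "", ""),
               stringsAsFactors = FALSE)
  }
  structure(list(weights = u, amplitudes = amp, sigma = d,
                 n_processes = r - 1L, y = Y, site_info = site_info),
            class = "surprisal")
}

#' @export
print.surprisal <- function(x, ...) {
  cat(sprintf("surprisal decomposition: %d sites x %d samples, steady state + %d process(es)\n",
              nrow(x$weights), ncol(x$amplitudes), x$n_processes))
  cat("sigma:", paste(signif(utils::head(x$sigma, 6), 4), collapse = ", "),
      if (length(x$sigma) > 6) "..." else "", "\n")
  invisible(x)
}

#' Truncated reconstruction of the ln-intensity matrix
#'
#' Returns the steady state plus the first `n` unbalanced processes,
#' \eqn{\sum_{\alpha=0}^{n} G_{\cdot\alpha}\lambda_\alpha(\cdot)}.  The
#' Frobenius residual against the input is non-increasing in `n`; at
#' `n = n_processes` the input is reproduced to machine tolerance.
#'
#' @param d a [surprisal()] decomposition.
#' @param n number of processes to keep (0 = steady state only).
#' @return ln-matrix of the same shape as the input.
#' @export
reconstruct <- function(d, n) {
  stopifnot(inherits(d, "surprisal"))
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 0 ||
      n > d$n_processes)
    stop_passs("'n' must be an integer in 0..%d", d$n_processes)
  idx <- seq_len(n + 1L)
  d$weights[, idx, drop = FALSE] %*% d$amplitudes[idx, , drop = FALSE]
}

#' Signed contribution of one unbalanced process
#'
#' The per-site, per-sample deviation a process imposes on the ln levels:
#' \eqn{C_{ik} = G_{i\alpha}\lambda_\alpha(k)}.  Positive entries mean the
#' process raises site `i` above its steady-state prediction in sample `k`
#' (induced); negative entries mean it is lowered (repressed).
#'
#' @param d a [surprisal()] decomposition.
#' @param alpha process index, `1..n_processes` (the steady state `alpha = 0`
#'   is not an unbalanced process and is rejected).
#' @return sites x samples matrix of signed ln contributions.
#' @export
process_contribution <- function(d, alpha) {
  stopifnot(inherits(d, "surprisal"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha != round(alpha) ||
      alpha < 1 || alpha > d$n_processes)
    stop_passs("'alpha' must be a process index in 1..%d (0 is the steady state)",
               d$n_processes)
  tcrossprod(d$weights[, alpha + 1L], d$amplitudes[alpha + 1L, ])
}

#' Steady-state term of the decomposition
#'
#' The `alpha = 0` term \eqn{G_{\cdot 0}\lambda_0(\cdot)}: predicted ln levels
#' in the absence of constraints.
#'
#' @param d a [surprisal()] decomposition.
#' @return sites x samples ln-matrix.
#' @export
steady_state <- function(d) {
  stopifnot(inherits(d, "surprisal"))
  tcrossprod(d$weights[, 1L], d$amplitudes[1L, ])
}

# Root-mean-square residual of the n-process reconstruction, computed from
# the truncated singular spectrum (Parseval) without forming matrices.
rms_residual <- function(d, n) {
  r <- length(d$sigma)
  drop_sq <- if (n + 1L >= r) 0 else sum(d$sigma[(n + 2L):r]^2)
  sqrt(drop_sq / length(d$y))
}

#' Export a decomposition as tab-separated tables
#'
#' Writes `weights.tsv` (site x alpha), `amplitudes.tsv` (alpha x sample) and
#' `sigma.tsv` into `dir`; output is byte-stable across runs on identical
#' input.
#'
#' @param d a [surprisal()] decomposition.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_decomposition <- function(d, dir) {
  stopifnot(inherits(d, "surprisal"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(d$weights, file.path(dir, "weights.tsv"), "site_id")
  write_matrix_tsv(d$amplitudes, file.path(dir, "amplitudes.tsv"), "alpha")
  sig <- matrix(d$sigma, ncol = 1L,
                dimnames = list(rownames(d$amplitudes), "sigma"))
  write_matrix_tsv(sig, file.path(dir, "sigma.tsv"), "alpha")
  invisible(dir)
}
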