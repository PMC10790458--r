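#' Fit patient-specific signaling signatures
#'
#' The central fitting function.  Runs the full statistical chain on a
#' phosphosite quantification matrix:
#' \enumerate{
#'   \item imputation and ln transform (if given raw intensities; see
#'     [impute_and_log()]);
#'   \item surprisal decomposition into steady state + unbalanced processes
#'     ([surprisal()]);
#'   \item measurement-noise estimation ([estimate_noise()]), amplitude
#'     significance threshold from a simulated noise null
#'     ([amplitude_threshold()]), retained process count
#'     ([select_num_processes()]) and per-sample significance mask
#'     ([significance_mask()]);
#'   \item per-sample signatures: the set of significantly active processes
#'     with their amplitude signs.
#' }
#'
#' @param x a [quant_matrix()], a `log_quant_matrix`, or a numeric matrix of
#'   positive intensities (sites x samples).
#' @param floor_fraction left-censoring imputation fraction (see
#'   [impute_and_log()]).
#' @param noise_sd optional known noise sd in ln space; when `NULL` it is
#'   estimated from `replicate_groups` or from the factorization residual.
#' @param replicate_groups optional sample grouping for replicate-based noise
#'   estimation.
#' @param level confidence level of the amplitude gate (default 0.95).
#' @param n_null number of null decompositions for the threshold (default 200).
#' @param per_sample gate significance per sample (default) or per process.
#' @param seed integer seed for the threshold simulation.
#'
#' @return An object of class `passs`: list with `decomposition`
#'   (a [surprisal()] fit), `noise`, `threshold`, `n_star`, `mask`,
#'   `signatures` (see [signatures()]), `barcode` (see [passs_barcode()]),
#'   `level`, `n_null`, `seed`, `call`.
#' @examples
#' sim <- simulate_cohort(preset_cohort("paperlike_subset"))
#' fit <- passs(sim$quant, seed = 7)
#' fit
#' passs_barcode(fit)
#' @export
passs <- function(x, floor_fraction = 0.5, noise_sd = NULL,
                  replicate_groups = NULL, level = 0.95, n_null = 200L,
                  per_sample = TRUE, seed = 1L) {
  lq <- as_log_quant(x, floor_fraction)
  d <- surprisal(lq)
  noise <- if (!is.null(noise_sd)) {
    assert_scalar_number(noise_sd, "noise_sd", lower = 0)
    structure(list(sd_ln = noise_sd, method = "supplied", details = list()),
              class = "noise_model")
  } else estimate_noise(lq, replicate_groups)
  thr <- amplitude_threshold(d, noise, n_null = n_null, level = level,
                             seed = seed)
  n_star <- select_num_processes(d, noise, thr)
  mask <- significance_mask(d, n_star, thr, per_sample = per_sample)
  fit <- structure(list(decomposition = d, noise = noise, threshold = thr,
                        n_star = n_star, mask = mask, level = level,
                        n_null = n_null, seed = seed, call = match.call()),
                   class = "passs")
  fit$signatures <- signatures(fit)
  fit$barcode <- passs_barcode(fit)
  fit
}

#' Per-sample signaling signatures
#'
#' A sample's signature is the list of processes whose amplitude passes the
#' significance gate in that sample, with the amplitude's sign and value.  A
#' sample may have an empty signature (steady state only).
#'
#' @param fit a [passs()] fit.
#' @return named list (one per sample) of data frames with columns `alpha`,
#'   `sign`, `amplitude`, ordered by `alpha`.
#' @export
signatures <- function(fit) {
  stopifnot(inherits(fit, "passs"))
  d <- fit$decomposition
  samples <- colnames(d$amplitudes)
  out <- lapply(seq_along(samples), function(k) {
    act <- if (fit$n_star > 0L) which(fit$mask[, k]) else integer()
    data.frame(alpha = as.integer(act),
               sign = as.integer(sign(d$amplitudes[act + 1L, k])),
               amplitude = unname(d$amplitudes[act + 1L, k]),
               stringsAsFactors = FALSE)
  })
  names(out) <- samples
  out
}

#' Sign barcode of a cohort
#'
#' Samples x retained-processes matrix with entries `+1` (process
#' significantly active with positive amplitude; red in the usual display),
#' `-1` (negative; blue) or `0` (inactive; white).  Signs inherit the
#' deterministic component orientation of [surprisal()], so barcodes are
#' reproducible across runs but only comparable within one decomposition.
#'
#' @param fit a [passs()] fit.
#' @return integer matrix (samples x `n_star`), possibly with zero columns.
#' @export
passs_barcode <- function(fit) {
  stopifnot(inherits(fit, "passs"))
  d <- fit$decomposition
  samples <- colnames(d$amplitudes)
  bc <- matrix(0L, length(samples), fit$n_star,
               dimnames = list(samples,
                               if (fit$n_star > 0L)
                                 paste0("process", seq_len(fit$n_star))))
  if (fit$n_star > 0L) {
    amp <- d$amplitudes[seq_len(fit$n_star) + 1L, , drop = FALSE]
    bc[] <- t(ifelse(fit$mask, sign(amp), 0L))
  }
  bc
}

#' Sample coordinates in process space
#'
#' Raw amplitudes \eqn{\lambda_\alpha(k)} of the retained processes, one
#' coordinate per process: the nD map in which samples separate by their
#' active processes.  Coordinates are not significance-zeroed (that is the
#' barcode's job) and not normalized.
#'
#' @param fit a [passs()] fit.
#' @return numeric matrix (samples x `n_star`).
#' @export
map_coordinates <- function(fit) {
  stopifnot(inherits(fit, "passs"))
  if (fit$n_star < 1L)
    stop_passs("n_star = 0: no unbalanced processes to map")
  m <- t(fit$decomposition$amplitudes[seq_len(fit$n_star) + 1L, , drop = FALSE])
  colnames(m) <- paste0("process", seq_len(fit$n_star))
  m
}

#' @export
print.passs <- function(x, ...) {
  d <- x$decomposition
  cat(sprintf("PaSSS fit: %d sites x %d samples\n", nrow(d$weights),
              ncol(d$amplitudes)))
  cat(sprintf("  noise sd (ln): %.4g (%s);  amplitude threshold: %.4g (level %.2f)\n",
              x$noise$sd_ln, x$noise$method, x$threshold, x$level))
  cat(sprintf("  retained unbalanced processes (n*): %d\n", x$n_star))
  sizes <- vapply(x$signatures, nrow, 0L)
  cat(sprintf("  active processes per sample: mean %.2f, range %d-%d\n",
              mean(sizes), min(sizes), max(sizes)))
  invisible(x)
}

#' @export
summary.passs <- function(object, ...) {
  sizes <- vapply(object$signatures, nrow, 0L)
  out <- list(n_sites = nrow(object$decomposition$weights),
              n_samples = ncol(object$decomposition$amplitudes),
              n_star = object$n_star,
              noise_sd = object$noise$sd_ln,
              threshold = object$threshold,
              level = object$level,
              signature_sizes = sizes,
              mean_active = mean(sizes),
              barcode = object$barcode)
  class(out) <- "summary.passs"
  out
}

#' @export
print.summary.passs <- function(x, ...) {
  cat(sprintf("PaSSS summary: %d sites, %d samples, n* = %d\n",
              x$n_sites, x$n_samples, x$n_star))
  cat(sprintf("noise sd %.4g, threshold %.4g at level %.2f\n",
              x$noise_sd, x$threshold, x$level))
  cat(sprintf("mean active processes per sample: %.2f\n", x$mean_active))
  if (x$n_star > 0L) {
    cat("barcode (+1 red / -1 blue / 0 white):\n")
    print(x$barcode)
  }
  invisible(x)
}

#' Extract weights or amplitudes from a fit
#'
#' @param object a [passs()] fit.
#' @param type `"weights"` for the site x component matrix `G`, or
#'   `"amplitudes"` for the component x sample matrix of
#'   \eqn{\lambda_\alpha(k)}.
#' @param ... unused.
#' @export
coef.passs <- function(object, type = c("weights", "amplitudes"), ...) {
  type <- match.arg(type)
  if (type == "weights") object$decomposition$weights
  else object$decomposition$amplitudes
}

#' Reconstructed ln intensities from a fit
#'
#' @param object a [passs()] fit.
#' @param n_processes number of processes in the truncated reconstruction;
#'   defaults to the retained `n_star`.
#' @param ... unused.
#' @return ln-matrix (sites x samples).
#' @export
predict.passs <- function(object, n_processes = object$n_star, ...) {
  reconstruct(object$decomposition, n_processes)
}

#' @export
fitted.passs <- function(object, ...) predict(object)

#' Residual ln intensities after the retained processes
#'
#' @param object a [passs()] fit.
#' @param ... passed to [predict.passs()].
#' @export
residuals.passs <- function(object, ...) {
  object$decomposition$y - predict(object, ...)
}

#' Plot a PaSSS fit
#'
#' @param x a [passs()] fit.
#' @param type `"map"` (samples in the space of the first two process
#'   amplitudes), `"barcode"` (red/blue/white sign image) or `"scree"`
#'   (singular values).
#' @param ... passed to the underlying base-graphics call.
#' @export
plot.passs <- function(x, type = c("map", "barcode", "scree"), ...) {
  type <- match.arg(type)
  d <- x$decomposition
  if (type == "scree") {
    graphics::plot(seq_along(d$sigma) - 1L, d$sigma, log = "y",
                   xlab = expression(alpha), ylab = expression(sigma[alpha]),
                   main = "Singular-value scree", ...)
    graphics::abline(v = x$n_star + 0.5, lty = 2)
  } else if (type == "map") {
    m <- map_coordinates(x)
    xs <- m[, 1L]
    ys <- if (ncol(m) >= 2L) m[, 2L] else rep(0, nrow(m))
    graphics::plot(xs, ys, xlab = expression(lambda[1](k)),
                   ylab = if (ncol(m) >= 2L) expression(lambda[2](k)) else "",
                   main = "Sample map", ...)
    graphics::abline(h = 0, v = 0, col = "grey70")
    graphics::text(xs, ys, rownames(m), pos = 3, cex = 0.7)
  } else {
    bc <- x$barcode
    if (ncol(bc) == 0L) stop_passs("n_star = 0: nothing to draw")
    img <- t(bc)[, rev(seq_len(nrow(bc))), drop = FALSE]
    graphics::image(seq_len(ncol(bc)), seq_len(nrow(bc)), img,
                    col = c("#2166AC", "white", "#B2182B"),
                    breaks = c(-1.5, -0.5, 0.5, 1.5), axes = FALSE,
                    xlab = "", ylab = "", main = "PaSSS barcode", ...)
    graphics::axis(1, at = seq_len(ncol(bc)), labels = colnames(bc), las = 2)
    graphics::axis(2, at = seq_len(nrow(bc)), labels = rev(rownames(bc)),
                   las = 1, cex.axis = 0.7)
    graphics::box()
  }
  invisible(x)
}
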