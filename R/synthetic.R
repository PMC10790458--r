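# Synthetic cohorts with planted ground truth.
#
# The generator emulates the statistical structure of a phosphotyrosine
# tumor cohort: ln intensities are a per-site baseline plus a small number of
# sparse, mutually orthogonal unbalanced processes with sample-specific
# amplitudes, plus i.i.d. Gaussian noise in ln space (multiplicative in
# intensity).  Planted weight vectors use disjoint tails, so they are
# orthonormal by construction and recovery is well defined without rotation
# ambiguity; the baseline is projected orthogonal to the planted weights so
# that at zero noise the factorization recovers the planted components
# exactly (up to orientation).

# Default cast of tail proteins.  Each process gets a druggable central
# protein on each side (the largest-|weight| member); filler members come
# from a pool of recurring pY-signaling proteins, then generic symbols.
process_cast <- function() {
  list(
    list(plus = "EGFR|pY1172",          minus = "KIT|pY823"),
    list(plus = "EGFR|pY1197",          minus = "SRC|pY419"),
    list(plus = "MUC1|pY1209-pY1212",   minus = "MAPK3|pY204"),
    list(plus = "IGF1R|pY1165",         minus = "MAPK1|pY187"))
}

filler_sites <- function(n) {
  pool <- c("STAT3|pY705", "PIK3R1|pY580", "GAB1|pY627", "SHC1|pY427",
            "CBL|pY700", "PLCG1|pY783", "PTK2|pY397", "ANXA2|pY24",
            "CTNND1|pY228", "EPHA2|pY588", "MET|pY1234", "ERBB3|pY1289",
            "ABL1|pY245", "LYN|pY508", "PXN|pY118", "CAV1|pY14",
            "CDK1|pY15", "PRKCD|pY313", "DYRK1A|pY321", "INSR|pY1185")
  if (n <= length(pool)) pool[seq_len(n)]
  else c(pool, sprintf("PROT%03d|pY%d", seq_len(n - length(pool)),
                       100 + seq_len(n - length(pool))))
}

#' Configuration of a synthetic cohort
#'
#' @param n_sites total number of phosphosites.
#' @param n_samples number of samples.
#' @param amplitudes numeric matrix (processes x samples) of planted
#'   amplitudes in ln units; zero marks an inactive sample.  For exact
#'   noiseless recovery of signs and zeros the centered rows must be
#'   mutually orthogonal with distinct norms (the presets satisfy this).
#' @param tail_size planted tail sites per process (split half plus, half
#'   minus; default 8).
#' @param baseline_range range of per-site steady-state ln levels (default
#'   `c(6, 10)`, i.e. intensities of roughly 4e2-2e4 arbitrary units).
#' @param noise_sd measurement-noise standard deviation in ln space.
#' @param processes optional list (one element per process) of
#'   `list(plus = "SYM|site", minus = "SYM|site")` central sites; defaults to
#'   the built-in cast.
#' @param sample_names optional sample identifiers.
#' @param miss_prob probability of masking a cell as unobserved (default 0;
#'   at least one observed cell per site is always kept).
#' @param seed integer seed.
#' @return object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_sites, n_samples, amplitudes,
                             tail_size = 8L, baseline_range = c(6, 10),
                             noise_sd = 0.05, processes = NULL,
                             sample_names = NULL, miss_prob = 0,
                             seed = 1L) {
  amplitudes <- if (is.null(amplitudes)) matrix(0, 0L, n_samples)
  else as.matrix(amplitudes)
  m <- nrow(amplitudes)
  if (m > 0L && ncol(amplitudes) != n_samples)
    stop_passs("'amplitudes' must have %d columns", n_samples)
  if (any(!is.finite(amplitudes))) stop_passs("non-finite planted amplitudes")
  if (tail_size < 2L && m > 0L) stop_passs("'tail_size' must be >= 2")
  if (m * tail_size > n_sites)
    stop_passs("infeasible tail allocation: %d processes x %d tail sites > %d sites",
               m, tail_size, n_sites)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(miss_prob, "miss_prob", lower = 0, upper = 0.9)
  if (length(baseline_range) != 2L || baseline_range[1] > baseline_range[2])
    stop_passs("'baseline_range' must be c(lo, hi)")
  if (is.null(processes)) {
    cast <- process_cast()
    processes <- lapply(seq_len(m), function(a)
      if (a <= length(cast)) cast[[a]]
      else list(plus = sprintf("CEN%dP|pY%d", a, a),
                minus = sprintf("CEN%dM|pY%d", a, a)))
  }
  if (m > 0L && length(processes) != m)
    stop_passs("'processes' must list %d central pairs", m)
  if (is.null(sample_names))
    sample_names <- sprintf("tumor_%02d", seq_len(n_samples))
  structure(list(n_sites = as.integer(n_sites),
                 n_samples = as.integer(n_samples),
                 m_processes = m, tail_size = as.integer(tail_size),
                 amplitudes = amplitudes, baseline_range = baseline_range,
                 noise_sd = noise_sd, processes = processes,
                 sample_names = as.character(sample_names),
                 miss_prob = miss_prob, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Preset cohort configurations
#'
#' Two fully specified, seeded configurations shaped like the cohorts the
#' method is typically applied to:
#' \describe{
#'   \item{paperlike_subset}{3 tumors, 2 planted processes.  Sample A is
#'     active only in process 1, with sign opposite to samples B and C;
#'     process 2 separates B from C.  Process 1 couples induced EGFR to
#'     repressed KIT; process 2 couples IGF1R to SRC.}
#'   \item{paperlike_cohort}{28 tumors, 4 planted processes built from
#'     mutually orthogonal, mean-zero block sign patterns.  Per-sample
#'     process counts range 1-4 and average exactly 2; EGFR is the
#'     plus-side central target in half of the processes.}
#' }
#'
#' @param name `"paperlike_subset"` or `"paperlike_cohort"`.
#' @return a [synthetic_config()].
#' @export
preset_cohort <- function(name = c("paperlike_subset", "paperlike_cohort")) {
  name <- match.arg(name)
  if (name == "paperlike_subset") {
    amp <- rbind(2.2 * c(1, -1, -1),
                 1.6 * c(0, 1, -1))
    synthetic_config(n_sites = 60L, n_samples = 3L, amplitudes = amp,
                     tail_size = 8L, noise_sd = 0.02,
                     processes = list(
                       list(plus = "EGFR|pY1172", minus = "KIT|pY823"),
                       list(plus = "IGF1R|pY1165", minus = "SRC|pY419")),
                     sample_names = c("tumor_A", "tumor_B", "tumor_C"),
                     seed = 101L)
  } else {
    # orthogonal mean-zero block design: one block of 8 samples carrying all
    # four processes (Hadamard sign rows), four blocks of 4 carrying one
    # process each, one block of 4 carrying two.
    h8 <- rbind(c(1, 1, 1, 1, -1, -1, -1, -1),
                c(1, 1, -1, -1, 1, 1, -1, -1),
                c(1, -1, 1, -1, 1, -1, 1, -1),
                c(1, -1, -1, 1, 1, -1, -1, 1))
    h4a <- c(1, 1, -1, -1); h4b <- c(1, -1, 1, -1)
    A <- matrix(0, 4L, 28L)
    A[, 1:8] <- h8
    A[1L, 9:12] <- h4a
    A[2L, 13:16] <- h4a
    A[3L, 17:20] <- h4a
    A[4L, 21:24] <- h4a
    A[1L, 25:28] <- h4a; A[2L, 25:28] <- h4b
    A <- A * c(3.0, 2.6, 2.2, 1.8)
    synthetic_config(n_sites = 300L, n_samples = 28L, amplitudes = A,
                     tail_size = 8L, noise_sd = 0.05, seed = 202L)
  }
}

#' Generate a synthetic cohort with ground truth
#'
#' ln intensities are `baseline + W %*% A + noise`: a per-site constant drawn
#' from `baseline_range` (then projected orthogonal to the planted weights),
#' planted orthonormal weight columns `W` with disjoint signed tails, the
#' configured amplitude matrix `A`, and i.i.d. Gaussian ln-space noise.
#' Exported intensities are the elementwise exponential, hence strictly
#' positive and multiplicatively noisy.  Deterministic given the config seed.
#'
#' Planted tail weights boost the central proteins (plus-side central 2.0,
#' minus-side central 1.6, other members 1.0 before normalization), so the
#' plus-side central carries the largest |weight| of its column — which also
#' pins the component orientation rule to the planted sign.
#'
#' @param cfg a [synthetic_config()].
#' @return list with:
#'   \describe{
#'     \item{quant}{a [quant_matrix()] of intensities.}
#'     \item{truth}{planted ground truth: `weights`, `amplitudes` (as
#'       configured), `amplitudes_centered` (rows centered across samples —
#'       what an uncentered factorization can recover next to the steady
#'       state), `signs` (planted activity signs), `baseline`, `tails`
#'       (per-process signed member tables), `central` (per process:
#'       `plus`/`minus` protein), `intended_target` (process x sample matrix
#'       of the druggable central protein induced in each active cell),
#'       `order` (process order by decreasing recoverable magnitude).}
#'   }
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  m <- cfg$m_processes
  t_half <- cfg$tail_size %/% 2L
  # site table: tails first, then background sites
  tail_ids <- character(0); W <- NULL; tails <- list(); central <- list()
  if (m > 0L) {
    n_fill <- m * (cfg$tail_size - 2L)
    fillers <- filler_sites(n_fill)
    used <- unlist(lapply(cfg$processes, unlist), use.names = FALSE)
    fillers <- setdiff(fillers, used)
    while (length(fillers) < n_fill)
      fillers <- c(fillers, sprintf("XTRA%03d|pY%d", length(fillers) + 1L,
                                    length(fillers) + 1L))
    W <- matrix(0, cfg$n_sites, m)
    fi <- 0L
    for (a in seq_len(m)) {
      plus_c <- cfg$processes[[a]]$plus
      minus_c <- cfg$processes[[a]]$minus
      n_other <- cfg$tail_size - 2L
      n_plus_other <- t_half - 1L
      others <- fillers[fi + seq_len(n_other)]; fi <- fi + n_other
      plus_ids <- c(plus_c, others[seq_len(n_plus_other)])
      minus_ids <- c(minus_c, others[(n_plus_other + 1L):n_other])
      ids <- c(plus_ids, minus_ids)
      w_raw <- c(2.0, rep(1.0, length(plus_ids) - 1L),
                 -1.6, rep(-1.0, length(minus_ids) - 1L))
      rows <- length(tail_ids) + seq_along(ids)
      tail_ids <- c(tail_ids, ids)
      W[rows, a] <- w_raw / sqrt(sum(w_raw^2))
      tails[[a]] <- data.frame(site_id = ids,
                               sign = as.integer(sign(w_raw)),
                               weight = w_raw / sqrt(sum(w_raw^2)),
                               stringsAsFactors = FALSE)
      central[[a]] <- list(plus = sub("\\|.*$", "", plus_c),
                           minus = sub("\\|.*$", "", minus_c))
    }
  }
  n_bg <- cfg$n_sites - length(tail_ids)
  bg_ids <- sprintf("P%04d|pY%d", seq_len(n_bg), 100L + seq_len(n_bg))
  ids <- c(tail_ids, bg_ids)
  stopifnot(!anyDuplicated(ids))

  out <- with_seed(cfg$seed, {
    b <- stats::runif(cfg$n_sites, cfg$baseline_range[1], cfg$baseline_range[2])
    if (m > 0L) b <- b - W %*% crossprod(W, b)   # baseline _|_ planted weights
    ln <- matrix(b, cfg$n_sites, cfg$n_samples)
    if (m > 0L) ln <- ln + W %*% cfg$amplitudes
    if (cfg$noise_sd > 0)
      ln <- ln + matrix(stats::rnorm(length(ln), sd = cfg$noise_sd),
                        nrow(ln), ncol(ln))
    vals <- exp(ln)
    if (cfg$miss_prob > 0) {
      mask <- matrix(stats::runif(length(vals)) < cfg$miss_prob,
                     nrow(vals), ncol(vals))
      keep <- cbind(seq_len(nrow(vals)),
                    sample.int(ncol(vals), nrow(vals), replace = TRUE))
      mask[keep] <- FALSE                        # every site keeps >= 1 cell
      vals[mask] <- NA_real_
    }
    list(vals = vals, b = as.numeric(b))
  })

  parts <- strsplit(ids, "|", fixed = TRUE)
  q <- quant_matrix(out$vals,
                    protein = vapply(parts, `[`, "", 1L),
                    site_label = vapply(parts, `[`, "", 2L),
                    samples = cfg$sample_names)

  A <- cfg$amplitudes
  A_c <- if (m > 0L) A - rowMeans(A) else A
  ord <- if (m > 0L) order(-sqrt(rowSums(A_c^2))) else integer()
  intended <- if (m > 0L) {
    it <- matrix(NA_character_, m, cfg$n_samples,
                 dimnames = list(paste0("process", seq_len(m)),
                                 cfg$sample_names))
    for (a in seq_len(m)) {
      it[a, A[a, ] > 0] <- central[[a]]$plus
      it[a, A[a, ] < 0] <- central[[a]]$minus
    }
    it
  } else matrix(character(), 0L, cfg$n_samples)
  truth <- list(weights = if (m > 0L) {
                  dimnames(W) <- list(ids, paste0("process", seq_len(m))); W
                } else matrix(numeric(), cfg$n_sites, 0L),
                amplitudes = A, amplitudes_centered = A_c,
                signs = sign(A), baseline = out$b, tails = tails,
                central = central, intended_target = intended, order = ord)
  list(quant = q, truth = truth)
}
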