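# Shared fixtures built in code.

# Small quantification table written to a temp file; returns the path.
write_fixture_table <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}

tiny_quant <- function() {
  quant_matrix(matrix(c(1, 2, 3, 4), 2, 2,
                      dimnames = list(NULL, c("s1", "s2"))),
               protein = c("EGFR", "KIT"),
               site_label = c("pY1172", "pY823"))
}

# A minimal object carrying just what tail/ranking code reads from a
# decomposition: weights, site_info, n_processes, amplitudes, y.
fake_decomposition <- function(weights, amplitudes, site_info = NULL) {
  if (is.null(site_info)) {
    parts <- strsplit(rownames(weights), "|", fixed = TRUE)
    site_info <- data.frame(site_id = rownames(weights),
                            protein = vapply(parts, `[`, "", 1L),
                            site_label = vapply(parts, function(p)
                              if (length(p) > 1L) p[[2L]] else "", ""),
                            stringsAsFactors = FALSE)
  }
  structure(list(weights = weights, amplitudes = amplitudes,
                 sigma = rep(1, ncol(weights)),
                 n_processes = ncol(weights) - 1L,
                 y = matrix(0, nrow(weights), ncol(amplitudes)),
                 site_info = site_info),
            class = "surprisal")
}

# Compare a fitted barcode (samples x n) to planted signs (n x samples),
# allowing a global sign flip per column: returns cellwise agreement in [0,1].
barcode_agreement <- function(barcode, planted_signs) {
  if (ncol(barcode) != nrow(planted_signs)) return(0)
  truth <- t(planted_signs)
  hits <- vapply(seq_len(ncol(barcode)), function(j) {
    max(sum(barcode[, j] == truth[, j]), sum(barcode[, j] == -truth[, j]))
  }, numeric(1))
  sum(hits) / length(truth)
}

# Largest principal angle (radians) between the column spaces of A and B.
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, min(s)))
}

# PDX11-like two-process cohort: 4 samples, sample 1 induced in both an
# EGFR-centered and an IGF1R-centered process (mean-zero orthogonal design).
pdx11_like_config <- function(noise_sd = 0.02, seed = 303L) {
  amp <- rbind(2.4 * c(1, 1, -1, -1),
               1.8 * c(1, -1, 1, -1))
  synthetic_config(n_sites = 80L, n_samples = 4L, amplitudes = amp,
                   tail_size = 8L, noise_sd = noise_sd,
                   processes = list(
                     list(plus = "EGFR|pY1172", minus = "KIT|pY823"),
                     list(plus = "IGF1R|pY1165", minus = "SRC|pY419")),
                   sample_names = paste0("pdx_", 1:4), seed = seed)
}
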