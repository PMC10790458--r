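#' Phosphosite-by-sample quantification matrix
#'
#' A `quant_matrix` holds raw (positive) intensity measurements for a set of
#' phosphosites across samples, together with an observation mask recording
#' which cells were actually measured.  Rows are identified by a site id of
#' the form `"PROTEIN|site"` (e.g. `"EGFR|pY1172"`); multi-site labels such as
#' `"MUC1|pY1209-pY1212"` are allowed and treated as single rows.
#'
#' @param values numeric matrix of intensities (sites x samples); cells may be
#'   `NA` where unobserved, all observed cells must be strictly positive.
#' @param protein character vector of protein symbols, one per row.
#' @param site_label character vector of phosphosite labels, one per row.
#' @param samples optional character vector of sample identifiers; defaults to
#'   the column names of `values`.
#'
#' @return An object of class `quant_matrix` with components `values`
#'   (intensities, `NA` where unobserved), `observed` (logical mask),
#'   `protein`, `site_label` and row names `"protein|site_label"`.
#' @examples
#' q <- quant_matrix(matrix(c(1, 2, 3, 4), 2, 2,
#'                          dimnames = list(NULL, c("s1", "s2"))),
#'                   protein = c("EGFR", "KIT"),
#'                   site_label = c("pY1172", "pY823"))
#' q
#' @export
quant_matrix <- function(values, protein, site_label, samples = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (length(protein) != n || length(site_label) != n)
    stop_passs("'protein' and 'site_label' must have one entry per row (%d)", n)
  protein <- as.character(protein)
  site_label <- as.character(site_label)
  if (any(!nzchar(protein)) || any(is.na(protein)))
    stop_passs("empty or missing protein symbols at rows: %s",
               paste(which(!nzchar(protein) | is.na(protein)), collapse = ", "))
  if (any(!nzchar(site_label)) || any(is.na(site_label)))
    stop_passs("empty or missing site labels at rows: %s",
               paste(which(!nzchar(site_label) | is.na(site_label)), collapse = ", "))
  site_id <- paste(protein, site_label, sep = "|")
  dup <- site_id[duplicated(site_id)]
  if (length(dup))
    stop_passs("duplicate site ids: %s", paste(unique(dup), collapse = ", "))
  if (is.null(samples)) samples <- paste0("sample_", seq_len(ncol(values)))
  samples <- as.character(samples)
  if (anyDuplicated(samples))
    stop_passs("duplicate sample identifiers: %s",
               paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (length(samples) != ncol(values))
    stop_passs("length of 'samples' (%d) does not match columns (%d)",
               length(samples), ncol(values))
  observed <- !is.na(values)
  bad <- which(observed & values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop_passs("non-positive intensity at [%s]; intensities must be > 0",
               paste(sprintf("%s, %s", site_id[bad[, 1]], samples[bad[, 2]]),
                     collapse = "; "))
  dimnames(values) <- dimnames(observed) <- list(site_id, samples)
  structure(list(values = values, observed = observed,
                 protein = protein, site_label = site_label),
            class = "quant_matrix")
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d sites x %d samples (%d unobserved cells)\n",
              nrow(x$values), ncol(x$values), sum(!x$observed)))
  cat("samples:", paste(utils::head(colnames(x$values), 8), collapse = ", "),
      if (ncol(x$values) > 8) "..." else "", "\n")
  invisible(x)
}

site_ids <- function(x) rownames(x$values %||% x$log_values)

#' Impute missing cells and move to natural-log space
#'
#' Surprisal analysis operates on a complete matrix of natural-log
#' intensities.  Unobserved cells are filled by left-censoring imputation:
#' each missing cell receives `floor_fraction` times the smallest observed
#' intensity of its site, the mildest standard proxy for values below the
#' detection limit.  Every imputed cell is recorded in the provenance table.
#'
#' @param q a [quant_matrix()].
#' @param floor_fraction positive fraction of the per-site minimum used for
#'   imputation (default 0.5, half-minimum).
#'
#' @return An object of class `log_quant_matrix` with components `log_values`
#'   (complete matrix of ln intensities), `protein`, `site_label`, and
#'   `provenance` (data frame of imputed cells: `site_id`, `sample`,
#'   `imputed_intensity`).
#' @examples
#' q <- quant_matrix(matrix(c(4, NA, 8, 2), 2, 2,
#'                          dimnames = list(NULL, c("s1", "s2"))),
#'                   protein = c("EGFR", "KIT"),
#'                   site_label = c("pY1172", "pY823"))
#' lq <- impute_and_log(q, floor_fraction = 0.5)
#' lq$provenance
#' @export
impute_and_log <- function(q, floor_fraction = 0.5) {
  if (!inherits(q, "quant_matrix")) stop_passs("'q' must be a quant_matrix")
  assert_scalar_number(floor_fraction, "floor_fraction", lower = 1e-12)
  nobs <- rowSums(q$observed)
  if (any(nobs == 0))
    stop_passs("sites with no observed values: %s",
               paste(rownames(q$values)[nobs == 0], collapse = ", "))
  vals <- q$values
  miss <- which(!q$observed, arr.ind = TRUE)
  prov <- data.frame(site_id = character(), sample = character(),
                     imputed_intensity = numeric(), stringsAsFactors = FALSE)
  if (nrow(miss)) {
    site_min <- apply(vals, 1L, min, na.rm = TRUE)
    fill <- floor_fraction * site_min[miss[, 1]]
    vals[miss] <- fill
    prov <- data.frame(site_id = rownames(vals)[miss[, 1]],
                       sample = colnames(vals)[miss[, 2]],
                       imputed_intensity = unname(fill),
                       stringsAsFactors = FALSE)
    prov <- prov[order(prov$site_id, prov$sample), , drop = FALSE]
    rownames(prov) <- NULL
  }
  structure(list(log_values = log(vals), protein = q$protein,
                 site_label = q$site_label, provenance = prov),
            class = "log_quant_matrix")
}

#' @export
dim.log_quant_matrix <- function(x) dim(x$log_values)

#' @export
print.log_quant_matrix <- function(x, ...) {
  cat(sprintf("log_quant_matrix: %d sites x %d samples (%d imputed cells)\n",
              nrow(x$log_values), ncol(x$log_values), nrow(x$provenance)))
  invisible(x)
}

# Coerce user input (quant_matrix, log_quant_matrix, or plain intensity
# matrix) to a log_quant_matrix.
as_log_quant <- function(x, floor_fraction = 0.5) {
  if (inherits(x, "log_quant_matrix")) return(x)
  if (inherits(x, "quant_matrix")) return(impute_and_log(x, floor_fraction))
  if (is.matrix(x) && is.numeric(x)) {
    if (is.null(rownames(x)))
      rownames(x) <- sprintf("site_%d|pY", seq_len(nrow(x)))
    parts <- strsplit(rownames(x), "|", fixed = TRUE)
    prot <- vapply(parts, `[`, "", 1L)
    lab <- vapply(parts, function(p) if (length(p) > 1L)
      paste(p[-1L], collapse = "|") else "pY", "")
    q <- quant_matrix(x, protein = prot, site_label = lab,
                      samples = colnames(x) %||% paste0("sample_", seq_len(ncol(x))))
    return(impute_and_log(q, floor_fraction))
  }
  stop_passs("cannot interpret input of class '%s' as a quantification matrix",
             paste(class(x), collapse = "/"))
}
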