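# Readers and writers for the package's external tabular artifacts.
# All tables are plain text: UTF-8, tab-separated by default (comma via
# `sep = ","`), '#' comment lines ignored, decimal point only.

read_delim_raw <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_passs("file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"",
                    fileEncoding = "UTF-8")
}

# Convert character columns to numeric, reporting the first offending cell.
numeric_cols <- function(tab, path, col_offset = 2L) {
  out <- matrix(NA_real_, nrow(tab), ncol(tab) - col_offset)
  for (j in seq_len(ncol(tab) - col_offset)) {
    col <- tab[[j + col_offset]]
    blank <- is.na(col) | !nzchar(trimws(col)) | toupper(trimws(col)) == "NA"
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!blank & is.na(num))
    if (length(bad))
      stop_passs("non-numeric value '%s' at row %d, column '%s' of %s",
                 col[bad[1]], bad[1], colnames(tab)[j + col_offset], path)
    num[blank] <- NA_real_
    out[, j] <- num
  }
  colnames(out) <- colnames(tab)[-seq_len(col_offset)]
  out
}

#' Read a phosphosite quantification table
#'
#' Expects a header row naming the samples; the first two columns give the
#' protein symbol and phosphosite label, the remaining columns hold positive
#' intensities.  Empty cells and `NA` are recorded as unobserved.
#'
#' @param path path to the table.
#' @param sep field separator, `"\t"` (default) or `","`.
#' @return a [quant_matrix()].
#' @export
read_quant_table <- function(path, sep = "\t") {
  tab <- read_delim_raw(path, sep)
  if (ncol(tab) < 3L)
    stop_passs("%s needs at least protein, site and one sample column", path)
  vals <- numeric_cols(tab, path, col_offset = 2L)
  quant_matrix(vals, protein = tab[[1L]], site_label = tab[[2L]],
               samples = colnames(tab)[-(1:2)])
}

#' Write a quantification table
#'
#' Inverse of [read_quant_table()]: `read_quant_table(write_quant_table(q))`
#' reproduces values, mask and orderings exactly (full `%.17g` precision).
#'
#' @param q a [quant_matrix()].
#' @param path output path (parent directory must exist).
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(q, path, sep = "\t") {
  if (!inherits(q, "quant_matrix")) stop_passs("'q' must be a quant_matrix")
  if (nrow(q$values) == 0L || ncol(q$values) == 0L)
    stop_passs("refusing to write an empty matrix")
  vals <- matrix(sprintf("%.17g", q$values), nrow(q$values))
  vals[!q$observed] <- ""
  tab <- cbind(protein = q$protein, site = q$site_label, vals)
  colnames(tab) <- c("protein", "site", colnames(q$values))
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a protein-interaction edge list
#'
#' STRING-export-compatible: three columns `protein_a`, `protein_b`,
#' `confidence` with confidence in \[0, 1\].  Self-loops are dropped with a
#' warning; duplicate pairs keep the highest confidence.
#'
#' @param path path to the edge list.
#' @param sep field separator.
#' @return an `interaction_network`: data frame of undirected edges
#'   (`protein_a < protein_b`) with confidences.
#' @export
read_edge_list <- function(path, sep = "\t") {
  tab <- read_delim_raw(path, sep)
  if (ncol(tab) < 3L)
    stop_passs("%s needs columns protein_a, protein_b, confidence", path)
  conf <- suppressWarnings(as.numeric(tab[[3L]]))
  bad <- which(is.na(conf))
  if (length(bad))
    stop_passs("non-numeric confidence at row %d of %s", bad[1], path)
  interaction_network(tab[[1L]], tab[[2L]], conf)
}

#' Construct an interaction network from vectors
#'
#' @param protein_a,protein_b character vectors of interacting symbols.
#' @param confidence numeric vector of edge confidences in \[0, 1\].
#' @return an `interaction_network` data frame.
#' @export
interaction_network <- function(protein_a = character(),
                                protein_b = character(),
                                confidence = numeric()) {
  protein_a <- as.character(protein_a); protein_b <- as.character(protein_b)
  if (length(protein_a) != length(protein_b) ||
      length(protein_a) != length(confidence))
    stop_passs("edge columns must have equal length")
  if (length(confidence) && (any(confidence < 0) || any(confidence > 1)))
    stop_passs("edge confidence outside [0, 1]")
  self <- protein_a == protein_b
  if (any(self)) {
    warning(sprintf("dropping %d self-loop(s)", sum(self)), call. = FALSE)
    protein_a <- protein_a[!self]; protein_b <- protein_b[!self]
    confidence <- confidence[!self]
  }
  a <- pmin(protein_a, protein_b); b <- pmax(protein_a, protein_b)
  df <- data.frame(protein_a = a, protein_b = b, confidence = confidence,
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    df <- df[order(df$protein_a, df$protein_b, -df$confidence), , drop = FALSE]
    df <- df[!duplicated(df[c("protein_a", "protein_b")]), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("interaction_network", "data.frame")
  df
}

#' Read a druggable-target map
#'
#' Two columns, `protein` and `inhibitor`, one row per (protein, inhibitor)
#' pair.
#'
#' @param path path to the map.
#' @param sep field separator.
#' @return a named list: protein symbol -> character vector of inhibitors, in
#'   file order.
#' @export
read_druggable_map <- function(path, sep = "\t") {
  tab <- read_delim_raw(path, sep)
  if (ncol(tab) < 2L) stop_passs("%s needs columns protein, inhibitor", path)
  druggable_map(tab[[1L]], tab[[2L]])
}

#' Construct a druggable-target map
#'
#' @param protein character vector of protein symbols.
#' @param inhibitor character vector of inhibitor names, same length.
#' @return named list mapping each protein to its inhibitors.
#' @export
druggable_map <- function(protein, inhibitor) {
  protein <- as.character(protein); inhibitor <- as.character(inhibitor)
  if (length(protein) != length(inhibitor))
    stop_passs("'protein' and 'inhibitor' must have equal length")
  if (any(!nzchar(protein)) || any(!nzchar(inhibitor)))
    stop_passs("empty protein or inhibitor names in druggable map")
  split(inhibitor, factor(protein, levels = unique(protein)))
}

# Write a plain numeric matrix with a leading id column; used for all
# pipeline exports (weights, amplitudes, barcode, map, significance).
write_matrix_tsv <- function(m, path, id_name = "id") {
  if (is.null(dim(m)) || nrow(m) == 0L)
    stop_passs("refusing to write an empty matrix to %s", path)
  tab <- cbind(rownames(m) %||% as.character(seq_len(nrow(m))),
               matrix(sprintf("%.17g", m), nrow(m)))
  colnames(tab) <- c(id_name, colnames(m) %||% paste0("c", seq_len(ncol(m))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_matrix_tsv <- function(path) {
  tab <- read_delim_raw(path)
  m <- numeric_cols(tab, path, col_offset = 1L)
  rownames(m) <- tab[[1L]]
  m
}
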