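#' Signed weight tails of an unbalanced process
#'
#' The sites that define a process are those on the tails of its weight
#' column: by default all sites whose weight lies at least `c` standard
#' deviations from the column mean (`method = "sd"`), or alternatively the
#' top and bottom `q` quantiles (`method = "quantile"`).  Each tail member
#' carries the sign of its weight; opposite-sign members move in opposite
#' directions whenever the process acts.
#'
#' @param fit a [passs()] fit or [surprisal()] decomposition.
#' @param alpha process index (>= 1).
#' @param c spread multiplier for `method = "sd"` (default 2).
#' @param method `"sd"` (mean +/- c*SD) or `"quantile"` (top/bottom q).
#' @param q tail fraction for `method = "quantile"` (default 0.05).
#' @return data frame with columns `site_id`, `protein`, `site_label`,
#'   `sign`, `weight`, sorted by `|weight|` descending; zero rows when the
#'   weight column has no spread (with a warning).
#' @export
process_tails <- function(fit, alpha, c = 2, method = c("sd", "quantile"),
                          q = 0.05) {
  d <- if (inherits(fit, "passs")) fit$decomposition else fit
  stopifnot(inherits(d, "surprisal"))
  method <- match.arg(method)
  if (alpha < 1 || alpha > d$n_processes)
    stop_passs("'alpha' must be in 1..%d", d$n_processes)
  if (c < 0) stop_passs("'c' must be >= 0")
  g <- d$weights[, alpha + 1L]
  s <- stats::sd(g)
  empty <- data.frame(site_id = character(), protein = character(),
                      site_label = character(), sign = integer(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (s == 0) {
    warning(sprintf("process %d has a constant weight column; no tails", alpha),
            call. = FALSE)
    return(empty)
  }
  keep <- if (method == "sd") abs(g - mean(g)) >= c * s
  else {
    lo <- stats::quantile(g, q, type = 7)
    hi <- stats::quantile(g, 1 - q, type = 7)
    g <= lo | g >= hi
  }
  if (!any(keep)) return(empty)
  info <- d$site_info[keep, , drop = FALSE]
  out <- data.frame(site_id = info$site_id, protein = info$protein,
                    site_label = info$site_label,
                    sign = as.integer(sign(g[keep])),
                    weight = unname(g[keep]), stringsAsFactors = FALSE)
  out <- out[order(-abs(out$weight), out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interaction subnetwork of a process
#'
#' Maps the tail members of a process onto their proteins and induces the
#' subgraph of the supplied interaction network over those proteins, keeping
#' edges at or above `min_confidence`.  Multiple phosphosites of one protein
#' collapse onto a single network node but remain distinct tail members;
#' proteins absent from the network stay in the tails as isolated members —
#' missing annotation never drops signal.  The network is interpretive only:
#' it never changes tail membership.
#'
#' @param tails a tail data frame from [process_tails()].
#' @param network an `interaction_network` (see [read_edge_list()]), or
#'   `NULL` for no network (everything isolated).
#' @param min_confidence minimum edge confidence (default 0.7, the usual
#'   STRING high-confidence cut).
#' @param alpha process index recorded on the result.
#' @param cutoff the `|G|` cutoff recorded on the result.
#' @return An object of class `unbalanced_process`: list with `alpha`,
#'   `tails`, `cutoff`, `edges` (induced edge data frame), `components`
#'   (named integer: protein -> component id), `degree` (named integer),
#'   `isolated` (site ids of members without any edge).
#' @export
process_subnetwork <- function(tails, network = NULL, min_confidence = 0.7,
                               alpha = NA_integer_, cutoff = NA_real_) {
  assert_scalar_number(min_confidence, "min_confidence", lower = 0, upper = 1)
  proteins <- unique(tails$protein)
  edges <- if (is.null(network) || nrow(network) == 0L || length(proteins) == 0L)
    data.frame(protein_a = character(), protein_b = character(),
               confidence = numeric(), stringsAsFactors = FALSE)
  else {
    keep <- network$protein_a %in% proteins & network$protein_b %in% proteins &
      network$confidence >= min_confidence
    as.data.frame(network[keep, , drop = FALSE])
  }
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = proteins))
  comp <- igraph::components(g)$membership
  deg <- igraph::degree(g)
  isolated <- tails$site_id[deg[tails$protein] == 0L]
  structure(list(alpha = alpha, tails = tails, cutoff = cutoff,
                 edges = edges, components = comp,
                 degree = deg, isolated = isolated),
            class = "unbalanced_process")
}

#' @export
print.unbalanced_process <- function(x, ...) {
  n_comp <- if (length(x$components))
    length(unique(x$components[x$degree > 0])) else 0L
  cat(sprintf("unbalanced process %s: %d tail sites (%d+, %d-), %d edges, %d connected component(s), %d isolated\n",
              ifelse(is.na(x$alpha), "?", x$alpha), nrow(x$tails),
              sum(x$tails$sign > 0), sum(x$tails$sign < 0),
              nrow(x$edges), n_comp, length(x$isolated)))
  invisible(x)
}

# Convenience: tails + subnetwork for every retained process of a fit.
build_processes <- function(fit, network = NULL, c = 2, min_confidence = 0.7,
                            method = "sd", q = 0.05) {
  stopifnot(inherits(fit, "passs"))
  lapply(seq_len(fit$n_star), function(a) {
    tl <- process_tails(fit, a, c = c, method = method, q = q)
    process_subnetwork(tl, network, min_confidence, alpha = a,
                       cutoff = if (nrow(tl)) min(abs(tl$weight)) else NA_real_)
  })
}

#' Induced and repressed sites of a process in one sample
#'
#' Splits a process's tail members by the sign of their contribution
#' \eqn{G_{i\alpha}\lambda_\alpha(k)} in sample `k`: positive = induced
#' (raised above the steady-state prediction), negative = repressed.
#' Flipping the amplitude's sign swaps the two lists.
#'
#' @param fit a [passs()] fit or [surprisal()] decomposition.
#' @param proc an `unbalanced_process` from [process_subnetwork()] (or a tail
#'   data frame).
#' @param sample sample identifier or column index.
#' @return list with data frames `induced` and `repressed`.
#' @export
sample_direction <- function(fit, proc, sample) {
  d <- if (inherits(fit, "passs")) fit$decomposition else fit
  stopifnot(inherits(d, "surprisal"))
  tails <- if (inherits(proc, "unbalanced_process")) proc$tails else proc
  alpha <- if (inherits(proc, "unbalanced_process")) proc$alpha else
    stop_passs("supply an unbalanced_process to identify the component")
  k <- if (is.character(sample)) match(sample, colnames(d$amplitudes)) else sample
  if (is.na(k) || k < 1 || k > ncol(d$amplitudes))
    stop_passs("unknown sample '%s'", as.character(sample))
  lam <- d$amplitudes[alpha + 1L, k]
  contrib <- tails$weight * lam
  list(induced = tails[contrib > 0, , drop = FALSE],
       repressed = tails[contrib < 0, , drop = FALSE])
}
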