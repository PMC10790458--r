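#' Bundled druggable-target map
#'
#' A small default map for examples and tests, pairing recurring central
#' proteins of phosphotyrosine signaling with a representative inhibitor:
#' EGFR/erlotinib, IGF1R/AG-1024, KIT/imatinib, SRC/dasatinib, MUC1/GO-203
#' and the MAPK axis (MAP2K1, MAPK1, MAPK3) with trametinib.  Real analyses
#' should supply their own map via [read_druggable_map()].
#'
#' @return named list: protein -> inhibitors.
#' @export
default_druggable_map <- function() {
  druggable_map(
    protein = c("EGFR", "IGF1R", "KIT", "SRC", "MUC1",
                 "MAP2K1", "MAPK1", "MAPK3"),
    inhibitor = c("erlotinib", "AG-1024", "imatinib", "dasatinib", "GO-203",
                  "trametinib", "trametinib", "trametinib"))
}

#' Ranked druggable targets of a process in one sample
#'
#' Candidates are the tail members *induced* by the process in this sample
#' (contribution \eqn{G_{i\alpha}\lambda_\alpha(k) > 0}) whose protein
#' appears in the druggable map; repressed members are never candidates —
#' inhibiting a protein the process already suppresses cannot reduce the
#' process's flux.  Candidates are scored by \eqn{|G_{i\alpha}|} (weights
#' drive the reconstruction), with ties broken by subnetwork degree
#' (descending) and then protein symbol (ascending), making the ranking
#' total and deterministic.  With `centrality = "degree"` the degree is the
#' primary key and the weight breaks ties instead.
#'
#' @param proc an `unbalanced_process` from [process_subnetwork()].
#' @param sample sample identifier or index.
#' @param fit the [passs()] fit (or decomposition) the process came from.
#' @param drugs a druggable map (see [druggable_map()]); default bundled map.
#' @param centrality `"weight"` (default) or `"degree"` primary ranking key.
#' @return data frame `rank`, `protein`, `inhibitor`, `score`, `degree`
#'   (possibly zero rows).  Proteins with several inhibitors repeat the rank
#'   across rows.
#' @export
rank_targets <- function(proc, sample, fit, drugs = default_druggable_map(),
                         centrality = c("weight", "degree")) {
  centrality <- match.arg(centrality)
  dir <- sample_direction(fit, proc, sample)
  cand <- dir$induced
  cand <- cand[cand$protein %in% names(drugs), , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(rank = integer(), protein = character(),
                      inhibitor = character(), score = numeric(),
                      degree = integer(), stringsAsFactors = FALSE))
  # collapse multi-site entries of one protein onto its best site
  score <- abs(cand$weight)
  deg <- unname(proc$degree[cand$protein])
  ord <- if (centrality == "weight")
    order(-score, -deg, cand$protein, cand$site_id)
  else order(-deg, -score, cand$protein, cand$site_id)
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[!duplicated(cand$protein), , drop = FALSE]
  score <- abs(cand$weight); deg <- unname(proc$degree[cand$protein])
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    inh <- drugs[[cand$protein[i]]]
    data.frame(rank = i, protein = cand$protein[i], inhibitor = inh,
               score = score[i], degree = deg[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Predict per-sample mono/combination therapy from active processes
#'
#' For every sample, takes the processes passing the significance gate,
#' ranks the induced druggable tail members of each ([rank_targets()]), and
#' picks the top-ranked target per active process — the process's central
#' target.  Identical (protein, inhibitor) choices across processes are
#' deduplicated, so two processes centered on the same protein yield a
#' single drug.  A plan's class is `"none"` (no drug), `"monotherapy"`
#' (exactly one) or `"combination"`; active processes without any druggable
#' induced candidate are flagged uncovered rather than silently skipped.
#'
#' @param fit a [passs()] fit.
#' @param network optional `interaction_network` used for subnetworks and
#'   degree tie-breaks.
#' @param drugs druggable map (default [default_druggable_map()]).
#' @param tail_c spread multiplier for tail membership (see
#'   [process_tails()]).
#' @param min_confidence minimum edge confidence for subnetworks.
#' @param centrality ranking key, see [rank_targets()].
#' @return An object of class `passs_therapy`: list with `plans` (one per
#'   sample: `sample`, `class`, `combination` data frame, `per_process` list
#'   of candidate tables and chosen rows, `uncovered` process indices),
#'   `processes` (list of `unbalanced_process`), and `summary` (see
#'   [cohort_summary()]).
#' @examples
#' sim <- simulate_cohort(preset_cohort("paperlike_subset"))
#' fit <- passs(sim$quant, seed = 7)
#' th <- predict_therapy(fit)
#' th
#' @export
predict_therapy <- function(fit, network = NULL,
                            drugs = default_druggable_map(), tail_c = 2,
                            min_confidence = 0.7,
                            centrality = c("weight", "degree")) {
  stopifnot(inherits(fit, "passs"))
  centrality <- match.arg(centrality)
  procs <- build_processes(fit, network, c = tail_c,
                           min_confidence = min_confidence)
  samples <- colnames(fit$decomposition$amplitudes)
  plans <- lapply(seq_along(samples), function(k) {
    active <- if (fit$n_star > 0L) unname(which(fit$mask[, k])) else integer()
    per_process <- list(); uncovered <- integer()
    chosen <- data.frame(process = integer(), protein = character(),
                         inhibitor = character(), score = numeric(),
                         stringsAsFactors = FALSE)
    for (a in active) {
      cand <- rank_targets(procs[[a]], k, fit, drugs, centrality)
      per_process[[as.character(a)]] <- cand
      if (nrow(cand) == 0L) {
        uncovered <- c(uncovered, a)
      } else {
        top <- cand[cand$rank == 1L, , drop = FALSE][1L, ]
        chosen <- rbind(chosen,
                        data.frame(process = a, protein = top$protein,
                                   inhibitor = top$inhibitor,
                                   score = top$score,
                                   stringsAsFactors = FALSE))
      }
    }
    combo <- unique(chosen[, c("protein", "inhibitor"), drop = FALSE])
    rownames(combo) <- NULL
    cls <- if (nrow(combo) == 0L) "none"
    else if (nrow(combo) == 1L) "monotherapy" else "combination"
    list(sample = samples[k], active = active, class = cls,
         chosen = chosen, combination = combo,
         per_process = per_process, uncovered = uncovered)
  })
  names(plans) <- samples
  out <- structure(list(plans = plans, processes = procs, drugs = drugs,
                        centrality = centrality),
                   class = "passs_therapy")
  out$summary <- cohort_summary(out)
  out
}

#' Cohort-level therapy summary
#'
#' Counts samples by therapy class, counts plans whose single drug targets
#' EGFR (EGFR monotherapy) and plans containing an EGFR-targeting drug
#' within a combination, and reports the mean number of active processes per
#' sample.
#'
#' @param therapy a `passs_therapy` from [predict_therapy()], or its `plans`
#'   list.
#' @return list with `n_samples`, `by_class` (named counts), `egfr_monotherapy`,
#'   `egfr_in_combination`, `mean_active_processes`, `uncovered_processes`.
#' @export
cohort_summary <- function(therapy) {
  plans <- if (inherits(therapy, "passs_therapy")) therapy$plans else therapy
  if (length(plans) == 0L) stop_passs("empty cohort: no plans to summarize")
  cls <- vapply(plans, `[[`, "", "class")
  by_class <- c(none = sum(cls == "none"),
                monotherapy = sum(cls == "monotherapy"),
                combination = sum(cls == "combination"))
  has_egfr <- vapply(plans, function(p) "EGFR" %in% p$combination$protein,
                     logical(1L))
  list(n_samples = length(plans),
       by_class = by_class,
       egfr_monotherapy = sum(has_egfr & cls == "monotherapy"),
       egfr_in_combination = sum(has_egfr & cls == "combination"),
       mean_active_processes = mean(vapply(plans, function(p)
         length(p$active), 0L)),
       uncovered_processes = sum(vapply(plans, function(p)
         length(p$uncovered), 0L)))
}

#' @export
print.passs_therapy <- function(x, ...) {
  s <- x$summary
  cat(sprintf("PaSSS therapy plans for %d samples (mean %.2f active processes)\n",
              s$n_samples, s$mean_active_processes))
  cat(sprintf("  classes: %d none, %d monotherapy, %d combination\n",
              s$by_class[["none"]], s$by_class[["monotherapy"]],
              s$by_class[["combination"]]))
  cat(sprintf("  EGFR monotherapy: %d; EGFR within combination: %d\n",
              s$egfr_monotherapy, s$egfr_in_combination))
  for (p in x$plans) {
    drugs <- if (nrow(p$combination))
      paste(sprintf("%s (%s)", p$combination$inhibitor,
                    p$combination$protein), collapse = " + ")
    else "-"
    flag <- if (length(p$uncovered))
      sprintf(" [uncovered: %s]", paste(p$uncovered, collapse = ",")) else ""
    cat(sprintf("  %s: %s, %s%s\n", p$sample, p$class, drugs, flag))
  }
  invisible(x)
}
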