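# End-to-end orchestration with stable on-disk artifacts.

#' Run configuration for the PaSSS pipeline
#'
#' Exactly one of `preset` or `quant_table` must be supplied.  All parameters
#' have the package defaults; `seed` drives every stochastic stage.
#'
#' @param output_dir directory for run artifacts (created if needed).
#' @param preset name of a [preset_cohort()] configuration.
#' @param quant_table path to a quantification table ([read_quant_table()]).
#' @param edge_list optional path to an interaction edge list.
#' @param druggable_map_path optional path to a druggable map; default map
#'   used when absent.
#' @param sep field separator of the input tables.
#' @param floor_fraction,level,n_null,tail_c,min_confidence,noise_sd,seed
#'   pipeline parameters; see [passs()], [process_tails()],
#'   [process_subnetwork()].
#' @return object of class `passs_run_config`.
#' @export
run_config <- function(output_dir, preset = NULL, quant_table = NULL,
                       edge_list = NULL, druggable_map_path = NULL,
                       sep = "\t", floor_fraction = 0.5, level = 0.95,
                       n_null = 200L, tail_c = 2, min_confidence = 0.7,
                       noise_sd = NULL, seed = 1L) {
  if (is.null(preset) == is.null(quant_table))
    stop_passs("supply exactly one of 'preset' or 'quant_table'")
  assert_scalar_number(floor_fraction, "floor_fraction", lower = 1e-12)
  assert_scalar_number(level, "level", lower = 1e-9, upper = 1 - 1e-9)
  assert_scalar_number(tail_c, "tail_c", lower = 0)
  assert_scalar_number(min_confidence, "min_confidence", lower = 0, upper = 1)
  if (!is.null(quant_table) && !file.exists(quant_table))
    stop_passs("quantification table not found: %s", quant_table)
  if (!is.null(edge_list) && !file.exists(edge_list))
    stop_passs("edge list not found: %s", edge_list)
  if (!is.null(druggable_map_path) && !file.exists(druggable_map_path))
    stop_passs("druggable map not found: %s", druggable_map_path)
  structure(list(output_dir = output_dir, preset = preset,
                 quant_table = quant_table, edge_list = edge_list,
                 druggable_map_path = druggable_map_path, sep = sep,
                 floor_fraction = floor_fraction, level = level,
                 n_null = as.integer(n_null), tail_c = tail_c,
                 min_confidence = min_confidence, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "passs_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the [run_config()] argument names exactly; unknown keys are an
#' error.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file's values.
#' @return a `passs_run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop_passs("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_passs("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the full PaSSS pipeline
#'
#' Loads or simulates the inputs, fits [passs()], derives processes,
#' signatures and therapy plans, and writes every artifact to the output
#' directory: `weights.tsv`, `amplitudes.tsv`, `sigma.tsv`, `noise.json`,
#' `thresholds.tsv`, `significance.tsv`, `processes.tsv`, `signatures.tsv`,
#' `barcode.tsv`, `map.tsv`, `therapy.tsv`, `summary.json`,
#' `provenance.json`.  Identical config + inputs give byte-identical
#' outputs.  On error, partial outputs are removed.
#'
#' @param cfg a `passs_run_config` (see [run_config()], [read_run_config()]).
#' @param quiet suppress progress messages on stderr.
#' @return (invisibly) list with `fit`, `therapy`, `dir`.
#' @export
run_passs_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "passs_run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  written <- character()
  on.exit(if (!ok) unlink(file.path(cfg$output_dir, written)))
  emit <- function(name) written <<- c(written, name)

  stage <- "input"
  res <- tryCatch({
    if (!is.null(cfg$preset)) {
      say("simulating preset cohort '%s'", cfg$preset)
      sim <- simulate_cohort(preset_cohort(cfg$preset))
      q <- sim$quant
    } else {
      say("reading %s", cfg$quant_table)
      q <- read_quant_table(cfg$quant_table, sep = cfg$sep)
    }
    network <- if (!is.null(cfg$edge_list)) read_edge_list(cfg$edge_list, cfg$sep)
    drugs <- if (!is.null(cfg$druggable_map_path))
      read_druggable_map(cfg$druggable_map_path, cfg$sep)
    else default_druggable_map()

    stage <- "decomposition"
    say("fitting PaSSS (seed %d)", cfg$seed)
    fit <- passs(q, floor_fraction = cfg$floor_fraction,
                 noise_sd = cfg$noise_sd, level = cfg$level,
                 n_null = cfg$n_null, seed = cfg$seed)

    stage <- "therapy"
    therapy <- predict_therapy(fit, network = network, drugs = drugs,
                               tail_c = cfg$tail_c,
                               min_confidence = cfg$min_confidence)

    stage <- "export"
    d <- fit$decomposition
    write_decomposition(d, cfg$output_dir)
    emit(c("weights.tsv", "amplitudes.tsv", "sigma.tsv"))
    jsonlite::write_json(
      list(sd_ln = fit$noise$sd_ln, method = fit$noise$method,
           details = fit$noise$details),
      file.path(cfg$output_dir, "noise.json"), auto_unbox = TRUE, digits = NA)
    emit("noise.json")
    thr <- matrix(rep(fit$threshold, max(fit$n_star, 1L)), ncol = 1L,
                  dimnames = list(paste0("process",
                                         seq_len(max(fit$n_star, 1L))),
                                  "threshold"))
    write_matrix_tsv(thr, file.path(cfg$output_dir, "thresholds.tsv"), "alpha")
    emit("thresholds.tsv")
    sig_m <- matrix(0L, max(fit$n_star, 1L), ncol(d$amplitudes),
                    dimnames = list(paste0("process",
                                           seq_len(max(fit$n_star, 1L))),
                                    colnames(d$amplitudes)))
    if (fit$n_star > 0L) sig_m[seq_len(fit$n_star), ] <- fit$mask + 0L
    write_matrix_tsv(sig_m, file.path(cfg$output_dir, "significance.tsv"),
                     "alpha")
    emit("significance.tsv")

    proc_rows <- do.call(rbind, c(list(
      data.frame(process = integer(), site_id = character(),
                 sign = integer(), weight = numeric(),
                 component = integer(), isolated = integer(),
                 stringsAsFactors = FALSE)),
      lapply(therapy$processes, function(p)
        if (nrow(p$tails)) data.frame(
          process = p$alpha, site_id = p$tails$site_id,
          sign = p$tails$sign, weight = p$tails$weight,
          component = unname(p$components[p$tails$protein]),
          isolated = as.integer(p$tails$site_id %in% p$isolated),
          stringsAsFactors = FALSE))))
    write_df_tsv(proc_rows, file.path(cfg$output_dir, "processes.tsv"))
    emit("processes.tsv")

    sig_rows <- do.call(rbind, c(list(
      data.frame(sample = character(), process = integer(), sign = integer(),
                 amplitude = numeric(), stringsAsFactors = FALSE)),
      lapply(names(fit$signatures), function(s) {
        sg <- fit$signatures[[s]]
        if (nrow(sg)) data.frame(sample = s, process = sg$alpha,
                                 sign = sg$sign, amplitude = sg$amplitude,
                                 stringsAsFactors = FALSE)
      })))
    write_df_tsv(sig_rows, file.path(cfg$output_dir, "signatures.tsv"))
    emit("signatures.tsv")

    write_matrix_tsv(fit$barcode + 0L, file.path(cfg$output_dir, "barcode.tsv"),
                     "sample")
    emit("barcode.tsv")
    if (fit$n_star >= 1L) {
      write_matrix_tsv(map_coordinates(fit), file.path(cfg$output_dir, "map.tsv"),
                       "sample")
      emit("map.tsv")
    }

    ther_rows <- do.call(rbind, c(list(
      data.frame(sample = character(), process = integer(), rank = integer(),
                 protein = character(), inhibitor = character(),
                 score = numeric(), chosen = integer(), uncovered = integer(),
                 stringsAsFactors = FALSE)),
      lapply(therapy$plans, function(p)
        do.call(rbind, lapply(names(p$per_process), function(a) {
          cand <- p$per_process[[a]]
          ai <- as.integer(a)
          if (nrow(cand) == 0L)
            return(data.frame(sample = p$sample, process = ai, rank = NA_integer_,
                              protein = NA_character_, inhibitor = NA_character_,
                              score = NA_real_, chosen = 0L, uncovered = 1L,
                              stringsAsFactors = FALSE))
          ch <- p$chosen[p$chosen$process == ai, , drop = FALSE]
          data.frame(sample = p$sample, process = ai, rank = cand$rank,
                     protein = cand$protein, inhibitor = cand$inhibitor,
                     score = cand$score,
                     chosen = as.integer(cand$rank == 1L &
                                           cand$protein == ch$protein[1L] &
                                           cand$inhibitor == ch$inhibitor[1L]),
                     uncovered = 0L, stringsAsFactors = FALSE)
        })))))
    write_df_tsv(ther_rows, file.path(cfg$output_dir, "therapy.tsv"))
    emit("therapy.tsv")

    summ_out <- therapy$summary
    summ_out$by_class <- as.list(summ_out$by_class)  # keep class names in JSON
    jsonlite::write_json(summ_out,
                         file.path(cfg$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("summary.json")
    prov <- list(package_version = as.character(utils::packageVersion("passs")),
                 r_version = paste(R.version$major, R.version$minor, sep = "."),
                 parameters = cfg[setdiff(names(unclass(cfg)), "output_dir")],
                 n_star = fit$n_star, noise_sd = fit$noise$sd_ln,
                 threshold = fit$threshold)
    jsonlite::write_json(prov, file.path(cfg$output_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    emit("provenance.json")
    list(fit = fit, therapy = therapy, dir = cfg$output_dir)
  }, error = function(e) {
    stop_passs("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  ok <- TRUE
  say("run complete: %s", cfg$output_dir)
  invisible(res)
}

write_df_tsv <- function(df, path) {
  utils::write.table(format_df(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

format_df <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Summarize a completed pipeline run
#'
#' Reads the artifacts of a [run_passs_pipeline()] directory and prints a
#' human-readable summary: per-sample signature sizes and therapy classes,
#' cohort counts and the mean number of active processes (recomputed from
#' `signatures.tsv`).
#'
#' @param dir run directory.
#' @return (invisibly) list with the recomputed summary fields.
#' @export
passs_report <- function(dir) {
  need <- c("barcode.tsv", "signatures.tsv", "therapy.tsv", "summary.json",
            "provenance.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop_passs("incomplete run in %s: missing %s", dir,
               paste(missing, collapse = ", "))
  bc <- read_matrix_tsv(file.path(dir, "barcode.tsv"))
  sig <- utils::read.table(file.path(dir, "signatures.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  summ <- jsonlite::read_json(file.path(dir, "summary.json"),
                              simplifyVector = TRUE)
  sizes <- table(factor(sig$sample, levels = rownames(bc)))
  mean_active <- sum(sizes) / nrow(bc)
  cat(sprintf("PaSSS run: %d samples, %d retained processes\n",
              nrow(bc), ncol(bc)))
  cat(sprintf("mean active processes per sample: %.2f\n", mean_active))
  cat(sprintf("therapy classes: %d none, %d monotherapy, %d combination\n",
              summ$by_class[["none"]], summ$by_class[["monotherapy"]],
              summ$by_class[["combination"]]))
  for (s in rownames(bc))
    cat(sprintf("  %s: %d active process(es)\n", s, sizes[[s]]))
  invisible(list(n_samples = nrow(bc), n_star = ncol(bc),
                 mean_active = mean_active, by_class = summ$by_class,
                 signature_sizes = as.integer(sizes)))
}
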