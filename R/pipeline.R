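#' Pipeline configuration
#'
#' Collects every stage parameter with its default. Unknown keys are
#' rejected. The defaults define the package's reference simulation
#' scenario: ten related 16S-like references (400 bp, 10% divergence,
#' log-uniform abundances), 2,000 reads at a raw per-base error rate around
#' 0.5%, basic trimming, a PUK-SVM with omega = sigma = C = 1, a 2%
#' preclustering difference budget and a chimera margin of 3.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 7L,
    n_species = 10L, ref_length = 400L, divergence = 0.10,
    n_reads = 2000L,
    flow_order = "TACG", n_flows = 800L,
    sd0 = 0.08, sd_slope = 0.03,
    carry_forward_rate = 0.005, incomplete_extension_rate = 0.005,
    positional_decay = 0.001,
    min_len = 200L, max_homopolymer = 8L,
    strict = FALSE, window = 100L, q_cutoff = 30L,
    omega = 1, sigma = 1, C = 1,
    balance = c(insertion = 132L, deletion = 132L, substitution = 132L,
                clean = 700L),
    diff_pct = 0.02, margin = 3L,
    out_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown pipeline_config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Run the full denoising pipeline on a simulated mock community
#'
#' Executes the stages in order: reference generation, flowgram simulation,
#' basic (optionally strict) trimming, reference-based error labelling,
#' balanced training-set construction, PUK-SVM training and held-out
#' evaluation, per-position masking, template alignment, dereplication,
#' masking-aware preclustering, mask restoration, and error assessment of
#' the raw versus denoised reads.
#'
#' @param config A [pipeline_config].
#' @return List of class `pipeline_result` with the fitted classifier
#'   (`model`), its held-out evaluation (`evaluation`), raw and denoised
#'   [compute_error_report]s, the corrected reads, the trim report, truth
#'   bookkeeping, and a one-row `summary` data.frame.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  refs <- generate_references(config$n_species, config$ref_length,
                              config$divergence, seed = config$seed)
  params <- sim_params(flow_order = config$flow_order,
                       n_flows = config$n_flows, sd0 = config$sd0,
                       sd_slope = config$sd_slope,
                       carry_forward_rate = config$carry_forward_rate,
                       incomplete_extension_rate =
                         config$incomplete_extension_rate,
                       positional_decay = config$positional_decay,
                       seed = config$seed + 1L)
  sim <- simulate_reads(refs$records, refs$weights, config$n_reads, params)

  trim <- basic_trim(sim$reads, min_len = config$min_len,
                     max_homopolymer = config$max_homopolymer)
  reads <- trim$kept
  if (isTRUE(config$strict)) {
    st <- strict_trim_set(reads, window = config$window,
                          q_cutoff = config$q_cutoff,
                          min_len = config$min_len)
    reads <- st$kept
  }
  kept_ids <- vapply(reads, function(r) r$read_id, "")
  truth <- sim$truth[vapply(sim$truth, function(tr) tr$read_id, "") %in%
                       kept_ids]

  lab <- label_reads(reads, refs$records)
  sets <- prepare_training_sets(lab$instances, balance = config$balance,
                                seed = config$seed + 2L)
  model <- train_error_classifier(sets, omega = config$omega,
                                  sigma = config$sigma, C = config$C)
  evaluation <- evaluate_classifier(model, sets$subset_b)

  masks <- predict_mask(model, reads)
  records <- reads_to_records(reads)[, c("id", "seq", "abundance")]
  derep <- dereplicate_reads(records, masks)
  proj <- align_to_template(derep$records, refs$records, derep$masks)
  clu <- precluster_masked(proj$reads, diff_pct = config$diff_pct)
  originals <- stats::setNames(derep$records$seq, derep$records$id)
  corrected <- restore_masks(clu, originals)

  report_raw <- compute_error_report(records, refs$records,
                                     margin = config$margin)
  report_denoised <- compute_error_report(corrected, refs$records,
                                          margin = config$margin)
  agree <- label_agreement(lab$labels, truth)

  summary <- data.frame(
    n_reads = config$n_reads,
    n_kept = length(reads),
    n_unique = nrow(derep$records),
    n_clusters = nrow(clu$clusters),
    sensitivity = evaluation$sensitivity,
    specificity = evaluation$specificity,
    label_agreement = agree$agreement,
    error_rate_raw = report_raw$error_rate,
    error_rate_denoised = report_denoised$error_rate,
    relative_reduction = 1 - report_denoised$error_rate /
      report_raw$error_rate,
    chimera_pct_raw = report_raw$chimera_pct
  )
  res <- structure(list(
    config = config, references = refs, truth = truth,
    trim_report = trim$report, model = model, evaluation = evaluation,
    training_sets = sets, masks = masks, derep = derep,
    cluster_result = clu,
    corrected = corrected, report_raw = report_raw,
    report_denoised = report_denoised, label_agreement = agree,
    summary = summary), class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result>\n")
  cat(sprintf("  reads: %d simulated, %d kept, %d unique, %d clusters\n",
              s$n_reads, s$n_kept, s$n_unique, s$n_clusters))
  cat(sprintf("  classifier (held out): sensitivity %.3f, specificity %.3f\n",
              s$sensitivity, s$specificity))
  cat(sprintf("  error rate: %.5f raw -> %.5f denoised (%.1f%% reduction)\n",
              s$error_rate_raw, s$error_rate_denoised,
              100 * s$relative_reduction))
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_sequences(res$corrected, file.path(out_dir, "corrected.fasta"),
                  format = "fasta")
  write_classifier(res$model, file.path(out_dir, "model.json"))
  utils::write.table(res$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$cluster_result$merge_log,
                     file.path(out_dir, "merges.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

#' Agreement between alignment-derived labels and simulator bookkeeping
#'
#' Matches per-read (position, type) error events from the reference-based
#' labelling against the simulator's ground-truth log; the agreement is the
#' fraction of truth events (weighted by multiplicity) that the labelling
#' reproduced exactly.
#'
#' @param labels Named list of per-read event tables (from
#'   [label_reads]`$labels`).
#' @param truth Truth list from [simulate_reads].
#' @return List: `agreement`, `n_truth`, `n_labelled`, `n_matched`.
#' @export
label_agreement <- function(labels, truth) {
  n_truth <- 0L; n_lab <- 0L; matched <- 0L
  for (tr in truth) {
    tev <- tr$events
    lev <- labels[[tr$read_id]]
    n_truth <- n_truth + sum(tev$n)
    if (!is.null(lev)) n_lab <- n_lab + sum(lev$n)
    if (is.null(lev) || !nrow(lev) || !nrow(tev)) next
    key_t <- paste(tev$position, tev$type)
    key_l <- paste(lev$position, lev$type)
    common <- intersect(key_t, key_l)
    matched <- matched +
      sum(pmin(tev$n[match(common, key_t)], lev$n[match(common, key_l)]))
  }
  list(agreement = if (n_truth > 0) matched / n_truth else 1,
       n_truth = n_truth, n_labelled = n_lab, n_matched = matched)
}

#' Run the bundled end-to-end self-test scenario
#'
#' Runs [run_pipeline] on the default simulation (10 generated references,
#' 2,000 reads, fixed seed) and checks the pipeline's core guarantees:
#' the 13-attribute feature schema, classifier sensitivity/specificity
#' gates, truth-label agreement, abundance conservation, and a strict
#' error-rate reduction of at least 40%.
#'
#' @param seed Integer seed for the scenario.
#' @param verbose Print the pass/fail table.
#' @return Data.frame (`check`, `value`, `pass`) with attribute `passed`
#'   (all checks green) and attribute `result` (the `pipeline_result`).
#' @export
run_selftest <- function(seed = 7L, verbose = TRUE) {
  res <- run_pipeline(pipeline_config(seed = as.integer(seed)))
  s <- res$summary
  n_attrs <- length(feature_columns())
  ab_in <- s$n_kept                      # every kept read has abundance 1
  ab_out <- sum(res$corrected$abundance)
  checks <- data.frame(
    check = c("feature schema has 13 attributes",
              "classifier sensitivity >= 0.5",
              "classifier specificity >= 0.9",
              "truth-label agreement >= 0.95",
              "abundance conserved through clustering",
              "denoised error rate < raw",
              "relative error reduction >= 40%"),
    value = c(n_attrs, s$sensitivity, s$specificity, s$label_agreement,
              ab_out - ab_in, s$error_rate_denoised - s$error_rate_raw,
              s$relative_reduction),
    pass = c(n_attrs == 13L, s$sensitivity >= 0.5, s$specificity >= 0.9,
             s$label_agreement >= 0.95, ab_out == ab_in,
             s$error_rate_denoised < s$error_rate_raw,
             s$relative_reduction >= 0.4)
  )
  attr(checks, "passed") <- all(checks$pass)
  attr(checks, "result") <- res
  if (verbose) {
    print(checks[, c("check", "value", "pass")], row.names = FALSE)
    cat(if (all(checks$pass)) "All checks passed.\n" else
      "SELF-TEST FAILURES PRESENT.\n")
  }
  invisible(checks)
}
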