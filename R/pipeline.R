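# One-call orchestration: simulate (or read) -> consensus -> assign ->
# enrich -> overlap, from a single validated configuration, with a
# machine-readable run report.

# every key a configuration may carry, with its default (NULL = required
# or absent); kept in one place so unknown keys can be rejected loudly
config_schema <- function() {
  list(
    annotation = NULL,          # path to GFF3 (real-data mode)
    treatment_peaks = NULL,     # character vector of narrowPeak paths
    control_peaks = NULL,       # character vector of narrowPeak paths
    reference_set = NULL,       # optional gene-list path for overlap test
    simulation = NULL,          # named list of simulation_params overrides
    fdr_threshold = 0.001,
    upstream_bp = 3000L,
    downstream_bp = 1500L,
    assignment_anchor = "coding",
    enrichment_anchor = "transcript",
    bin_width = 100L,
    B = 10000L,
    alpha = 0.05,
    seed = NULL,                # required
    output_dir = NULL           # required
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a named list (or a path to a YAML file holding one), rejects
#' unknown keys, fills documented defaults (FDR 0.001, window 3,000 bp
#' upstream / 1,500 bp downstream, coding-span assignment anchor,
#' transcript-span enrichment anchor, 10,000 bootstrap simulations, alpha
#' 0.05) and range-checks every field. Exactly one input mode must be
#' given: either `annotation` + `treatment_peaks` + `control_peaks`
#' (real-data mode) or a `simulation` block of [simulation_params()]
#' overrides (the simulation seed is derived from the run seed).
#'
#' @param raw named list or YAML path.
#' @return Validated list of class `pipeline_config`; the names of fields
#'   that were defaulted are in `attr(, "defaulted")`.
#' @export
validate_config <- function(raw) {
  if (is.character(raw) && length(raw) == 1L) raw <- yaml::read_yaml(raw)
  if (!is.list(raw)) stop("config must be a named list or a YAML path")
  schema <- config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- schema
  cfg[names(raw)] <- raw
  defaulted <- setdiff(names(schema)[!vapply(schema, is.null, logical(1))],
                       names(raw))
  if (is.null(cfg$seed)) stop("config requires a seed")
  if (is.null(cfg$output_dir)) stop("config requires an output_dir")
  cfg$seed <- as.integer(cfg$seed)
  sim_mode <- !is.null(cfg$simulation)
  real_mode <- !is.null(cfg$annotation) || !is.null(cfg$treatment_peaks) ||
    !is.null(cfg$control_peaks)
  if (sim_mode && real_mode) {
    stop("provide either input files or a simulation block, not both")
  }
  if (!sim_mode) {
    if (is.null(cfg$annotation) || is.null(cfg$treatment_peaks)) {
      stop("real-data mode requires annotation and treatment_peaks")
    }
  } else {
    extra <- setdiff(names(cfg$simulation),
                     setdiff(names(formals(simulation_params)), "seed"))
    if (length(extra)) {
      stop("unknown simulation key(s): ", paste(extra, collapse = ", "))
    }
  }
  range_check <- function(name, lo, hi, open = FALSE) {
    v <- cfg[[name]]
    bad <- !is.numeric(v) || length(v) != 1L || is.na(v) ||
      (open && (v <= lo || v >= hi)) || (!open && (v < lo || v > hi))
    if (bad) {
      stop(sprintf("%s must be in %s%s, %s%s; got %s", name,
                   if (open) "(" else "[", format(lo), format(hi),
                   if (open) ")" else "]", format(cfg[[name]])))
    }
  }
  range_check("fdr_threshold", 0, 1, open = TRUE)
  range_check("alpha", 0, 1, open = TRUE)
  range_check("upstream_bp", 0, Inf)
  range_check("downstream_bp", 0, Inf)
  range_check("bin_width", 1, Inf)
  range_check("B", 1, Inf)
  if (!cfg$assignment_anchor %in% c("coding", "transcript")) {
    stop("assignment_anchor must be 'coding' or 'transcript'")
  }
  if (!cfg$enrichment_anchor %in% c("coding", "transcript")) {
    stop("enrichment_anchor must be 'coding' or 'transcript'")
  }
  for (k in c("upstream_bp", "downstream_bp", "bin_width", "B")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  structure(cfg, defaulted = defaulted, class = "pipeline_config")
}

#' Run the full target-identification pipeline
#'
#' Executes, in order: input acquisition (simulation or file reading),
#' FDR filtering and replicate-consensus intersection, control exclusion,
#' window-based target assignment, bootstrap positional-enrichment testing
#' and (when a reference set is available) the target-set overlap test.
#' All intermediate files are written under `output_dir`; the run is a
#' pure function of the configuration, including its seed (the bootstrap
#' stage draws from `seed + 3`; a simulation block consumes `seed` to
#' `seed + 2`).
#'
#' @param config a `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @param quiet suppress per-stage progress messages.
#' @return A list of class `run_report`: configuration echo, per-stage
#'   record counts, enrichment table, overlap result, target gene set,
#'   package version, seed and timestamp. Also written as
#'   `report.json` in `output_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  for (f in attr(config, "defaulted")) {
    say("config: %s defaulted to %s", f, format(config[[f]]))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)

  truth <- NULL
  reference <- NULL
  if (!is.null(config$simulation)) {
    params <- do.call(simulation_params,
                      c(list(seed = config$seed), config$simulation))
    annotation <- simulate_genome(params)
    sim <- simulate_peaksets(annotation, params)
    treatment <- sim$treatment
    control <- sim$control
    truth <- sim$truth
    reference <- simulate_reference_set(truth, annotation, params)
    write_simulated_dataset(sim, annotation, out("input"))
    writeLines(reference, out("input", "reference_set.txt"))
    say("simulated %d genes, %d true targets, %d+%d replicates",
        length(annotation), length(truth$true_target_ids),
        length(treatment), length(control))
  } else {
    annotation <- read_gff3(config$annotation)
    treatment <- lapply(config$treatment_peaks, read_narrowpeak)
    names(treatment) <- sprintf("t%d", seq_along(treatment))
    control <- lapply(config$control_peaks, read_narrowpeak)
    if (length(control)) names(control) <- sprintf("c%d", seq_along(control))
    if (!is.null(config$reference_set)) {
      reference <- read_gene_list(config$reference_set)
    }
    say("read %d genes, %d treatment and %d control replicates",
        length(annotation), length(treatment), length(control))
  }

  peaks_in <- sum(vapply(treatment, length, integer(1)))
  passing <- lapply(treatment, filter_by_fdr, config$fdr_threshold)
  peaks_passing <- sum(vapply(passing, length, integer(1)))
  regions <- intersect_replicates(passing)
  n_consensus <- length(regions)
  regions <- exclude_control(regions, control, config$fdr_threshold)
  write_consensus_bed(regions, out("consensus.bed"))
  say("consensus: %d/%d peaks pass FDR < %g; %d regions, %d after control exclusion",
      peaks_passing, peaks_in, config$fdr_threshold, n_consensus,
      length(regions))

  windows <- build_windows(annotation, config$upstream_bp,
                           config$downstream_bp, config$assignment_anchor)
  assignments <- assign_regions(regions, windows, annotation)
  targets <- target_gene_set(assignments)
  write_assignments(assignments, out("assignments.tsv"))
  writeLines(targets, out("target_genes.txt"))
  say("assignment: %d assignments, %d target genes",
      nrow(assignments), length(targets))

  enrichment <- NULL
  histogram <- NULL
  if (length(targets)) {
    observed <- observed_zone_counts(assignments, annotation,
                                     config$upstream_bp, config$downstream_bp,
                                     config$enrichment_anchor)
    null <- bootstrap_null(annotation, targets, observed$total, config$B,
                           seed = config$seed + 3L, config$upstream_bp,
                           config$downstream_bp, config$enrichment_anchor)
    enrichment <- enrichment_test(observed, null, config$alpha)
    histogram <- metagene_histogram(assignments, annotation, config$bin_width,
                                    config$upstream_bp, config$downstream_bp)
    utils::write.table(histogram, out("histogram.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(enrichment, out("enrichment.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    for (i in seq_len(nrow(enrichment))) {
      say("enrichment: %s observed %.3f vs null %.3f; p_enriched=%.2g p_depleted=%.2g (%s)",
          enrichment$zone[i], enrichment$observed_fraction[i],
          enrichment$null_mean[i], enrichment$p_enriched[i],
          enrichment$p_depleted[i], enrichment$direction[i])
    }
  }

  overlap <- NULL
  if (!is.null(reference)) {
    overlap <- overlap_test(targets, intersect(reference, annotation$gene_id),
                            annotation$gene_id)
    jsonlite::write_json(unclass_deep(overlap), out("overlap.json"),
                         auto_unbox = TRUE, digits = NA)
    say("overlap: %d shared genes, p = %.3g",
        overlap$table$n_both, overlap$p_two_tailed)
  }

  report <- structure(list(
    config = unclass_config(config),
    counts = list(
      peaks_in = peaks_in,
      peaks_passing_fdr = peaks_passing,
      consensus_regions = n_consensus,
      regions_after_control = length(regions),
      assignments = nrow(assignments),
      target_genes = length(targets)
    ),
    target_genes = targets,
    enrichment = enrichment,
    overlap = if (is.null(overlap)) NULL else unclass_deep(overlap),
    recovery = if (is.null(truth)) NULL else
      recovery_metrics(targets, truth$true_target_ids),
    version = as.character(utils::packageVersion("peakTargets")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_report")
  jsonlite::write_json(report[names(report) != "timestamp"],
                       out("report.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", force = TRUE)
  report
}

# precision/recall of a recovered target set against simulated truth
recovery_metrics <- function(targets, truth_ids) {
  tp <- length(intersect(targets, truth_ids))
  list(
    true_targets = length(truth_ids),
    recovered = length(targets),
    true_positives = tp,
    precision = if (length(targets)) tp / length(targets) else NA_real_,
    recall = if (length(truth_ids)) tp / length(truth_ids) else NA_real_
  )
}

unclass_config <- function(config) {
  x <- unclass(config)
  attr(x, "defaulted") <- NULL
  x[!vapply(x, is.null, logical(1))]
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run (seed ", x$seed, ")\n", sep = "")
  for (k in names(x$counts)) cat(sprintf("  %-22s %d\n", k, x$counts[[k]]))
  if (!is.null(x$enrichment)) {
    cat("  enrichment:\n")
    print(x$enrichment, row.names = FALSE)
  }
  if (!is.null(x$overlap)) {
    cat(sprintf("  overlap p = %.3g (%d shared)\n",
                x$overlap$p_two_tailed, x$overlap$table$n_both))
  }
  if (!is.null(x$recovery)) {
    cat(sprintf("  recovery: precision %.3f, recall %.3f\n",
                x$recovery$precision, x$recovery$recall))
  }
  invisible(x)
}
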