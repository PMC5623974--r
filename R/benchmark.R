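# Benchmark orchestration: YAML-driven evaluation of one or more pipelines
# against a truth database, with a tidy report ordered by F-score.

default_thresholds <- function() list(splice = 10L, mutation = 5L, fusion = 20L)

#' Run a benchmark from a configuration
#'
#' The configuration (YAML file or list) names the truth directory, the
#' evaluation thresholds and, per pipeline, the prediction files per event
#' type:
#'
#' ```yaml
#' truth_dir: path/to/dataset
#' thresholds: {splice: 10, mutation: 5, fusion: 20}
#' max_hits: 1
#' count_ignored_as_fp: false
#' tp_dir: path/for/tp-lists   # optional
#' pipelines:
#'   - name: my_pipeline
#'     alignment: aln.sam      # SAM
#'     splice: junctions.bed   # BED (or a SAM to extract N ops from)
#'     snv: calls.vcf          # VCF
#'     insertion: calls.vcf    # VCF
#'     deletion: calls.vcf     # VCF
#'     fusion: fusions.tsv     # TSV
#' ```
#'
#' Every named event type of every pipeline is evaluated independently;
#' a missing or unreadable file fails that row only. Report rows are
#' ordered by decreasing F-score. When `tp_dir` is set, the true-positive
#' identifier list of each pipeline x event is written there (one
#' identifier per line) for downstream intersection analysis.
#'
#' @param config Path to a YAML file or an equivalent list.
#' @return Object of class `sim_benchmark`: list with `report` (tibble: pipeline,
#'   event, tp, fp, fn, precision, recall, fscore, status) and `tp`
#'   (nested list of TP identifier vectors).
#' @export
run_benchmark <- function(config) {
  if (is.character(config)) {
    config <- tryCatch(yaml::read_yaml(config), error = function(e) {
      stop("Invalid YAML configuration: ", conditionMessage(e))
    })
  }
  if (is.null(config$truth_dir)) stop("Configuration must name truth_dir")
  truth <- read_truth_db(config$truth_dir)
  thr <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  max_hits <- config$max_hits %||% 1L
  ign_fp <- isTRUE(config$count_ignored_as_fp)
  pipelines <- config$pipelines %||% list()

  rows <- list()
  tp_lists <- list()
  for (pl in pipelines) {
    name <- pl$name %||% "pipeline"
    for (event in intersect(c("alignment", "splice", "snv", "insertion",
                              "deletion", "fusion"), names(pl))) {
      path <- pl[[event]]
      conf <- tryCatch(
        evaluate_event(event, path, truth, thr, max_hits, ign_fp),
        error = function(e) e
      )
      if (inherits(conf, "error")) {
        message("benchmark: ", name, "/", event, " failed: ",
                conditionMessage(conf))
        rows[[length(rows) + 1]] <- tibble::tibble(
          pipeline = name, event = event, tp = NA_integer_, fp = NA_integer_,
          fn = NA_integer_, precision = NA_real_, recall = NA_real_,
          fscore = NA_real_, status = "failed")
      } else {
        rows[[length(rows) + 1]] <- dplyr::mutate(
          compute_metrics(conf), pipeline = name, event = event,
          status = "ok", .before = 1)
        tp_lists[[name]][[event]] <- conf$tp_ids
      }
    }
  }
  report <- if (length(rows) > 0) {
    dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$fscore))
  } else {
    tibble::tibble(pipeline = character(), event = character(),
                   tp = integer(), fp = integer(), fn = integer(),
                   precision = double(), recall = double(),
                   fscore = double(), status = character())
  }
  if (!is.null(config$tp_dir)) {
    dir.create(config$tp_dir, recursive = TRUE, showWarnings = FALSE)
    for (name in names(tp_lists)) {
      for (event in names(tp_lists[[name]])) {
        writeLines(tp_lists[[name]][[event]],
                   file.path(config$tp_dir, paste0(name, "_", event, "_tp.txt")))
      }
    }
  }
  structure(list(report = report, tp = tp_lists,
                 thresholds = thr, max_hits = max_hits),
            class = "sim_benchmark")
}

evaluate_event <- function(event, path, truth, thr, max_hits, ign_fp) {
  switch(
    event,
    alignment = evaluate_alignments(path, truth$n_read_pairs, max_hits, ign_fp),
    splice = {
      pred <- if (grepl("\\.sam$", path)) extract_sam_junctions(path) else
        read_junction_bed(path)
      evaluate_splices(pred, truth$splices, thr$splice, ign_fp)
    },
    snv = evaluate_mutations(read_vcf_predictions(path), truth$mutations,
                             "SNV", thr$mutation, ign_fp),
    insertion = evaluate_mutations(read_vcf_predictions(path), truth$mutations,
                                   "INS", thr$mutation, ign_fp),
    deletion = evaluate_mutations(read_vcf_predictions(path), truth$mutations,
                                  "DEL", thr$mutation, ign_fp),
    fusion = evaluate_fusions(read_fusion_tsv(path), truth$fusions,
                              truth$chrom_lengths, thr$fusion, ign_fp),
    stop("Unknown event type: ", event)
  )
}

#' @exportS3Method base::print
print.sim_benchmark <- function(x, ...) {
  cat("<sim_benchmark> ", length(unique(x$report$pipeline)), " pipeline(s), ",
      nrow(x$report), " evaluation(s)\n", sep = "")
  print(x$report)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a benchmark result
#'
#' @param x A `sim_benchmark` object.
#' @param ... Unused.
#' @return The report tibble: one row per pipeline x event with confusion
#'   counts and metrics, ordered by decreasing F-score.
#' @export
tidy.sim_benchmark <- function(x, ...) {
  x$report
}

#' One-row summary of a benchmark result
#'
#' @param x A `sim_benchmark` object.
#' @param ... Unused.
#' @return Tibble with the number of pipelines and evaluations, the number
#'   of failed rows, and the best pipeline by mean F-score.
#' @export
glance.sim_benchmark <- function(x, ...) {
  ok <- x$report[x$report$status == "ok", , drop = FALSE]
  best <- if (nrow(ok) > 0) {
    agg <- stats::aggregate(fscore ~ pipeline, data = ok, FUN = mean)
    agg$pipeline[which.max(agg$fscore)]
  } else NA_character_
  tibble::tibble(
    n_pipelines = length(unique(x$report$pipeline)),
    n_evaluations = nrow(x$report),
    n_failed = sum(x$report$status == "failed"),
    best_pipeline = best
  )
}

#' Precision/recall plot of a benchmark result
#'
#' One point per pipeline x event type, the standard display for comparing
#' pipelines on a simulated dataset.
#'
#' @param object A `sim_benchmark` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_benchmark <- function(object, ...) {
  df <- object$report[object$report$status == "ok", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   colour = .data$pipeline,
                                   shape = .data$event)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot precision/recall for a benchmark report tibble
#'
#' Data-frame-first companion to [autoplot.sim_benchmark()].
#'
#' @param report A benchmark report tibble (from `tidy()`).
#' @return A ggplot object.
#' @export
plot_benchmark <- function(report) {
  autoplot.sim_benchmark(list(report = report))
}
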