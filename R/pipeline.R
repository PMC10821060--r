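#' Run the full pipeline on a synthetic participant
#'
#' Convenience wrapper chaining the stages end to end: simulate a
#' participant's lab and home sessions, select the best method on the lab
#' data, classify the home session by 1-nearest-neighbor, and score the
#' predictions against the generator's ground truth. Optionally writes all
#' outputs (sessions, selection table, report JSON and predictions CSV) to
#' a directory; with a fixed seed and configuration the written outputs
#' are byte-identical across runs.
#'
#' @param config a [synthetic_config()].
#' @param seed root seed for the simulation.
#' @param grid method grid for selection.
#' @param alpha significance level for selection.
#' @param out_dir optional output directory.
#' @return list with `lab`, `home`, `truth`, `selection`, `predictions`,
#'   `report`.
#' @export
run_pipeline <- function(config = synthetic_config(), seed = 1,
                         grid = method_grid(), alpha = 0.05,
                         out_dir = NULL) {
  sim <- simulate_participant(config, seed)
  selection <- select_method(sim$lab, grid = grid, alpha = alpha)
  predictions <- classify_session(sim$home, sim$lab, selection)
  report <- score_session(predictions, sim$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_session(sim$lab, file.path(out_dir, "lab"))
    write_session(sim$home, file.path(out_dir, "home"))
    utils::write.csv(sim$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(selected = format(selection$selected), trace = selection$trace,
           table = selection$table),
      file.path(out_dir, "selection.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    write_report(report, file.path(out_dir, "report.json"))
  }
  list(lab = sim$lab, home = sim$home, truth = sim$truth,
       selection = selection, predictions = predictions, report = report)
}
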