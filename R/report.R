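#' Write an efficiency-pipeline report as JSON
#'
#' Serializes the counts, efficiency, distance summary and unbound-gold
#' fraction of an [efficiency_pipeline()] result; the per-particle distances
#' and bound flags go to a companion CSV when `csv_path` is given.
#'
#' @param result an [efficiency_pipeline()] result.
#' @param path output JSON path.
#' @param csv_path optional per-particle CSV path.
#' @return `path`, invisibly.
#' @export
write_efficiency_report <- function(result, path, csv_path = NULL) {
  rep <- list(
    n_labeled = result$efficiency$n_labeled,
    n_unlabeled = result$efficiency$n_unlabeled,
    efficiency = result$efficiency$efficiency,
    unbound_gold_fraction = result$unbound_gold_fraction,
    distance_mean_nm = if (is.null(result$summary)) NA
                       else result$summary$mean,
    distance_sd_nm = if (is.null(result$summary)) NA
                     else result$summary$sd,
    n_distances = if (is.null(result$summary)) 0L else result$summary$n)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(csv_path)) {
    utils::write.csv(
      data.frame(min_distance_nm = result$distances, bound = result$bound),
      csv_path, row.names = FALSE)
  }
  invisible(path)
}
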