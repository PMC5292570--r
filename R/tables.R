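#' Packaged reference tables
#'
#' Plain-text transcriptions of the published per-trial reference tables:
#' \code{"correlations"} (12 wet-vs-PPy envelope correlation coefficients),
#' \code{"accuracy"} (per task/subject/electrode recognition accuracies in
#' percent, long format) and \code{"impedance"} (per-trial source-impedance
#' imbalances at the three rest-state noise levels).
#' \code{"published_summaries"} holds the printed Mean/SD summary values with
#' their printed precision and comparison tolerance.
#'
#' @param name One of \code{"correlations"}, \code{"accuracy"},
#'   \code{"impedance"}, \code{"published_summaries"}.
#' @return A data.frame.
#' @examples
#' head(referenceTable("impedance"))
#' @export
referenceTable <- function(name = c("correlations", "accuracy", "impedance",
                                    "published_summaries")) {
  name <- match.arg(name)
  file <- switch(name,
    correlations = "table1_correlations.csv",
    accuracy = "table2_accuracy.csv",
    impedance = "table3_impedance.csv",
    published_summaries = "published_summaries.csv")
  path <- system.file("extdata", file, package = "myobench", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Recompute the printed summary statistics from the reference tables
#'
#' Recomputes every Mean/SD summary value from the packaged per-trial tables
#' — the correlation mean and SD, the per-task, per-subject and overall
#' accuracy means, and the per-level impedance-imbalance means and SDs — and
#' compares each against its printed value within the recorded tolerance
#' (half a unit in the last printed decimal place); the half-away-from-zero
#' rounding to printed precision is reported alongside.
#'
#' @return A data.frame with columns \code{quantity}, \code{computed},
#'   \code{rounded}, \code{printed}, \code{match}.
#' @examples
#' tab <- reproduceTables()
#' all(tab$match)
#' @export
reproduceTables <- function() {
  pub <- referenceTable("published_summaries")

  corr <- referenceTable("correlations")
  acc <- referenceTable("accuracy")
  imp <- referenceTable("impedance")
  accSum <- accuracySummary(acc)
  corrSum <- meanSd(corr$r)

  computed <- c(
    corr_mean_r = corrSum[["mean"]],
    corr_sd_r = corrSum[["sd"]]
  )
  for (i in seq_len(nrow(accSum$perTask))) {
    row <- accSum$perTask[i, ]
    computed[paste0("acc_task_", row$task, "_", row$electrode)] <- row$accuracy
  }
  for (i in seq_len(nrow(accSum$perSubject))) {
    row <- accSum$perSubject[i, ]
    computed[paste0("acc_subject_", row$subject, "_", row$electrode)] <- row$accuracy
  }
  for (i in seq_len(nrow(accSum$overall))) {
    row <- accSum$overall[i, ]
    computed[paste0("acc_overall_", row$electrode)] <- row$accuracy
  }
  for (lv in 1:3) {
    d <- imp[imp$level == lv, ]
    m <- meanSd(d$mag_ohm); p <- meanSd(d$phase_deg)
    computed[paste0("imp_mag_mean_level", lv)] <- m[["mean"]]
    computed[paste0("imp_mag_sd_level", lv)] <- m[["sd"]]
    computed[paste0("imp_phase_mean_level", lv)] <- p[["mean"]]
    computed[paste0("imp_phase_sd_level", lv)] <- p[["sd"]]
  }

  stopifnot(all(pub$quantity %in% names(computed)))
  comp <- computed[pub$quantity]
  rounded <- mapply(roundHalfUp, comp, pub$digits)
  data.frame(quantity = pub$quantity,
             computed = unname(comp),
             rounded = unname(rounded),
             printed = pub$printed,
             match = unname(abs(comp - pub$printed) <= pub$tolerance + 1e-9))
}
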