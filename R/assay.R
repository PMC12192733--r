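#' Kinetic slope of a fluorescence trace
#'
#' Slope of fluorescence increase between minutes 10 and 20,
#' (FLU20 - FLU10) / 10, in fluorescence units per minute. Readings not
#' taken exactly at minutes 10/20 are linearly interpolated from bracketing
#' timepoints; the trace must cover the window.
#'
#' @param times Numeric vector of read times in minutes, strictly
#'   increasing.
#' @param flu Fluorescence readings aligned to `times`.
#' @param window Two endpoints in minutes; default `c(10, 20)`.
#' @return Slope in FLU/minute.
#' @examples
#' kinetic_slope(c(0, 10, 20, 30), c(0, 200, 450, 700))
#' @export
kinetic_slope <- function(times, flu, window = c(10, 20)) {
  stopifnot(length(times) == length(flu), length(times) >= 2,
            all(diff(times) > 0))
  if (min(times) > window[1] || max(times) < window[2]) {
    stop("trace does not cover the minute-", window[1], " to minute-",
         window[2], " window")
  }
  at <- stats::approx(times, flu, xout = window)$y
  (at[2] - at[1]) / (window[2] - window[1])
}

#' Percent inhibition from control and sample slopes
#'
#' 100 * (slope_control - slope_sample) / slope_control. Negative values
#' (activation) are reported as-is, not clamped.
#'
#' @param slope_control Positive uninhibited (control) slope.
#' @param slope_sample Slope(s) in the presence of the test compound.
#' @return Percent inhibition.
#' @examples
#' percent_inhibition(10, 8.5)
#' @export
percent_inhibition <- function(slope_control, slope_sample) {
  if (!is.finite(slope_control) || slope_control <= 0) {
    stop("invalid control: control slope must be positive")
  }
  100 * (slope_control - slope_sample) / slope_control
}

#' Analyze single-point assay kinetics into per-compound inhibition
#'
#' Takes a long kinetics table (one row per read), computes the minute
#' 10-20 slope per trace, averages replicate slopes per compound, and
#' expresses each compound's activity as percent inhibition relative to the
#' mean control slope.
#'
#' @param data Long tibble with columns `compound_id`, `role`
#'   (`"control"`/`"sample"`), `time_min`, `flu`, and optionally
#'   `replicate`.
#' @param window Slope window in minutes; default `c(10, 20)`.
#' @return Tibble with `compound_id`, `slope`, `percent_inhibition`.
#' @export
analyze_kinetics <- function(data, window = c(10, 20)) {
  stopifnot(all(c("compound_id", "role", "time_min", "flu") %in% names(data)))
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  slopes <- data |>
    dplyr::group_by(.data$compound_id, .data$role, .data$replicate) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::summarise(slope = kinetic_slope(.data$time_min, .data$flu, window),
                     .groups = "drop") |>
    dplyr::group_by(.data$compound_id, .data$role) |>
    dplyr::summarise(slope = mean(.data$slope), .groups = "drop")
  controls <- dplyr::filter(slopes, .data$role == "control")
  if (nrow(controls) == 0) stop("no control traces found")
  slope_control <- mean(controls$slope)
  slopes |>
    dplyr::filter(.data$role == "sample") |>
    dplyr::mutate(percent_inhibition =
                    percent_inhibition(slope_control, .data$slope)) |>
    dplyr::select("compound_id", "slope", "percent_inhibition")
}

#' Call screening hits from percent-inhibition values
#'
#' A compound is an experimental hit when its inhibition strictly exceeds
#' the cutoff (default 15% at a single test concentration of 1.5 uM); the
#' boundary value itself is inactive.
#'
#' @param data Tibble with `compound_id` and `percent_inhibition` (e.g.
#'   from [analyze_kinetics()]).
#' @param cutoff Percent-inhibition cutoff; default 15.
#' @param concentration_uM Test concentration recorded with each call;
#'   default 1.5.
#' @return Tibble with `compound_id`, `percent_inhibition`, `active`
#'   (logical), `cutoff`, `concentration_uM`.
#' @export
call_hits <- function(data, cutoff = 15, concentration_uM = 1.5) {
  stopifnot(cutoff >= 0,
            all(c("compound_id", "percent_inhibition") %in% names(data)))
  dplyr::transmute(
    data,
    compound_id = .data$compound_id,
    percent_inhibition = .data$percent_inhibition,
    active = .data$percent_inhibition > cutoff,
    cutoff = cutoff, concentration_uM = concentration_uM)
}

#' Score model predictions against experimental hit calls
#'
#' Builds the confusion matrix treating the experimental hit calls as
#' ground truth and reports the screening-oriented metrics (PPV, NPV, TPR,
#' TNR, ACC) alongside the full metric set.
#'
#' @param predicted Tibble with `compound_id` and predicted `label`
#'   (`"active"`/`"inactive"`).
#' @param hits Hit calls from [call_hits()] (or any tibble with
#'   `compound_id` and logical `active`).
#' @return A `qsar_screen_score`: list with `counts` (tp/tn/fp/fn) and
#'   `metrics` (one-row tibble).
#' @export
score_screen <- function(predicted, hits) {
  stopifnot(all(c("compound_id", "label") %in% names(predicted)),
            all(c("compound_id", "active") %in% names(hits)))
  unmatched <- c(setdiff(predicted$compound_id, hits$compound_id),
                 setdiff(hits$compound_id, predicted$compound_id))
  if (length(unmatched) > 0) {
    stop("unmatched compound ids: ", paste(unique(unmatched), collapse = ", "))
  }
  joined <- dplyr::inner_join(predicted, hits, by = "compound_id")
  truth <- ifelse(joined$active, "active", "inactive")
  counts <- confusion_counts(truth, joined$label)
  metrics <- classification_metrics(counts) |>
    dplyr::mutate(ppv = .data$precision, tpr = .data$recall,
                  tnr = .data$specificity, acc = .data$accuracy)
  structure(list(counts = counts, metrics = metrics, n = nrow(joined)),
            class = "qsar_screen_score")
}

#' @export
print.qsar_screen_score <- function(x, ...) {
  c_ <- x$counts
  cat(sprintf("Screen scoring over %d compounds\n", x$n))
  cat(sprintf("              experimental+  experimental-\n"))
  cat(sprintf("  predicted+  %13d  %13d\n", c_$tp, c_$fp))
  cat(sprintf("  predicted-  %13d  %13d\n", c_$fn, c_$tn))
  cat(sprintf("PPV %.0f%%  NPV %.0f%%  TPR %.0f%%  TNR %.0f%%  ACC %.0f%%\n",
              100 * x$metrics$ppv, 100 * x$metrics$npv, 100 * x$metrics$tpr,
              100 * x$metrics$tnr, 100 * x$metrics$acc))
  invisible(x)
}

#' @method tidy qsar_screen_score
#' @export
tidy.qsar_screen_score <- function(x, ...) {
  dplyr::bind_cols(x$counts, x$metrics)
}

#' @method glance qsar_screen_score
#' @export
glance.qsar_screen_score <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n = x$n), x$counts,
                   dplyr::select(x$metrics, "ppv", "npv", "tpr", "tnr", "acc"))
}

#' Plot a screen confusion matrix
#'
#' @param object A `qsar_screen_score`.
#' @param ... Unused.
#' @return A ggplot tile rendering of the confusion matrix.
#' @method autoplot qsar_screen_score
#' @export
autoplot.qsar_screen_score <- function(object, ...) {
  d <- tibble::tibble(
    predicted = factor(c("active", "active", "inactive", "inactive"),
                       levels = c("active", "inactive")),
    experimental = factor(c("active", "inactive", "active", "inactive"),
                          levels = c("inactive", "active")),
    count = c(object$counts$tp, object$counts$fp,
              object$counts$fn, object$counts$tn),
    outcome = c("correct", "error", "error", "correct"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$experimental,
                                  fill = .data$outcome)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 6) +
    ggplot2::scale_fill_manual(values = c(correct = "#88c999",
                                          error = "#e88a8a")) +
    ggplot2::labs(title = "Predicted vs experimental hit calls") +
    ggplot2::theme_minimal()
}
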