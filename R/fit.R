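#' Fit the gap-null essentiality model to an insertion screen
#'
#' The package's central estimator. Given per-day insertion tables, a feature
#' annotation and gold-standard gene sets, it
#' \enumerate{
#'   \item selects the analysis timepoint ([select_timepoint()]) -- the day at
#'     which essential-gene insertions have washed out of the population while
#'     dispensable-gene insertions persist;
#'   \item calibrates the relaxed and stringent reads-per-insertion thresholds
#'     from the gold sets ([calibrate_read_threshold()]); when the chosen day
#'     leaves a gold class without insertions (late days after decay), it
#'     falls back to the latest day on which both classes carry insertions;
#'   \item builds the [scoring_model()] from the threshold-passing,
#'     orientation-merged sites of the analysis day;
#'   \item scores every annotated feature with the insertion-free-gap null
#'     model ([score_region()]) and classifies it E/NE/F;
#'   \item derives the genome-wide essentiality landscape
#'     ([essential_landscape()]).
#' }
#'
#' @param tables Insertion data: a single table with a `day` column, or a
#'   named list of tables keyed by day label.
#' @param annotation Feature annotation data.frame (`id`, `type`, `start`,
#'   `end`, `strand`).
#' @param gold A [gold_set()].
#' @param G Genome length in bp; defaults to the `G` attribute of the first
#'   table.
#' @param alpha Significance level for the gap null (default 0.01).
#' @param read_threshold `"stringent"` (default), `"relaxed"`, or an explicit
#'   integer threshold.
#' @param w Neighbourhood radius override in bp (default `ceiling(G/(2N))`).
#' @param day Analysis day override (skips timepoint selection).
#' @param circular Treat the genome as circular (default TRUE).
#' @return Object of class `essfit` with components `model`, `calls`
#'   (per-feature data.frame), `calibration`, `timepoint`, `landscape`,
#'   `annotation`, `day`, `table` (analysis-day insertions).
#' @seealso [summary.essfit()], [predict.essfit()], [plot.essfit()]
#' @export
fit_essentiality <- function(tables, annotation, gold, G = NULL,
                             alpha = 0.01, read_threshold = "stringent",
                             w = NULL, day = NULL, circular = TRUE) {
  assert_annotation(annotation)
  day_tables <- as_day_list(tables)
  G <- G %||% attr(day_tables[[1]], "G")
  if (is.null(G) || is.na(G)) stop("genome length G is required", call. = FALSE)

  timepoint <- NULL
  if (is.null(day)) {
    if (length(day_tables) > 1L) {
      timepoint <- select_timepoint(day_tables, gold, annotation)
      day <- timepoint$day
    } else {
      day <- as.numeric(names(day_tables)[1])
    }
  }
  table <- day_tables[[as.character(day)]]
  if (is.null(table)) stop("no insertion table for day ", day, call. = FALSE)

  calib <- calibrate_with_fallback(day_tables, day, gold, annotation)
  thr <- if (is.numeric(read_threshold)) as.integer(read_threshold)
         else switch(match.arg(read_threshold, c("stringent", "relaxed")),
                     stringent = calib$stringent, relaxed = calib$relaxed)

  sites <- threshold_sites(table, thr)
  if (nrow(sites) == 0L)
    stop("no insertion passes the read threshold: N = 0 is degenerate", call. = FALSE)
  model <- scoring_model(G = G, N = nrow(sites), alpha = alpha, w = w,
                         read_threshold = thr, circular = circular)
  cover <- evidence_cover(sites$position, G, model$N, model$alpha, model$w,
                          model$circular)
  calls <- score_features(annotation, cover, G)
  landscape <- landscape_from_cover(annotation, calls, cover, G)

  structure(list(model = model, calls = calls, calibration = calib,
                 timepoint = timepoint, landscape = landscape,
                 annotation = annotation, day = day, table = table,
                 cover = cover),
            class = "essfit")
}

calibrate_with_fallback <- function(day_tables, day, gold, annotation) {
  try_day <- function(d) tryCatch(
    c(calibrate_read_threshold(day_tables[[as.character(d)]], gold, annotation),
      list(calibration_day = d)),
    error = function(e) NULL)
  res <- try_day(day)
  if (!is.null(res)) return(res)
  days <- sort(as.numeric(names(day_tables)), decreasing = TRUE)
  for (d in setdiff(days, day)) {
    res <- try_day(d)
    if (!is.null(res)) {
      message("gold class empty on day ", day,
              "; thresholds calibrated on day ", d)
      return(res)
    }
  }
  stop("threshold calibration failed on every day (a gold class has no ",
       "insertions anywhere)", call. = FALSE)
}

score_features <- function(annotation, cover, G) {
  res <- lapply(seq_len(nrow(annotation)), function(i)
    score_region_core(annotation$start[i], annotation$end[i], cover, G))
  cbind(annotation[, c("id", "type", "start", "end", "strand"), drop = FALSE],
        do.call(rbind, lapply(res, as.data.frame)))
}

#' @export
print.essfit <- function(x, ...) {
  cat("Transposon-screen essentiality fit\n")
  cat(sprintf("  analysis day %g; thresholds relaxed %d / stringent %d (applied: %d reads)\n",
              x$day, x$calibration$relaxed, x$calibration$stringent,
              x$model$read_threshold))
  cat(sprintf("  N = %d insertions, G = %d bp, alpha = %g, w = %d bp\n",
              x$model$N, as.integer(x$model$G), x$model$alpha, x$model$w))
  orf <- x$calls[x$calls$type == "ORF", ]
  tab <- table(factor(orf$category, levels = c("E", "NE", "F")))
  cat(sprintf("  ORFs: %d E / %d NE / %d F of %d\n",
              tab["E"], tab["NE"], tab["F"], nrow(orf)))
  cat(sprintf("  essential genome: %d bp (%.1f%%)\n",
              x$landscape$essential_bp, 100 * x$landscape$essential_fraction))
  invisible(x)
}

#' @export
coef.essfit <- function(object, ...) {
  c(G = object$model$G, N = object$model$N, alpha = object$model$alpha,
    w = object$model$w, read_threshold = object$model$read_threshold,
    relaxed = object$calibration$relaxed,
    stringent = object$calibration$stringent, day = object$day)
}

#' Summarise an essentiality fit
#'
#' Per-feature-class E/NE/F counts and percentages plus the landscape
#' headline numbers.
#'
#' @param object An `essfit`.
#' @param ... Unused.
#' @return Object of class `summary.essfit`.
#' @export
summary.essfit <- function(object, ...) {
  cls <- split(object$calls, object$calls$type)
  per_class <- do.call(rbind, lapply(names(cls), function(ty) {
    tab <- table(factor(cls[[ty]]$category, levels = c("E", "NE", "F")))
    data.frame(type = ty, n = nrow(cls[[ty]]),
               E = as.integer(tab["E"]), NE = as.integer(tab["NE"]),
               F = as.integer(tab["F"]),
               pct_E = 100 * tab[["E"]] / nrow(cls[[ty]]),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_class = per_class, coef = coef(object),
                 essential_bp = object$landscape$essential_bp,
                 essential_fraction = object$landscape$essential_fraction),
            class = "summary.essfit")
}

#' @export
print.summary.essfit <- function(x, ...) {
  cat("Essentiality fit summary\n")
  cat(sprintf("  model: N = %d, alpha = %g, w = %d, threshold = %d reads, day %g\n",
              as.integer(x$coef["N"]), x$coef["alpha"], as.integer(x$coef["w"]),
              as.integer(x$coef["read_threshold"]), x$coef["day"]))
  cat(sprintf("  essential genome: %d bp (%.1f%%)\n\n",
              x$essential_bp, 100 * x$essential_fraction))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Score new regions with a fitted essentiality model
#'
#' @param object An `essfit`.
#' @param regions data.frame with `start` and `end` columns (and optionally
#'   `id`).
#' @param ... Unused.
#' @return data.frame of [score_region()] results, one row per region.
#' @export
predict.essfit <- function(object, regions, ...) {
  res <- lapply(seq_len(nrow(regions)), function(i)
    as.data.frame(score_region_core(as.integer(regions$start[i]),
                                    as.integer(regions$end[i]),
                                    object$cover, object$model$G)))
  out <- do.call(rbind, res)
  if (!is.null(regions$id)) out <- cbind(id = regions$id, out)
  out
}

#' Plot the essentiality landscape
#'
#' A linear track of the genome with essential segments in black and
#' insertion sites as ticks, the textual analogue of a genome-circle
#' essentiality map.
#'
#' @param x An `essfit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.essfit <- function(x, ...) {
  G <- x$model$G
  graphics::plot(NA, xlim = c(1, G), ylim = c(0, 2), yaxt = "n",
                 xlab = "genome position (bp)", ylab = "",
                 main = "Essentiality landscape", ...)
  graphics::axis(2, at = c(0.5, 1.5), labels = c("insertions", "essential"),
                 las = 1)
  seg <- x$landscape$essential_segments
  if (nrow(seg))
    graphics::rect(seg$start, 1.25, seg$end, 1.75, col = "black", border = NA)
  pos <- x$cover$positions
  graphics::segments(pos, 0.25, pos, 0.75, col = grDevices::grey(0.4, 0.3))
  invisible(x)
}
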