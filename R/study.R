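#' Build or validate a study measurement matrix
#'
#' A study matrix is a tidy table of per-subject, per-segment, per-time mean
#' ICG saturations on the 0--255 scale, with columns `subject_id`, `segment`
#' (`"right"` or `"left"`), `time_label` (`"pre"`, `"post15"`, `"post45"`,
#' `"post75"`, `"post105"`, `"post135"`) and `saturation`. At most one
#' observation may exist per (subject, segment, time); missing cells are
#' permitted and always skipped, never imputed (subjects can drop out, e.g.
#' through intra-operative death).
#'
#' @param x A data frame with the four columns above.
#' @return A validated tibble of class `study_matrix`.
#' @export
as_study_matrix <- function(x) {
  need <- c("subject_id", "segment", "time_label", "saturation")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(sprintf("A study matrix needs columns %s.", paste(need, collapse = ", ")),
          class = "icgquant_bad_study")
  }
  x <- as_tibble(x)[need]
  x$subject_id <- as.character(x$subject_id)
  x$segment <- as.character(x$segment)
  x$time_label <- as.character(x$time_label)
  if (!all(x$segment %in% SEGMENTS)) {
    abort(sprintf("`segment` must be one of: %s.", paste(SEGMENTS, collapse = ", ")),
          class = "icgquant_bad_study")
  }
  if (!all(x$time_label %in% TIME_LABELS)) {
    abort(sprintf("`time_label` must be one of: %s.", paste(TIME_LABELS, collapse = ", ")),
          class = "icgquant_bad_study")
  }
  if (anyNA(x$saturation) || any(x$saturation < 0) || any(x$saturation > 255)) {
    abort("`saturation` must lie in [0, 255] with no missing values.",
          class = "icgquant_bad_study")
  }
  key <- paste(x$subject_id, x$segment, x$time_label)
  if (anyDuplicated(key)) {
    abort("At most one observation per (subject, segment, time).",
          class = "icgquant_bad_study")
  }
  class(x) <- c("study_matrix", class(x))
  x
}

#' Read / write a study matrix CSV
#'
#' Tidy CSV with columns `subject_id,segment,time_label,saturation`.
#'
#' @param path CSV path.
#' @return [as_study_matrix()] tibble (`read_study_csv`); `path` invisibly
#'   (`write_study_csv`).
#' @export
read_study_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Study CSV not found: %s", path), class = "icgquant_io_error")
  }
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort(
                   sprintf("Failed to parse %s: %s", path, conditionMessage(e)),
                   class = "icgquant_io_error"))
  tryCatch(as_study_matrix(df), error = function(e) {
    abort(sprintf("Invalid study matrix in %s: %s", path, conditionMessage(e)),
          class = "icgquant_bad_study")
  })
}

#' @rdname read_study_csv
#' @param study A `study_matrix`.
#' @export
write_study_csv <- function(study, path) {
  study <- as_study_matrix(study)
  write.csv(as.data.frame(study), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Group mean saturation for one segment and observation time
#'
#' The sample mean over the subjects with an available observation at that
#' segment and time; missing cells are skipped.
#'
#' @param study A `study_matrix`.
#' @param segment `"right"` or `"left"`.
#' @param time_label One of the six observation-time labels.
#' @return List with `mean` and `n`.
#' @export
group_mean <- function(study, segment, time_label) {
  study <- as_study_matrix(study)
  v <- study$saturation[study$segment == segment & study$time_label == time_label]
  if (length(v) == 0L) {
    abort(sprintf("No observations for segment '%s' at time '%s'.",
                  segment, time_label),
          class = "icgquant_empty_group")
  }
  list(mean = mean(v), n = length(v))
}

#' Mean ICG saturation before ischemia (MISPreI)
#'
#' Mean over subjects of the pre-phase saturations of one segment.
#'
#' @inheritParams group_mean
#' @return Numeric scalar.
#' @export
mis_pre <- function(study, segment = "left") {
  group_mean(study, segment, "pre")$mean
}

#' Mean ICG saturation after ischemia (MISPostI)
#'
#' The pooled mean over *all* available post-phase observations of the
#' segment — every subject and every observation time contributes one value,
#' so subjects observed at more times carry more weight. This is a flat
#' average of the post-phase cells, not a mean of per-time means.
#'
#' @inheritParams group_mean
#' @return Numeric scalar.
#' @export
mis_post <- function(study, segment = "left") {
  study <- as_study_matrix(study)
  v <- study$saturation[study$segment == segment &
                          study$time_label %in% POST_LABELS]
  if (length(v) == 0L) {
    abort(sprintf("No post-ischemia observations for segment '%s'.", segment),
          class = "icgquant_empty_group")
  }
  mean(v)
}

#' Absolute mean ICG saturation decrease (AMISD)
#'
#' `AMISD = MISPreI - MISPostI`, in intensity points on the 0--255 scale.
#' Negative values indicate an intensity increase.
#'
#' @param mis_pre_value,mis_post_value Mean saturations in \[0, 255\].
#' @return Numeric scalar.
#' @export
amisd <- function(mis_pre_value, mis_post_value) {
  check_saturation_pair(mis_pre_value, mis_post_value)
  mis_pre_value - mis_post_value
}

#' Relative mean ICG saturation decrease (RMISD), percent
#'
#' `RMISD = (1 - MISPostI / MISPreI) * 100`. Being scale-relative, it is
#' comparable across acquisitions with different absolute brightness.
#'
#' @inheritParams amisd
#' @return Numeric scalar (percent).
#' @export
rmisd <- function(mis_pre_value, mis_post_value) {
  check_saturation_pair(mis_pre_value, mis_post_value)
  if (mis_pre_value == 0) {
    abort("RMISD is undefined when the pre-ischemia mean is 0.",
          class = "icgquant_undefined_ratio")
  }
  (1 - mis_post_value / mis_pre_value) * 100
}

check_saturation_pair <- function(pre, post) {
  v <- c(pre, post)
  if (length(v) != 2L || anyNA(v) || any(v < 0) || any(v > 255)) {
    abort("Mean saturations must be single values in [0, 255].",
          class = "icgquant_bad_study")
  }
  invisible(TRUE)
}

#' Classify ischemia from the relative intensity decrease
#'
#' A segment is called ischemic when its RMISD reaches or exceeds the
#' threshold (closed comparison, `>=`). The default 32.6% is the relative
#' decrease observed at complete devascularization in a porcine colon model;
#' it is an experimental estimate, not a clinical constant, and should be
#' recalibrated for other tissues, doses or acquisition settings.
#'
#' @param rmisd_percent Relative decrease, percent.
#' @param threshold_percent Classification cutoff in (0, 100\].
#' @param mis_pre_value,mis_post_value Optional means carried into the record.
#' @return An `ischemia_assessment`: list with `mis_pre`, `mis_post`,
#'   `amisd`, `rmisd_percent`, `threshold_percent`, `is_ischemic`.
#' @export
classify_ischemia <- function(rmisd_percent, threshold_percent = 32.6,
                              mis_pre_value = NA_real_,
                              mis_post_value = NA_real_) {
  if (is.na(threshold_percent) || threshold_percent <= 0 || threshold_percent > 100) {
    abort("`threshold_percent` must lie in (0, 100].", class = "icgquant_bad_spec")
  }
  structure(list(
    mis_pre = mis_pre_value,
    mis_post = mis_post_value,
    amisd = if (anyNA(c(mis_pre_value, mis_post_value))) NA_real_ else
      amisd(mis_pre_value, mis_post_value),
    rmisd_percent = rmisd_percent,
    threshold_percent = threshold_percent,
    is_ischemic = rmisd_percent >= threshold_percent
  ), class = "ischemia_assessment")
}

#' Full ischemia assessment of one segment
#'
#' Convenience wrapper: computes MISPreI, MISPostI, AMISD and RMISD for the
#' segment and classifies against the threshold.
#'
#' @inheritParams group_mean
#' @inheritParams classify_ischemia
#' @return An `ischemia_assessment` (see [classify_ischemia()]), with the
#'   observation counts `n_pre` and `n_post` attached.
#' @export
assess_ischemia <- function(study, segment = "left", threshold_percent = 32.6) {
  study <- as_study_matrix(study)
  pre <- mis_pre(study, segment)
  post <- mis_post(study, segment)
  out <- classify_ischemia(rmisd(pre, post), threshold_percent,
                           mis_pre_value = pre, mis_post_value = post)
  out$n_pre <- group_mean(study, segment, "pre")$n
  out$n_post <- sum(study$segment == segment & study$time_label %in% POST_LABELS)
  out
}

#' @export
print.ischemia_assessment <- function(x, ...) {
  cat("<ischemia_assessment>\n")
  cat(sprintf("  MISPreI  %.4f\n  MISPostI %.4f\n", x$mis_pre, x$mis_post))
  cat(sprintf("  AMISD    %.1f points\n  RMISD    %.1f%%\n", x$amisd, x$rmisd_percent))
  cat(sprintf("  ischemic at >= %.1f%%: %s\n", x$threshold_percent,
              if (isTRUE(x$is_ischemic)) "YES" else "no"))
  invisible(x)
}

#' Serialize an ischemia assessment to JSON
#'
#' Raw precision is kept in the JSON; rounding to the conventional 1-decimal
#' reporting scale is left to presentation code.
#'
#' @param x An `ischemia_assessment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assessment_json <- function(x, path) {
  stopifnot(inherits(x, "ischemia_assessment"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
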