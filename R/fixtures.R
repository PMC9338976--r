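# Built-in porcine colon study fixture.
#
# Mean ICG saturations (0-255 green scale) from a controlled experimental
# study in eight farm pigs: both colon segments measured before ischemia,
# then the left-colon vascular arcade divided and both segments re-measured
# at 15, 45, 75, 105 and 135 minutes. One animal's post-ischemia data and
# two animals' late time points are missing (cardiorespiratory arrest), so
# the post phase has 31 observations per segment. The two phases label
# their animals as printed in the source tables, including the label
# mismatch between phases (pre: 1,2,3,5,6,7,8; post: 1,2,4,5,6,7,8) --
# subject ids must never be joined across phases.

PRE_RIGHT <- c(`1` = 152.57, `2` = 159.43, `3` = 143.42, `5` = 103.08,
               `6` = 121.19, `7` = 130.77, `8` = 128.72)
PRE_LEFT  <- c(`1` = 156.90, `2` = 137.10, `3` = 167.29, `5` = 137.39,
               `6` = 130.66, `7` = 143.49, `8` = 155.99)

# rows: animals 1,2,4,5,6,7,8; columns: 15,45,75,105,135 minutes
POST_RIGHT <- matrix(c(
  163.80, 156.84, 170.54, 155.68, 162.36,
  174.84, 167.98, 165.34,     NA,     NA,
  126.81, 134.46, 136.31, 129.70, 126.07,
   99.80, 126.00, 128.37, 133.71, 122.30,
  123.98, 129.96, 132.34, 129.63, 138.74,
  133.30, 138.58, 141.98, 142.63, 143.20,
  151.93, 146.11, 145.57,     NA,     NA),
  nrow = 7, byrow = TRUE,
  dimnames = list(c("1", "2", "4", "5", "6", "7", "8"), POST_LABELS))

POST_LEFT <- matrix(c(
   74.27, 102.50, 112.06,  78.92,  89.75,
  126.93, 135.27, 136.91,     NA,     NA,
   90.72,  83.40,  82.15,  85.21,  90.04,
   87.42,  97.17,  84.61,  97.46,  90.70,
  107.12, 102.60, 104.77, 103.61, 104.70,
   91.04, 111.16,  93.94,  94.16,  96.59,
   91.04, 112.39, 112.99,     NA,     NA),
  nrow = 7, byrow = TRUE,
  dimnames = list(c("1", "2", "4", "5", "6", "7", "8"), POST_LABELS))

# Transcription checksums: per-group means the fixture must reproduce to
# 4 dp. Any drift in the tables above fails builtin_study() loudly.
FIXTURE_CHECK_MEANS <- c(
  right.pre = 134.1686, right.post15 = 139.2086, right.post45 = 142.8471,
  right.post75 = 145.7786, right.post105 = 138.2700, right.post135 = 138.5340,
  left.pre = 146.9743, left.post15 = 95.5057, left.post45 = 106.3557,
  left.post75 = 103.9186, left.post105 = 91.8720, left.post135 = 94.3560)

#' Built-in study fixture: ICG saturations from a porcine ischemia model
#'
#' Returns the package's built-in measurement matrix as a
#' [as_study_matrix()] tibble: per-pig mean ICG saturations of the right
#' and left colon before ischemia and at five times after division of the
#' inferior mesenteric artery arcade (the left colon is the ischemic
#' segment; the right colon is the undisturbed control). Missing late
#' observations reflect intra-operative animal deaths and are simply
#' absent. Animal labels differ between the pre and post phases as printed
#' in the source data; do not join subjects across phases.
#'
#' On every call (unless `verify = FALSE`) the twelve per-group means are
#' recomputed and checked to 4 decimal places against transcription
#' checksums, so any drift in the embedded tables fails loudly.
#'
#' @param verify Run the transcription self-check (default `TRUE`).
#' @return A `study_matrix` tibble with 76 observations: 14 pre-phase
#'   (7 animals x 2 segments) and 62 post-phase (31 per segment; 4 of the
#'   35 cells per segment are missing).
#' @export
builtin_study <- function(verify = TRUE) {
  pre <- dplyr::bind_rows(
    tibble(subject_id = names(PRE_RIGHT), segment = "right",
           time_label = "pre", saturation = unname(PRE_RIGHT)),
    tibble(subject_id = names(PRE_LEFT), segment = "left",
           time_label = "pre", saturation = unname(PRE_LEFT)))
  long <- function(m, seg) {
    df <- as_tibble(m, rownames = "subject_id")
    df <- tidyr::pivot_longer(df, -"subject_id", names_to = "time_label",
                              values_to = "saturation")
    df$segment <- seg
    df[!is.na(df$saturation), c("subject_id", "segment", "time_label", "saturation")]
  }
  study <- as_study_matrix(dplyr::bind_rows(pre, long(POST_RIGHT, "right"),
                                            long(POST_LEFT, "left")))
  if (verify) {
    for (nm in names(FIXTURE_CHECK_MEANS)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      got <- group_mean(study, parts[1], parts[2])$mean
      if (round(got, 4) != FIXTURE_CHECK_MEANS[[nm]]) {
        abort(sprintf(
          "Built-in fixture failed self-verification: %s mean %.4f != %.4f.",
          nm, got, FIXTURE_CHECK_MEANS[[nm]]),
          class = "icgquant_fixture_drift")
      }
    }
  }
  study
}
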