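#' Generate a synthetic fluorescence-mode RGB image with known ground truth
#'
#' Emulates the features of a fluorescence-mode laparoscopic still that
#' matter to green-channel quantification: a green intensity field
#' (`base_green` plus per-pixel Gaussian noise, clipped to \[0, 255\]) over
#' a dim red/blue background, white specular reflections
#' (`R = G = B = 255`) scattered over a chosen fraction of pixels, and
#' near-saturated vertical vessel streaks (`G = 255`). Reflection and
#' vessel positions are recorded so tests can verify that the
#' green-dominance filter and the ROI auto-sampler exclude them. The image
#' is deterministic for a given seed.
#'
#' @param height,width Image dimensions in pixels.
#' @param base_green Ground-truth green level (0--255).
#' @param noise_sd Per-pixel Gaussian noise SD, intensity units.
#' @param reflection_fraction Fraction of pixels turned pure white, in
#'   \[0, 0.5\]. Exactly `floor(reflection_fraction * height * width)`
#'   pixels are whitened.
#' @param n_vessels Number of 2-pixel-wide vertical saturated streaks.
#' @param background_rb Red/blue base level(s), strictly below
#'   `base_green`; length 1 (shared) or 2 (`c(red, blue)`).
#' @param seed Integer seed.
#' @return List with `image` (an [rgb_image]) and `truth`: `base_green`,
#'   `true_mean` (mean generated green over clean pixels, after clipping),
#'   `reflection_idx` (matrix of 1-based row/col pairs), `vessel_cols`
#'   (1-based column indices covered by streaks), `clean` (logical matrix,
#'   `TRUE` where the pixel is neither reflection nor vessel), and the
#'   generating parameters.
#' @export
generate_synthetic_image <- function(height = 256L, width = 256L,
                                     base_green = 147, noise_sd = 8,
                                     reflection_fraction = 0.10,
                                     n_vessels = 2L, background_rb = 60,
                                     seed = 1L) {
  if (base_green < 0 || base_green > 255) {
    abort("`base_green` must lie in [0, 255].", class = "icgquant_bad_spec")
  }
  if (reflection_fraction < 0 || reflection_fraction > 0.5) {
    abort("`reflection_fraction` must lie in [0, 0.5].", class = "icgquant_bad_spec")
  }
  if (length(background_rb) == 1L) background_rb <- rep(background_rb, 2L)
  if (any(background_rb >= base_green)) {
    abort("`background_rb` must be strictly below `base_green`.",
          class = "icgquant_bad_spec")
  }
  if (noise_sd < 0 || n_vessels < 0 || height < 1 || width < 1) {
    abort("Invalid image spec: negative noise, vessel count or size.",
          class = "icgquant_bad_spec")
  }
  npx <- height * width
  vessel_area <- min(n_vessels * 2L, width) * height
  if (reflection_fraction * npx + vessel_area > 0.9 * npx) {
    abort("Infeasible spec: reflections plus vessels would cover > 90% of the image.",
          class = "icgquant_bad_spec")
  }

  with_seed(seed, {
    G <- matrix(round(clip255(base_green + rnorm(npx, 0, noise_sd))), height, width)
    R <- matrix(round(clip255(background_rb[1] + rnorm(npx, 0, noise_sd))), height, width)
    B <- matrix(round(clip255(background_rb[2] + rnorm(npx, 0, noise_sd))), height, width)

    vessel_cols <- integer(0)
    if (n_vessels > 0L && width >= 2L) {
      starts <- sample.int(width - 1L, min(n_vessels, width - 1L))
      vessel_cols <- sort(unique(c(starts, starts + 1L)))
      G[, vessel_cols] <- 255L
    }

    n_refl <- floor(reflection_fraction * npx)
    reflection_idx <- matrix(integer(0), ncol = 2,
                             dimnames = list(NULL, c("row", "col")))
    if (n_refl > 0L) {
      flat <- sample.int(npx, n_refl)
      reflection_idx <- cbind(row = (flat - 1L) %% height + 1L,
                              col = (flat - 1L) %/% height + 1L)
      R[reflection_idx] <- 255L; G[reflection_idx] <- 255L; B[reflection_idx] <- 255L
    }

    clean <- matrix(TRUE, height, width)
    clean[, vessel_cols] <- FALSE
    clean[reflection_idx] <- FALSE

    list(
      image = rgb_image(R, G, B),
      truth = list(
        base_green = base_green, true_mean = mean(G[clean]),
        reflection_idx = reflection_idx, vessel_cols = vessel_cols,
        clean = clean, noise_sd = noise_sd,
        reflection_fraction = reflection_fraction, n_vessels = n_vessels,
        background_rb = background_rb, seed = seed)
    )
  })
}

#' Write a synthetic image as PNG with a ground-truth JSON sidecar
#'
#' @param gen Result of [generate_synthetic_image()].
#' @param path PNG output path; the sidecar is written next to it with a
#'   `.truth.json` suffix.
#' @return Character vector `c(png, json)`, invisibly.
#' @export
write_synthetic_image <- function(gen, path) {
  stopifnot(is.list(gen), inherits(gen$image, "rgb_image"))
  write_image(gen$image, path)
  json_path <- paste0(sub("\\.png$", "", path), ".truth.json")
  tr <- gen$truth
  jsonlite::write_json(list(
    base_green = tr$base_green, true_mean = tr$true_mean,
    noise_sd = tr$noise_sd, reflection_fraction = tr$reflection_fraction,
    n_vessels = tr$n_vessels, vessel_cols = tr$vessel_cols,
    n_reflections = nrow(tr$reflection_idx),
    background_rb = tr$background_rb, seed = tr$seed
  ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(png = path, json = json_path))
}

#' Simulate a pre/post ischemia study matrix with known ground truth
#'
#' Draws a two-segment study with the structure of the porcine experiment:
#' for each subject and segment a pre-ischemia mean saturation
#' `Normal(mu_pre, sigma_between)` (clipped to \[0, 255\]); the control
#' (right) segment's post-ischemia values scatter around the subject's own
#' pre value with SD `sigma_time`, while the ischemic (left) segment's
#' post values scatter around `pre * (1 - drop_fraction)` — a
#' multiplicative drop, matching the scale-relative RMISD metric. With
#' probability `dropout_prob` a subject loses its two late observation
#' times (105 and 135 minutes), mimicking intra-operative loss.
#'
#' @param n_subjects Number of subjects.
#' @param mu_pre Mean pre-ischemia saturation (0--255 scale).
#' @param sigma_between Between-subject SD of the pre level.
#' @param sigma_time Within-subject, between-time SD.
#' @param drop_fraction Multiplicative post-ischemia intensity reduction of
#'   the ischemic segment, in \[0, 1).
#' @param dropout_prob Per-subject probability of losing the late time
#'   points.
#' @param seed Integer seed.
#' @return List with `study` (a `study_matrix`) and `truth` (the
#'   generating parameters plus per-subject pre levels).
#' @export
simulate_study <- function(n_subjects = 8L, mu_pre = 147,
                           sigma_between = 13, sigma_time = 5,
                           drop_fraction = 0.326, dropout_prob = 0.15,
                           seed = 1L) {
  if (drop_fraction < 0 || drop_fraction >= 1) {
    abort("`drop_fraction` must lie in [0, 1).", class = "icgquant_bad_spec")
  }
  if (sigma_between < 0 || sigma_time < 0 || dropout_prob < 0 || dropout_prob > 1 ||
      n_subjects < 1) {
    abort("SDs must be >= 0, `dropout_prob` in [0, 1], `n_subjects` >= 1.",
          class = "icgquant_bad_spec")
  }
  with_seed(seed, {
    rows <- list()
    pre_levels <- matrix(NA_real_, n_subjects, 2,
                         dimnames = list(NULL, SEGMENTS))
    lost_late <- stats::runif(n_subjects) < dropout_prob
    for (i in seq_len(n_subjects)) {
      sid <- as.character(i)
      times <- if (lost_late[i]) POST_LABELS[1:3] else POST_LABELS
      for (seg in SEGMENTS) {
        pre_i <- clip255(rnorm(1, mu_pre, sigma_between))
        pre_levels[i, seg] <- pre_i
        post_centre <- if (seg == "left") pre_i * (1 - drop_fraction) else pre_i
        rows[[length(rows) + 1L]] <- tibble(
          subject_id = sid, segment = seg,
          time_label = c("pre", times),
          saturation = clip255(c(pre_i,
                                 rnorm(length(times), post_centre, sigma_time))))
      }
    }
    list(
      study = as_study_matrix(dplyr::bind_rows(rows)),
      truth = list(n_subjects = n_subjects, mu_pre = mu_pre,
                   sigma_between = sigma_between, sigma_time = sigma_time,
                   drop_fraction = drop_fraction, dropout_prob = dropout_prob,
                   pre_levels = pre_levels, lost_late = lost_late, seed = seed)
    )
  })
}
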