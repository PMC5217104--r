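#' Convert counts to relative frequencies
#'
#' Divides each strain's count by the total count of its sample
#' (condition x replicate x time point), so frequencies sum to 1 within
#' every sample.
#'
#' @param counts Long count tibble (`strain_id`, `condition`, `replicate`,
#'   `time_point`, `count`) or an `iseq_counts` object.
#' @return Tibble with a `freq` column replacing `count`.
#' @export
relative_frequencies <- function(counts) {
  if (inherits(counts, "iseq_counts")) counts <- counts$counts
  counts <- tibble::as_tibble(counts)
  out <- dplyr::mutate(
    dplyr::group_by(counts, .data$condition, .data$replicate,
                    .data$time_point),
    total = sum(.data$count))
  out <- dplyr::ungroup(out)
  if (any(out$total == 0)) {
    bad <- dplyr::distinct(out[out$total == 0,
                               c("condition", "replicate", "time_point")])
    stop(sprintf("all-zero sample(s): %s",
                 paste(bad$condition, bad$replicate, bad$time_point,
                       sep = "/", collapse = ", ")))
  }
  out$freq <- out$count / out$total
  out[, c("strain_id", "condition", "replicate", "time_point", "freq")]
}

#' Normalize frequency trajectories to the wild-type reference
#'
#' With `W(t)` the summed frequency of the control (double-dubious-ORF)
#' strains, each strain's trajectory is divided by `W(t)` and then by its
#' own value at the first time point, so `z(t0) = 1` and a strain moving
#' with the controls stays at 1 throughout. Time points where a strain's
#' frequency is zero (below sequencing detection) are dropped; strains
#' with zero frequency at t0 carry no usable points and are censored
#' downstream. The sum (not mean) over controls makes the reference
#' invariant to how many control barcodes are distinguished.
#'
#' @param freqs Output of [relative_frequencies()].
#' @param control_ids Character vector of control strain ids.
#' @return Tibble `strain_id`, `condition`, `replicate`, `time_point`,
#'   `z` — only usable (z > 0) points are retained.
#' @export
normalize_to_wt <- function(freqs, control_ids) {
  stopifnot(length(control_ids) > 0)
  if (!any(freqs$strain_id %in% control_ids)) {
    stop("none of control_ids present in the frequency table")
  }
  wt <- dplyr::summarise(
    dplyr::group_by(freqs[freqs$strain_id %in% control_ids, ],
                    .data$condition, .data$replicate, .data$time_point),
    W = sum(.data$freq), .groups = "drop")
  if (any(wt$W == 0)) {
    bad <- wt[wt$W == 0, ]
    stop(sprintf("WT controls extinct in sample(s): %s",
                 paste(bad$condition, bad$replicate, bad$time_point,
                       sep = "/", collapse = ", ")))
  }
  x <- dplyr::left_join(freqs, wt,
                        by = c("condition", "replicate", "time_point"))
  x$ratio <- x$freq / x$W
  x <- dplyr::mutate(
    dplyr::group_by(x, .data$strain_id, .data$condition, .data$replicate),
    t0 = min(.data$time_point),
    ratio0 = .data$ratio[.data$time_point == min(.data$time_point)][1])
  x <- dplyr::ungroup(x)
  x <- x[x$freq > 0 & x$ratio0 > 0, ]
  x$z <- x$ratio / x$ratio0
  x[, c("strain_id", "condition", "replicate", "time_point", "z")]
}

# zero-intercept least squares of y on t via R's lm machinery
fit_zero_intercept <- function(t, y) {
  fit <- stats::lm(y ~ 0 + t)
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
  list(slope = unname(stats::coef(fit)[["t"]]),
       stderr = if (length(t) >= 2) unname(sm[1, 2]) else NA_real_)
}

#' Estimate per-strain relative fitness from normalized trajectories
#'
#' Fits, per strain / replicate / condition, a least-squares regression
#' of `ln z` on the transfer-cycle index with the intercept fixed at 0
#' (the trajectory starts at `z = 1` by construction); fitness is
#' `1 + m`, with `m` the fitted slope per cycle. Only the time points in
#' `timepoints` (default the first four cycles) enter the fit. A strain
#' with fewer than `min_points` usable points — e.g. one driven below the
#' sequencing detection limit, or absent at t0 — is censored: `fitness`
#' is `NA` and `censored` is `TRUE`.
#'
#' @param norm Output of [normalize_to_wt()].
#' @param timepoints Cycle indices used for the regression (default 0:3).
#' @param min_points Minimum usable points, including t0 (default 2).
#' @param per_generation Report the slope per generation instead of per
#'   cycle, dividing by `generations`.
#' @param generations Generations per transfer cycle (default 3, the
#'   log2 of a 1:8 dilution; see [generations_per_cycle()]).
#' @return Tibble `strain_id`, `condition`, `replicate`, `fitness`,
#'   `slope`, `stderr`, `n_points`, `censored`.
#' @export
estimate_fitness <- function(norm, timepoints = 0:3, min_points = 2L,
                             per_generation = FALSE,
                             generations = generations_per_cycle(8)) {
  norm <- norm[norm$time_point %in% timepoints, ]
  t0 <- min(timepoints)
  est <- dplyr::summarise(
    dplyr::group_by(norm, .data$strain_id, .data$condition,
                    .data$replicate),
    n_points = dplyr::n(),
    has_t0 = any(.data$time_point == t0),
    fit = list(if (dplyr::n() >= min_points && any(.data$time_point == t0))
      fit_zero_intercept(.data$time_point - t0, log(.data$z))
      else list(slope = NA_real_, stderr = NA_real_)),
    .groups = "drop")
  est$slope <- vapply(est$fit, `[[`, numeric(1), "slope")
  est$stderr <- vapply(est$fit, `[[`, numeric(1), "stderr")
  est$censored <- est$n_points < min_points | !est$has_t0
  if (per_generation) {
    est$slope <- est$slope / generations
    est$stderr <- est$stderr / generations
  }
  est$fitness <- 1 + est$slope
  est[, c("strain_id", "condition", "replicate", "fitness", "slope",
          "stderr", "n_points", "censored")]
}

#' Generations of regrowth implied by a serial-transfer dilution
#'
#' A culture diluted 1:D must double log2(D) times to return to
#' saturation; 1:8 (12.5 ml into 87.5 ml) gives 3 generations per cycle.
#'
#' @param dilution Dilution factor D (> 1).
#' @return log2(D).
#' @export
generations_per_cycle <- function(dilution) {
  stopifnot(dilution > 1)
  log2(dilution)
}

#' Counts-to-fitness convenience chain
#'
#' [relative_frequencies()] then [normalize_to_wt()] then
#' [estimate_fitness()].
#'
#' @inheritParams relative_frequencies
#' @inheritParams normalize_to_wt
#' @inheritParams estimate_fitness
#' @param ... Passed to [estimate_fitness()].
#' @export
pool_fitness <- function(counts, control_ids, timepoints = 0:3, ...) {
  if (inherits(counts, "iseq_counts")) counts <- counts$counts
  norm <- normalize_to_wt(relative_frequencies(counts), control_ids)
  est <- estimate_fitness(norm, timepoints = timepoints, ...)
  # strains absent at t0 drop out of the normalized table entirely;
  # reinstate them as censored rows so no strain silently disappears
  all_sr <- dplyr::distinct(counts[, c("strain_id", "condition",
                                       "replicate")])
  est <- dplyr::left_join(all_sr, est,
                          by = c("strain_id", "condition", "replicate"))
  missing <- is.na(est$censored)
  est$censored[missing] <- TRUE
  est$n_points[missing] <- 0L
  est
}
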