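#' Doubling time by sliding-window maximum-slope regression
#'
#' Regresses `ln(OD)` on time within every contiguous window of
#' `window` points, takes the window with the maximal slope (the
#' steepest stretch of exponential growth; earliest window on ties) and
#' converts it to a doubling time `ln(2) / slope`. Windowing avoids
#' choosing an arbitrary OD range and is insensitive to differing
#' starting densities. Points at or below zero after blank subtraction
#' are dropped; a window left with fewer than `window` points is
#' skipped.
#'
#' @param times Time stamps in minutes, strictly increasing (plate
#'   readers typically sample every 15 min).
#' @param od Background-subtracted optical density readings (OD595).
#' @param window Points per regression window (default 10).
#' @param blank Constant blank OD subtracted before the log (default 0).
#' @return List of class `iseq_growth_fit`: `doubling_time` (minutes,
#'   `NA` when growth is undetectable), `max_slope` (per minute),
#'   `window_start` (index of the winning window), `no_growth` flag.
#' @export
doubling_time <- function(times, od, window = 10L, blank = 0) {
  stopifnot(length(times) == length(od), length(od) >= window,
            all(diff(times) > 0))
  od <- od - blank
  n <- length(od)
  slopes <- rep(NA_real_, n - window + 1L)
  for (i in seq_len(n - window + 1L)) {
    idx <- i:(i + window - 1L)
    keep <- od[idx] > 0
    if (sum(keep) < window) next
    fit <- stats::lm(log(od[idx][keep]) ~ times[idx][keep])
    slopes[i] <- unname(stats::coef(fit)[2])
  }
  # slopes below 1e-10/min (doubling time ~ 10^10 min) are numerically flat
  if (all(is.na(slopes)) || max(slopes, na.rm = TRUE) <= 1e-10) {
    return(structure(list(doubling_time = NA_real_, max_slope = NA_real_,
                          window_start = NA_integer_, no_growth = TRUE),
                     class = "iseq_growth_fit"))
  }
  best <- which.max(slopes)            # earliest window wins ties
  structure(list(doubling_time = log(2) / slopes[best],
                 max_slope = slopes[best],
                 window_start = as.integer(best), no_growth = FALSE),
            class = "iseq_growth_fit")
}

#' OD-based fitness relative to a wild-type strain
#'
#' Fitness is the WT doubling time divided by the strain doubling time:
#' 1 for WT-like growth, below 1 for slower strains. A no-growth strain
#' gets fitness 0 (flagged); a no-growth WT is an error.
#'
#' @param strain_fit,wt_fit `iseq_growth_fit` objects from
#'   [doubling_time()].
#' @return List `fitness_od`, `no_growth`.
#' @export
od_fitness <- function(strain_fit, wt_fit) {
  if (isTRUE(wt_fit$no_growth)) stop("WT curve shows no growth")
  if (isTRUE(strain_fit$no_growth)) {
    return(list(fitness_od = 0, no_growth = TRUE))
  }
  list(fitness_od = wt_fit$doubling_time / strain_fit$doubling_time,
       no_growth = FALSE)
}

#' Fit growth curves for a plate of strains
#'
#' @param curves Long tibble `strain`, `time`, `od` (time in minutes).
#' @param wt_strain Strain id used as the wild-type reference for
#'   `fitness_od`.
#' @param window,blank Passed to [doubling_time()].
#' @return Tibble `strain`, `doubling_time`, `window_start`, `max_slope`,
#'   `fitness_od`, `no_growth`.
#' @export
growth_fits <- function(curves, wt_strain, window = 10L, blank = 0) {
  strains <- unique(curves$strain)
  stopifnot(wt_strain %in% strains)
  fits <- lapply(strains, function(s) {
    cc <- curves[curves$strain == s, ]
    cc <- cc[order(cc$time), ]
    doubling_time(cc$time, cc$od, window = window, blank = blank)
  })
  names(fits) <- strains
  wt <- fits[[wt_strain]]
  tibble::tibble(
    strain = strains,
    doubling_time = vapply(fits, `[[`, numeric(1), "doubling_time",
                           USE.NAMES = FALSE),
    window_start = vapply(fits, `[[`, integer(1), "window_start",
                          USE.NAMES = FALSE),
    max_slope = vapply(fits, `[[`, numeric(1), "max_slope",
                       USE.NAMES = FALSE),
    fitness_od = vapply(fits, function(f) od_fitness(f, wt)$fitness_od,
                        numeric(1), USE.NAMES = FALSE),
    no_growth = vapply(fits, `[[`, logical(1), "no_growth",
                       USE.NAMES = FALSE))
}
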