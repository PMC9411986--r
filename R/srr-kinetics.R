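#' Average duplicate rate measurements and extract a clean series
#' @noRd
srr_series <- function(data) {
  cols <- names(data)
  rate_col <- if ("rate_nmol_cm3_d" %in% cols) "rate_nmol_cm3_d" else "rate"
  if (!all(c("time_h", rate_col) %in% cols)) {
    stop("SRR data needs columns `time_h` and `rate_nmol_cm3_d` (or `rate`)",
         call. = FALSE)
  }
  df <- data[, c("time_h", rate_col)]
  names(df) <- c("time_h", "rate")
  if ("replicate" %in% cols) {
    df <- stats::aggregate(rate ~ time_h, data = df, FUN = mean)
  }
  df <- df[order(df$time_h), ]
  if (any(df$rate < 0)) stop("SRR series contains negative rates",
                             call. = FALSE)
  if (any(duplicated(df$time_h))) {
    df <- stats::aggregate(rate ~ time_h, data = df, FUN = mean)
  }
  df
}

#' Detect exponential sulfate-reduction phases
#'
#' Scans a rate time series for up to `max_phases` disjoint maximal windows in
#' which ln(rate) against time is strictly increasing and log-linear with
#' R^2 >= `r2_min`. All contiguous windows of at least `min_points` strictly
#' positive, strictly log-increasing rates are scored by ordinary least
#' squares; windows contained in a longer qualifying window are dropped, and
#' the survivors are admitted greedily (longest first, then highest R^2, then
#' earliest start) subject to disjointness. Zero rates never join a window.
#'
#' @param data Data frame with columns `time_h` and `rate_nmol_cm3_d` (or
#'   `rate`); an optional `replicate` column is averaged per timepoint first.
#' @param min_points Minimum number of points per window (default 4).
#' @param r2_min Minimum R^2 of the log-linear fit (default 0.95).
#' @param max_phases Maximum number of windows returned (default 2).
#' @return Tibble with one row per detected phase: `phase`, `t_start`,
#'   `t_end`, `n_points`, `slope`, `r_squared`, ordered by start time. Zero
#'   rows when nothing qualifies; fewer than `min_points` positive rates
#'   yields zero rows with a warning.
#' @export
#' @examples
#' d <- data.frame(time_h = 0:10, rate_nmol_cm3_d = 2^(0:10))
#' detect_exponential_phases(d)
detect_exponential_phases <- function(data, min_points = 4L, r2_min = 0.95,
                                      max_phases = 2L) {
  df <- srr_series(data)
  empty <- tibble::tibble(phase = integer(), t_start = numeric(),
                          t_end = numeric(), n_points = integer(),
                          slope = numeric(), r_squared = numeric())
  if (all(df$rate == 0)) return(empty)
  if (sum(df$rate > 0) < min_points) {
    warning("fewer than `min_points` positive rates; no phases detected",
            call. = FALSE)
    return(empty)
  }

  pos <- df$rate > 0
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- list()
  for (r in which(runs$values & runs$lengths >= min_points)) {
    idx <- starts[r]:ends[r]
    t <- df$time_h[idx]
    y <- log(df$rate[idx])
    n <- length(idx)
    for (i in seq_len(n - min_points + 1L)) {
      for (j in (i + min_points - 1L):n) {
        if (any(diff(y[i:j]) <= 0)) next
        tt <- t[i:j]; yy <- y[i:j]
        sxx <- sum((tt - mean(tt))^2)
        sxy <- sum((tt - mean(tt)) * (yy - mean(yy)))
        syy <- sum((yy - mean(yy))^2)
        slope <- sxy / sxx
        r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 0
        if (slope > 0 && r2 >= r2_min) {
          cand[[length(cand) + 1L]] <- list(
            start = idx[i], end = idx[j], t_start = tt[1],
            t_end = tt[length(tt)], n = j - i + 1L,
            slope = slope, r2 = r2)
        }
      }
    }
  }
  if (!length(cand)) return(empty)

  # keep maximal windows only
  keep <- vapply(seq_along(cand), function(a) {
    !any(vapply(seq_along(cand), function(b) {
      b != a && cand[[b]]$start <= cand[[a]]$start &&
        cand[[b]]$end >= cand[[a]]$end
    }, logical(1)))
  }, logical(1))
  cand <- cand[keep]

  ord <- order(-vapply(cand, `[[`, integer(1), "n"),
               -vapply(cand, `[[`, numeric(1), "r2"),
               vapply(cand, `[[`, numeric(1), "t_start"))
  chosen <- list()
  for (a in ord) {
    w <- cand[[a]]
    overlaps <- any(vapply(chosen, function(c) {
      w$start <= c$end && c$start <= w$end
    }, logical(1)))
    if (!overlaps) chosen[[length(chosen) + 1L]] <- w
    if (length(chosen) >= max_phases) break
  }
  chosen <- chosen[order(vapply(chosen, `[[`, numeric(1), "t_start"))]
  tibble::tibble(
    phase = seq_along(chosen),
    t_start = vapply(chosen, `[[`, numeric(1), "t_start"),
    t_end = vapply(chosen, `[[`, numeric(1), "t_end"),
    n_points = vapply(chosen, `[[`, integer(1), "n"),
    slope = vapply(chosen, `[[`, numeric(1), "slope"),
    r_squared = vapply(chosen, `[[`, numeric(1), "r2")
  )
}

#' Fit one exponential SRR phase by log-linear least squares
#'
#' Ordinary least squares of ln(rate) on time within `[t_start, t_end]`.
#' The specific growth rate mu is the slope (h^-1), the doubling time is
#' ln(2)/mu, and the intercept is the ln-rate extrapolated to t = 0. A
#' non-positive slope yields `doubling_time = Inf` and `no_growth = TRUE`
#' rather than an error.
#'
#' @param data SRR data as in [detect_exponential_phases()].
#' @param t_start,t_end Window bounds in hours (inclusive). A one-row window
#'   tibble/list with `t_start`/`t_end` elements can be given as `t_start`.
#' @return Object of class `growth_phase_fit` with fields `window`, `mu`,
#'   `doubling_time`, `intercept`, `r_squared`, `n_points`, `no_growth`.
#' @export
#' @examples
#' d <- data.frame(time_h = 9:23, rate_nmol_cm3_d = exp(log(2) / 1.5 * (9:23)))
#' fit <- fit_exponential_phase(d, 9, 23)
#' fit$doubling_time
fit_exponential_phase <- function(data, t_start, t_end = NULL) {
  if (is.null(t_end)) {
    if (is.list(t_start) && all(c("t_start", "t_end") %in% names(t_start))) {
      t_end <- t_start$t_end[1]
      t_start <- t_start$t_start[1]
    } else stop("provide `t_start` and `t_end`", call. = FALSE)
  }
  df <- srr_series(data)
  df <- df[df$time_h >= t_start & df$time_h <= t_end, ]
  if (nrow(df) < 3L) {
    stop("window must contain at least 3 points", call. = FALSE)
  }
  bad <- df$time_h[df$rate <= 0]
  if (length(bad)) {
    stop(sprintf("non-positive rate at t = %s h inside the fit window",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fit <- stats::lm(log(rate) ~ time_h, data = df)
  mu <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  y <- log(df$rate)
  syy <- sum((y - mean(y))^2)
  r2 <- if (syy > 0) 1 - sum(stats::residuals(fit)^2) / syy else 1
  structure(
    list(window = c(t_start = t_start, t_end = t_end),
         mu = mu,
         doubling_time = if (mu > 0) log(2) / mu else Inf,
         intercept = intercept,
         r_squared = r2,
         n_points = nrow(df),
         no_growth = mu <= 0,
         model = fit),
    class = "growth_phase_fit"
  )
}

#' @export
print.growth_phase_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_phase_fit> window %g-%g h: mu = %.4g /h, t_d = %.4g h, R2 = %.3f%s\n",
    x$window["t_start"], x$window["t_end"], x$mu, x$doubling_time,
    x$r_squared, if (x$no_growth) " [no growth]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.growth_phase_fit <- function(x, ...) {
  se <- tryCatch(
    suppressWarnings(summary(x$model)$coefficients["time_h", "Std. Error"]),
    error = function(e) NA_real_)
  tibble::tibble(
    term = c("mu", "doubling_time", "intercept"),
    estimate = c(x$mu, x$doubling_time, x$intercept),
    std.error = c(se, NA_real_, NA_real_)
  )
}

#' @export
glance.growth_phase_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n_points = x$n_points,
                 t_start = unname(x$window["t_start"]),
                 t_end = unname(x$window["t_end"]),
                 no_growth = x$no_growth)
}

#' Cell-specific sulfate reduction rate from biovolume
#'
#' csSRR = biovolume x biomass density x rate per biomass, the conversion
#' constant between a volumetric SRR and the cell density sustaining it.
#'
#' @param biovolume_um3 Cell biovolume, um^3 cell^-1.
#' @param biomass_density_pg_um3 Biomass density, pg um^-3 (default 1.0).
#' @param rate_per_biomass Sulfate reduction per biomass,
#'   fmol SO4 pg^-1 d^-1.
#' @return Object of class `cs_srr_model` with the derived `cs_srr`
#'   (fmol cell^-1 d^-1).
#' @export
#' @examples
#' cs_srr_from_biovolume(1, 1, 10)$cs_srr
cs_srr_from_biovolume <- function(biovolume_um3,
                                  biomass_density_pg_um3 = 1,
                                  rate_per_biomass = 10) {
  assert_number(biovolume_um3, "biovolume_um3", 0, strict_lower = TRUE)
  assert_number(biomass_density_pg_um3, "biomass_density_pg_um3", 0,
                strict_lower = TRUE)
  assert_number(rate_per_biomass, "rate_per_biomass", 0, strict_lower = TRUE)
  structure(
    list(biovolume_um3 = biovolume_um3,
         biomass_density_pg_um3 = biomass_density_pg_um3,
         rate_per_biomass = rate_per_biomass,
         cs_srr = biovolume_um3 * biomass_density_pg_um3 * rate_per_biomass),
    class = "cs_srr_model"
  )
}

#' Default cell-specific-rate model
#'
#' A 1.0 um^3 cell at 1.0 pg um^-3 reducing 10 fmol SO4 per pg biomass per
#' day: csSRR = 10 fmol cell^-1 d^-1, matching the default scenario's
#' populations.
#' @return A [cs_srr_from_biovolume()] model.
#' @export
default_cs_srr_model <- function() cs_srr_from_biovolume(1, 1, 10)

#' @export
print.cs_srr_model <- function(x, ...) {
  cat(sprintf(
    "<cs_srr_model> %g um3 x %g pg/um3 x %g fmol/pg/d = %g fmol SO4/cell/d\n",
    x$biovolume_um3, x$biomass_density_pg_um3, x$rate_per_biomass, x$cs_srr))
  invisible(x)
}

#' Back-extrapolate a fitted SRR phase to a time-zero cell census
#'
#' Under a cell-specific-rate model, the cell density sustaining a volumetric
#' rate is N(t) = SRR(t) / csSRR. Extrapolating the fitted exponential to
#' `extrapolation_time` (default 0 h, i.e. germination assumed at the start
#' of the incubation) gives the in situ density of the dormant population:
#' N0 = exp(intercept + mu * t) / (csSRR * 1e-6), with csSRR in
#' fmol cell^-1 d^-1 and SRR in nmol cm^-3 d^-1.
#'
#' @param fit A [fit_exponential_phase()] result with finite doubling time.
#' @param model A [cs_srr_from_biovolume()] model.
#' @param extrapolation_time Time (h) at which the census is evaluated.
#' @return Object of class `spore_population_estimate` with field `n0`
#'   (cells cm^-3) and the inputs embedded for provenance.
#' @export
estimate_population <- function(fit, model = default_cs_srr_model(),
                                extrapolation_time = 0) {
  stopifnot(inherits(fit, "growth_phase_fit"),
            inherits(model, "cs_srr_model"))
  if (!is.finite(fit$doubling_time)) {
    stop("no growth to extrapolate: infinite doubling time", call. = FALSE)
  }
  n0 <- exp(fit$intercept + fit$mu * extrapolation_time) /
    (model$cs_srr * FMOL_TO_NMOL)
  structure(
    list(phase = fit, model = model, n0 = n0,
         extrapolation_time = extrapolation_time),
    class = "spore_population_estimate"
  )
}

#' @export
print.spore_population_estimate <- function(x, ...) {
  cat(sprintf(
    "<spore_population_estimate> N0 = %.3g cells/cm3 at t = %g h (t_d = %.3g h)\n",
    x$n0, x$extrapolation_time, x$phase$doubling_time))
  invisible(x)
}

#' @export
tidy.spore_population_estimate <- function(x, ...) {
  tibble::tibble(
    n0 = x$n0,
    doubling_time = x$phase$doubling_time,
    mu = x$phase$mu,
    cs_srr = x$model$cs_srr,
    t_start = unname(x$phase$window["t_start"]),
    t_end = unname(x$phase$window["t_end"]),
    extrapolation_time = x$extrapolation_time
  )
}

#' Detect, fit and back-extrapolate all SRR phases in one call
#'
#' @param data SRR data as in [detect_exponential_phases()].
#' @param model Cell-specific-rate model for the censuses.
#' @param ... Passed to [detect_exponential_phases()].
#' @return Tibble with one row per phase: window, mu, doubling time, R^2 and
#'   the time-zero census `n0`.
#' @export
#' @examples
#' cfg <- default_scenario(noise_cv = 0, seed = 1)
#' exp <- simulate_germination_growth(cfg)
#' analyze_srr(subset(exp$srr, time_h <= 126))
analyze_srr <- function(data, model = default_cs_srr_model(), ...) {
  windows <- detect_exponential_phases(data, ...)
  if (!nrow(windows)) return(tibble::tibble())
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    fit <- fit_exponential_phase(data, windows$t_start[i], windows$t_end[i])
    est <- estimate_population(fit, model)
    dplyr::bind_cols(phase = windows$phase[i], tidy(est),
                     r_squared = fit$r_squared, n_points = fit$n_points)
  })
}
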