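#' Segment a concentration time series into depletion/accumulation phases
#'
#' Between-timepoint slopes are classified against `+/- min_slope`
#' (mM h^-1): below `-min_slope` is depletion, above `+min_slope`
#' accumulation, otherwise stable. Adjacent intervals with the same direction
#' are merged, so the returned windows tile the time axis with no gaps or
#' overlaps; boundaries snap to grid points (no interpolation).
#'
#' @param conc Concentration table: tibble with columns `time_h`, `analyte`,
#'   `mean_mM` (e.g. `simulate_germination_growth()$concentrations`).
#' @param analyte Analyte name to segment.
#' @param min_slope Slope dead-band in mM h^-1 (default 0.01, below
#'   chromatographic relevance).
#' @return Tibble: `phase`, `t_start`, `t_end`, `direction` in
#'   `c("depletion", "accumulation", "stable")`.
#' @export
#' @examples
#' conc <- data.frame(time_h = c(0, 10, 20, 30),
#'                    analyte = "lactate",
#'                    mean_mM = c(4, 3, 1, 0.2))
#' segment_phases(conc, "lactate")
segment_phases <- function(conc, analyte, min_slope = 0.01) {
  stopifnot(all(c("time_h", "analyte", "mean_mM") %in% names(conc)))
  df <- conc[conc$analyte == analyte, ]
  if (!nrow(df)) {
    stop(sprintf("analyte '%s' not found", analyte), call. = FALSE)
  }
  df <- df[order(df$time_h), ]
  if (nrow(df) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  slope <- diff(df$mean_mM) / diff(df$time_h)
  dir <- ifelse(slope < -min_slope, "depletion",
                ifelse(slope > min_slope, "accumulation", "stable"))
  runs <- rle(dir)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  tibble::tibble(
    phase = seq_along(runs$values),
    t_start = df$time_h[starts],
    t_end = df$time_h[ends + 1L],
    direction = runs$values
  )
}

#' Net concentration change between two grid timepoints
#'
#' Delta = mean(t_end) - mean(t_start), with the SD propagated as
#' sqrt(SD_start^2 + SD_end^2) under independence. Both times must lie on
#' the sampling grid; there is no interpolation.
#'
#' @param conc Concentration table with `time_h`, `analyte`, `mean_mM`,
#'   `sd_mM`.
#' @param analyte Analyte name.
#' @param t_start,t_end Grid timepoints in hours.
#' @return Tibble: `analyte`, `t_start`, `t_end`, `delta_mM`, `sd_mM`.
#' @export
#' @examples
#' conc <- data.frame(time_h = c(0, 216), analyte = "sulfate",
#'                    mean_mM = c(15.6, 2.5), sd_mM = c(0.3, 0.1))
#' net_change(conc, "sulfate", 0, 216)
net_change <- function(conc, analyte, t_start, t_end) {
  stopifnot(all(c("time_h", "analyte", "mean_mM", "sd_mM") %in% names(conc)))
  df <- conc[conc$analyte == analyte, ]
  if (!nrow(df)) stop(sprintf("analyte '%s' not found", analyte),
                      call. = FALSE)
  pick <- function(t) {
    row <- df[df$time_h == t, ]
    if (!nrow(row)) {
      stop(sprintf("time %g h is not on the sampling grid", t),
           call. = FALSE)
    }
    row[1, ]
  }
  a <- pick(t_start)
  b <- pick(t_end)
  tibble::tibble(
    analyte = analyte, t_start = t_start, t_end = t_end,
    delta_mM = b$mean_mM - a$mean_mM,
    sd_mM = sqrt(a$sd_mM^2 + b$sd_mM^2)
  )
}

#' Build a reaction table for stoichiometric auditing
#'
#' Each reaction lists substrate and product coefficients plus the moles of
#' sulfate consumed per reaction extent (0 for fermentative reactions).
#'
#' @param ... Named lists with elements `substrates` (named numeric),
#'   `products` (named numeric, may be empty) and `sulfate` (single number
#'   >= 0).
#' @return Object of class `reaction_table` (a named list of reactions).
#' @export
reaction_table <- function(...) {
  reactions <- list(...)
  if (!length(reactions)) stop("no reactions given", call. = FALSE)
  if (is.null(names(reactions)) || any(!nzchar(names(reactions)))) {
    stop("every reaction must be named", call. = FALSE)
  }
  for (nm in names(reactions)) {
    r <- reactions[[nm]]
    if (is.null(r$substrates) || !length(r$substrates)) {
      stop(sprintf("reaction '%s' has no substrates", nm), call. = FALSE)
    }
    if (any(unlist(r[c("substrates", "products")]) <= 0)) {
      stop("stoichiometric coefficients must be > 0", call. = FALSE)
    }
    reactions[[nm]]$sulfate <- r$sulfate %||% 0
  }
  structure(reactions, class = "reaction_table")
}

#' Default cross-feeding reaction set
#'
#' Incomplete oxidation of VFAs by sulfate reducers plus fermentative
#' succinate decarboxylation:
#' 2 lactate + SO4 -> 2 acetate; 4 formate + SO4 (complete, no acetate);
#' 2 butyrate + SO4 -> 4 acetate; 4 propionate + 3 SO4 -> 4 acetate;
#' succinate -> propionate 1:1 (not sulfate-linked).
#' @return A [reaction_table()].
#' @export
default_reaction_table <- function() {
  reaction_table(
    lactate_oxidation = list(substrates = c(lactate = 2),
                             products = c(acetate = 2), sulfate = 1),
    formate_oxidation = list(substrates = c(formate = 4),
                             products = c(), sulfate = 1),
    butyrate_oxidation = list(substrates = c(butyrate = 2),
                              products = c(acetate = 4), sulfate = 1),
    propionate_oxidation = list(substrates = c(propionate = 4),
                                products = c(acetate = 4), sulfate = 3),
    succinate_decarboxylation = list(substrates = c(succinate = 1),
                                     products = c(propionate = 1),
                                     sulfate = 0)
  )
}

#' Audit observed concentration changes against a reaction set
#'
#' Solves for non-negative reaction extents xi minimizing
#' ||delta_observed - S xi|| by non-negative least squares, where S is the
#' stoichiometric matrix (substrates and sulfate negative, products
#' positive). Reactions run forward only. Analytes missing from `deltas` are
#' taken as zero change.
#'
#' @param deltas Named numeric vector of observed concentration changes
#'   (mM), or a tibble with columns `analyte` and `delta_mM`.
#' @param reactions A [reaction_table()].
#' @return Object of class `stoichiometric_balance`: `extents` (tibble),
#'   `residuals` (tibble per analyte), `residual_norm`,
#'   `sulfate_demand_mM` (predicted sulfate consumption, positive), and
#'   `acetate_yield_mM`.
#' @export
#' @examples
#' bal <- stoichiometric_balance(c(succinate = -4, propionate = 4),
#'                               default_reaction_table())
#' bal$extents
stoichiometric_balance <- function(deltas, reactions) {
  stopifnot(inherits(reactions, "reaction_table"))
  if (is.data.frame(deltas)) {
    deltas <- stats::setNames(deltas$delta_mM, deltas$analyte)
  }
  rxn_analytes <- unique(unlist(lapply(reactions, function(r) {
    c(names(r$substrates), names(r$products),
      if (r$sulfate > 0) "sulfate")
  })))
  if (!length(intersect(names(deltas), rxn_analytes))) {
    stop("reactions share no analytes with the observed deltas",
         call. = FALSE)
  }
  analytes <- sort(unique(c(names(deltas), rxn_analytes)))
  S <- matrix(0, length(analytes), length(reactions),
              dimnames = list(analytes, names(reactions)))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    S[names(r$substrates), j] <- S[names(r$substrates), j] - r$substrates
    if (length(r$products)) {
      S[names(r$products), j] <- S[names(r$products), j] + r$products
    }
    if (r$sulfate > 0) S["sulfate", j] <- S["sulfate", j] - r$sulfate
  }
  d <- stats::setNames(rep(0, length(analytes)), analytes)
  d[names(deltas)] <- deltas

  xi <- pracma::lsqnonneg(S, d)$x
  names(xi) <- names(reactions)
  fitted <- as.vector(S %*% xi)
  res <- d - fitted
  sulfate_demand <- sum(vapply(reactions, `[[`, numeric(1), "sulfate") * xi)
  acetate_yield <- sum(vapply(reactions, function(r) {
    v <- unname(r$products["acetate"])
    if (length(v) != 1L || is.na(v)) 0 else v
  }, numeric(1)) * xi)

  structure(
    list(extents = tibble::tibble(reaction = names(xi), extent_mM = xi),
         residuals = tibble::tibble(analyte = analytes,
                                    observed_mM = unname(d),
                                    fitted_mM = fitted,
                                    residual_mM = unname(res)),
         residual_norm = sqrt(sum(res^2)),
         sulfate_demand_mM = sulfate_demand,
         acetate_yield_mM = acetate_yield),
    class = "stoichiometric_balance"
  )
}

#' @export
print.stoichiometric_balance <- function(x, ...) {
  cat("<stoichiometric_balance>\n")
  cat(sprintf("  residual norm %.3g mM; sulfate demand %.3g mM; acetate yield %.3g mM\n",
              x$residual_norm, x$sulfate_demand_mM, x$acetate_yield_mM))
  print(x$extents)
  invisible(x)
}
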