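#' Analysis configuration
#'
#' Collects the tunable choices of the trend-extrapolation procedure. The
#' defaults reproduce the method's published settings.
#'
#' @param weighting Sample weighting for the trend regression: `"linear"`
#'   (default) weights group `i` by `1 + d_i / d_max`, so recent groups count
#'   up to twice the root — a monotone recency weighting by evolutionary
#'   distance from the root; `"uniform"` disables weighting.
#' @param normalize Logical; rescale the distance axis by the trajectory's
#'   transition count before fitting (default `TRUE`), making slope
#'   magnitudes comparable across sites of different volatility. The
#'   extrapolation point is rescaled identically.
#' @param break_mode Which transition the break-trend flag inspects:
#'   `"last"` (default) the most recent group transition, `"penultimate"`
#'   the one before it.
#' @param min_transitions Minimum group transitions for a site to be
#'   eligible for prediction (default 3, inclusive).
#' @param drop_self Drop predictions whose successor equals the target's
#'   current residue (default `TRUE`; reported mutations are substitutions).
#' @return An object of class `ssp_config`.
#' @export
ssp_config <- function(weighting = c("linear", "uniform"),
                       normalize = TRUE,
                       break_mode = c("last", "penultimate"),
                       min_transitions = 3L,
                       drop_self = TRUE) {
  weighting <- match.arg(weighting)
  break_mode <- match.arg(break_mode)
  stopifnot(is.logical(normalize), length(normalize) == 1L,
            is.numeric(min_transitions), min_transitions >= 1L,
            is.logical(drop_self))
  structure(list(weighting = weighting, normalize = normalize,
                 break_mode = break_mode,
                 min_transitions = as.integer(min_transitions),
                 drop_self = drop_self),
            class = "ssp_config")
}

#' Build the residue trajectory of one alignment column
#'
#' Reads the column root-first along the main path, drops gap characters
#' (their nodes contribute no descriptor value; remaining nodes keep their
#' cumulative distances), and collapses maximal runs of identical residues
#' into groups. Transitions are boundaries between consecutive groups;
#' residues that persist across successive ancestors are one group and are
#' not penalised in scoring.
#'
#' @param path A `main_path`.
#' @param site Alignment column, 0-based.
#' @return Object of class `trajectory`: list with `site`, `residues`,
#'   `positions` (cumulative distances, parallel), `groups` (data.frame
#'   `residue`, `first`, `last` — indices into `residues`), and
#'   `n_transitions`.
#' @export
build_trajectory <- function(path, site) {
  stopifnot(inherits(path, "main_path"), is.numeric(site), length(site) == 1L)
  width <- nchar(path$sequences[1L])
  if (site < 0L || site >= width) stop("site out of range [0, ", width - 1L, "]")
  col <- substr(path$sequences, site + 1L, site + 1L)
  keep <- col != "-"
  residues <- col[keep]
  positions <- path$cumulative[keep]
  if (length(residues) > 0L) {
    r <- rle(residues)
    last <- cumsum(r$lengths)
    first <- last - r$lengths + 1L
    groups <- data.frame(residue = r$values, first = first, last = last,
                         stringsAsFactors = FALSE)
  } else {
    groups <- data.frame(residue = character(0), first = integer(0), last = integer(0))
  }
  structure(list(site = as.integer(site), residues = residues,
                 positions = positions, groups = groups,
                 n_transitions = max(nrow(groups) - 1L, 0L)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory at column %d: %s (%d groups, %d transitions)\n",
              x$site, paste(x$groups$residue, collapse = ">"),
              nrow(x$groups), x$n_transitions))
  invisible(x)
}

#' Is a site eligible for prediction?
#'
#' Sites with fewer than `min_transitions` group transitions carry too
#' little directional signal and are excluded; the boundary is inclusive
#' (exactly `min_transitions` transitions is eligible). A site where the
#' target itself has a gap cannot be mutated and is ineligible.
#'
#' @param traj A `trajectory`.
#' @param path The `main_path` the trajectory came from.
#' @param config An `ssp_config`.
#' @return Logical scalar.
#' @export
is_eligible <- function(traj, path, config = ssp_config()) {
  stopifnot(inherits(traj, "trajectory"), inherits(path, "main_path"))
  target_res <- substr(path$sequences[length(path$sequences)],
                       traj$site + 1L, traj$site + 1L)
  traj$n_transitions >= config$min_transitions && target_res != "-"
}

#' Project a trajectory through one descriptor scale
#'
#' Produces the regression input: one point per residue group, with x the
#' cumulative evolutionary distance at the group's first node, y the scale
#' value of the group's residue, and w the sample weight from the
#' configured weighting rule. Groups whose residue has no value on the
#' scale (e.g. `X`) are skipped with a warning.
#'
#' @param traj A `trajectory`.
#' @param scale An `aaindex_scale`.
#' @param path The `main_path` (supplies `d_max` for recency weighting).
#' @param config An `ssp_config`.
#' @return Object of class `feature_series`: list with `accession`, `x`,
#'   `y`, `w` (equal lengths) and `n_transitions` (from the trajectory).
#' @export
featurize <- function(traj, scale, path, config = ssp_config()) {
  stopifnot(inherits(traj, "trajectory"), inherits(scale, "aaindex_scale"),
            inherits(path, "main_path"))
  g <- traj$groups
  known <- g$residue %in% AA_ALPHABET
  if (any(!known)) {
    warning("skipping group(s) with residue(s) outside the scale: ",
            paste(unique(g$residue[!known]), collapse = ", "))
    g <- g[known, , drop = FALSE]
  }
  x <- traj$positions[g$first]
  y <- unname(scale$values[g$residue])
  d_max <- path$cumulative[length(path$cumulative)]
  w <- switch(config$weighting,
              uniform = rep(1, length(x)),
              linear = if (d_max > 0) 1 + x / d_max else rep(1, length(x)))
  structure(list(accession = scale$accession, x = x, y = y, w = w,
                 n_transitions = traj$n_transitions),
            class = "feature_series")
}

#' Fit the distance-weighted linear trend and extrapolate the successor
#'
#' Weighted least-squares regression of descriptor value on (optionally
#' transition-normalised) cumulative distance, extrapolated one mean
#' evolutionary step beyond the last group and inverted back to an amino
#' acid via [nearest_residue()].
#'
#' @param series A `feature_series`.
#' @param step Extrapolation step in substitutions/site, from
#'   [mean_step()].
#' @param scale The `aaindex_scale` the series was featurised with.
#' @param config An `ssp_config`.
#' @return Object of class `trend_model`: list with `accession`, `slope`,
#'   `intercept`, `step` and `x_last` (on the fitted axis),
#'   `predicted_value`, `predicted_residue`.
#' @export
fit_trend <- function(series, step, scale, config = ssp_config()) {
  stopifnot(inherits(series, "feature_series"), inherits(scale, "aaindex_scale"),
            is.numeric(step), length(step) == 1L, step >= 0)
  x <- series$x
  if (length(x) < 2L) stop("need at least two groups to fit a trend")
  if (length(unique(x)) == 1L) stop("degenerate fit: all group distances identical")
  if (config$normalize && series$n_transitions > 0L) {
    x <- x / series$n_transitions
    step <- step / series$n_transitions
  }
  fit <- stats::lm.wfit(cbind(1, x), series$y, series$w)
  intercept <- unname(fit$coefficients[1L])
  slope <- unname(fit$coefficients[2L])
  x_next <- x[length(x)] + step
  predicted_value <- slope * x_next + intercept
  structure(list(accession = series$accession, slope = slope,
                 intercept = intercept, step = step, x_last = x[length(x)],
                 predicted_value = predicted_value,
                 predicted_residue = nearest_residue(predicted_value, scale)),
            class = "trend_model")
}

#' Predict successor residues at one site across all descriptor scales
#'
#' Runs featurisation, trend fitting and scoring for every scale in the
#' table at an eligible site. Degenerate fits are skipped. Self-predictions
#' (successor equals the target's current residue) are dropped when
#' `config$drop_self` is set, since reported output is substitutions.
#'
#' @param path A `main_path`.
#' @param site Alignment column, 0-based.
#' @param table An `aaindex_table`.
#' @param config An `ssp_config`.
#' @return A data.frame with one row per retained scale: `site` (0-based
#'   column), `position` (1-based ungapped target numbering), `wild_type`,
#'   `predicted`, `accession`, `category`, `slope`, `predicted_value`,
#'   `sequentiality`, `fluctuation`, `break_trend`. Zero rows for an
#'   ineligible site.
#' @export
predict_site <- function(path, site, table = load_default_indices(),
                         config = ssp_config()) {
  stopifnot(inherits(path, "main_path"), inherits(table, "aaindex_table"))
  traj <- build_trajectory(path, site)
  empty <- data.frame(site = integer(0), position = integer(0),
                      wild_type = character(0), predicted = character(0),
                      accession = character(0), category = character(0),
                      slope = numeric(0), predicted_value = numeric(0),
                      sequentiality = numeric(0), fluctuation = numeric(0),
                      break_trend = logical(0), stringsAsFactors = FALSE)
  if (!is_eligible(traj, path, config)) return(empty)
  wild_type <- substr(path$sequences[length(path$sequences)],
                      site + 1L, site + 1L)
  pos <- target_positions(path)[site + 1L]
  step <- mean_step(path)
  rows <- lapply(table, function(scale) {
    series <- featurize(traj, scale, path, config)
    model <- tryCatch(fit_trend(series, step, scale, config),
                      error = function(e) NULL)
    if (is.null(model)) return(NULL)
    data.frame(site = traj$site, position = pos, wild_type = wild_type,
               predicted = model$predicted_residue,
               accession = scale$accession, category = scale$category,
               slope = model$slope, predicted_value = model$predicted_value,
               sequentiality = sequentiality(traj, scale, model$slope),
               fluctuation = fluctuation(traj),
               break_trend = break_trend(traj, scale, model$slope,
                                         mode = config$break_mode),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty), rows))
  rownames(out) <- NULL
  if (config$drop_self) out <- out[out$predicted != out$wild_type, , drop = FALSE]
  rownames(out) <- NULL
  out
}
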