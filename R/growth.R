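#' Construct a growth curve
#'
#' OD-vs-time series for one well of a plate-reader run (absorbance at 650 nm,
#' typically every 10 min over 24-30 h).
#'
#' @param t Time, h; strictly increasing.
#' @param od Optical density at 650 nm; non-negative.
#' @param well_id,strain Labels.
#' @param condition `"treated"` (freeze-thawed) or `"untreated"` control.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(t, od, well_id = NA_character_, strain = NA_character_,
                         condition = c("untreated", "treated")) {
  condition <- match.arg(condition)
  if (length(t) != length(od)) stop("t and od lengths differ", call. = FALSE)
  if (any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  if (any(od < 0)) stop("od must be non-negative", call. = FALSE)
  structure(list(t = t, od = od, well_id = well_id, strain = strain,
                 condition = condition),
            class = "growth_curve")
}

#' Log-transform a growth curve
#'
#' `od' = ln(max(od, floor))`; the floor keeps blank-level or negative-drift
#' readings from producing `-Inf`.
#'
#' @param curve A [growth_curve()] object.
#' @param floor Minimum OD before taking logs. Default 0.001.
#' @return The curve with `od` replaced by its floored natural log and a
#'   `log_transformed` flag set.
#' @export
log_transform <- function(curve, floor = 0.001) {
  stopifnot(inherits(curve, "growth_curve"))
  if (floor <= 0) stop("floor must be positive", call. = FALSE)
  curve$od <- log(pmax(curve$od, floor))
  curve$log_transformed <- TRUE
  curve
}

# Rolling-window OLS slope of (t, y) evaluated at each window end; returns
# data.frame(t_end, slope).
rolling_slopes <- function(t, y, window) {
  ends <- t[t >= t[1] + window]
  if (!length(ends)) stop("curve shorter than one window", call. = FALSE)
  slope <- vapply(ends, function(te) {
    sel <- t >= te - window & t <= te
    tt <- t[sel]; yy <- y[sel]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }, numeric(1))
  data.frame(t_end = ends, slope = slope)
}

#' Time at which a culture reaches stationary phase
#'
#' Earliest time, after the growth phase, at which the rolling-window slope of
#' the log-transformed curve falls below `slope_eps`. "After the growth phase"
#' is anchored at the window of maximal slope, so a flat lag phase at the start
#' does not trigger early. A curve that never grows (maximal slope already
#' below `slope_eps`) degenerately returns the first window end.
#'
#' @param curve A [growth_curve()] object (raw OD; log transform applied
#'   internally).
#' @param slope_eps Stationary slope threshold, h-1. Default 0.01.
#' @param window Rolling window, h. Default 2.
#' @param floor Log floor, see [log_transform()].
#' @return Stationary onset time, h.
#' @export
stationary_onset <- function(curve, slope_eps = 0.01, window = 2, floor = 0.001) {
  stopifnot(inherits(curve, "growth_curve"))
  lc <- log_transform(curve, floor)
  rs <- rolling_slopes(lc$t, lc$od, window)
  imax <- which.max(rs$slope)
  if (rs$slope[imax] < slope_eps) return(rs$t_end[1])
  after <- rs[imax:nrow(rs), , drop = FALSE]
  hit <- which(after$slope < slope_eps)
  if (!length(hit))
    stop(sprintf(
      "no plateau detected (min post-peak slope %.4f h-1 >= slope_eps %.4f); run longer or raise slope_eps",
      min(after$slope), slope_eps), call. = FALSE)
  after$t_end[hit[1]]
}

#' Freeze-thaw survival as percent area under the growth curve
#'
#' Cumulative growth of the treated culture relative to its untreated control:
#' both curves are log-transformed, anchored to their own t = 0 value, and
#' integrated by the trapezoid rule from time zero until the untreated control
#' reaches stationary phase; the ratio is reported as a percentage. Identical
#' curves give exactly 100; a treated culture that never grows gives ~0; values
#' above 100 (treated outgrowing control) are reported, not clamped.
#'
#' @param treated,untreated [growth_curve()] objects. If their time bases
#'   differ, the treated curve is linearly interpolated onto the untreated one.
#' @param floor Log floor, see [log_transform()].
#' @param slope_eps,window Stationary-phase detection, see [stationary_onset()].
#' @param log_od Integrate log-transformed OD (default TRUE) or raw
#'   baseline-anchored OD.
#' @return Percent AUC (treated relative to untreated), dimensionless.
#' @export
percent_auc <- function(treated, untreated, floor = 0.001, slope_eps = 0.01,
                        window = 2, log_od = TRUE) {
  stopifnot(inherits(treated, "growth_curve"), inherits(untreated, "growth_curve"))
  t_stat <- stationary_onset(untreated, slope_eps, window, floor)

  tr_od <- if (isTRUE(all.equal(treated$t, untreated$t))) treated$od
           else stats::approx(treated$t, treated$od, xout = untreated$t,
                              rule = 2)$y
  tt <- untreated$t
  if (log_od) {
    y_un <- log(pmax(untreated$od, floor))
    y_tr <- log(pmax(tr_od, floor))
  } else {
    y_un <- untreated$od
    y_tr <- tr_od
  }
  y_un <- y_un - y_un[1]
  y_tr <- y_tr - y_tr[1]
  sel <- tt <= t_stat
  auc_un <- pracma::trapz(tt[sel], y_un[sel])
  auc_tr <- pracma::trapz(tt[sel], y_tr[sel])
  if (auc_un <= 0)
    stop("control failed to grow: untreated AUC <= 0", call. = FALSE)
  100 * auc_tr / auc_un
}

#' Per-strain summary of freeze-thaw survival across a plate
#'
#' Computes percent AUC for each explicitly declared treated/untreated well
#' pair and aggregates to mean +/- SE per strain. Pairing is by the supplied
#' mapping, never by well order.
#'
#' @param curves List of [growth_curve()] objects.
#' @param pairs data.frame with columns `treated_well`, `untreated_well`
#'   naming the `well_id` of each pair.
#' @param ... Passed to [percent_auc()].
#' @return data.frame with columns `strain`, `mean_pct_auc`, `se_pct_auc`, `n`.
#' @export
plate_summary <- function(curves, pairs, ...) {
  ids <- vapply(curves, function(cu) cu$well_id, character(1))
  get_curve <- function(id) {
    j <- which(ids == id)
    if (length(j) != 1)
      stop(sprintf("well '%s' matched %d curves", id, length(j)), call. = FALSE)
    curves[[j]]
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    tr <- get_curve(pairs$treated_well[i])
    un <- get_curve(pairs$untreated_well[i])
    data.frame(strain = tr$strain, pct_auc = percent_auc(tr, un, ...))
  })
  res <- do.call(rbind, res)
  agg <- lapply(split(res, res$strain), function(d)
    data.frame(strain = d$strain[1],
               mean_pct_auc = mean(d$pct_auc),
               se_pct_auc = if (nrow(d) > 1) stats::sd(d$pct_auc) / sqrt(nrow(d)) else 0,
               n = nrow(d)))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Read plate-reader growth curves from long-format CSV
#'
#' Comma-separated with header `well_id,strain,condition,t_h,od650`.
#'
#' @param path CSV file path.
#' @return List of [growth_curve()] objects, one per well.
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  req <- c("well_id", "strain", "condition", "t_h", "od650")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  lapply(split(df, df$well_id), function(d) {
    d <- d[order(d$t_h), ]
    growth_curve(d$t_h, d$od650, well_id = d$well_id[1], strain = d$strain[1],
                 condition = d$condition[1])
  })
}
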