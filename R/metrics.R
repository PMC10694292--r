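#' Observation tables
#'
#' Observations are plain data frames with columns `subject_id`, `group`
#' ("control"/"cirrhosis"), `species`, `kind` ("plasma_conc",
#' "urine_cumulative", "bile_cumulative"), `time_min`, `value`
#' (nmol/L for plasma concentrations, nmol for cumulative amounts) and
#' `below_loq` (logical). [validate_observations()] checks the contract.
#'
#' @param obs a data frame of observations
#' @return the validated data frame, invisibly
#' @export
validate_observations <- function(obs) {
  req <- c("subject_id", "group", "species", "kind", "time_min", "value", "below_loq")
  miss <- setdiff(req, names(obs))
  if (length(miss))
    stop("observation table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(obs$kind %in% c("plasma_conc", "urine_cumulative", "bile_cumulative")))
    stop("unknown observation kind", call. = FALSE)
  if (!all(obs$group %in% c("control", "cirrhosis")))
    stop("group must be control or cirrhosis", call. = FALSE)
  if (any(obs$value < 0)) stop("observed values must be >= 0", call. = FALSE)
  cum <- obs[obs$kind != "plasma_conc", ]
  if (nrow(cum)) {
    by <- split(cum, list(cum$subject_id, cum$species, cum$kind), drop = TRUE)
    for (g in by) {
      g <- g[order(g$time_min), ]
      if (any(diff(g$value) < 0))
        stop("cumulative urine/bile values must be non-decreasing per subject",
             call. = FALSE)
    }
  }
  invisible(obs)
}

#' Area under the concentration-time curve by linear trapezoid
#'
#' Points are clipped to the window; no extrapolation beyond the first or
#' last point inside it. The sparse four-point design makes the linear rule
#' the appropriate choice (a log-trapezoid gains nothing at this density).
#'
#' @param times strictly increasing times (min)
#' @param conc concentrations (nmol/L)
#' @param window (start, end) in min, default 0-120 (the 0-2 h exposure)
#' @return AUC in nmol*min/L
#' @export
auc_trapezoid <- function(times, conc, window = c(0, 120)) {
  if (length(times) != length(conc)) stop("times and conc lengths differ", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  keep <- times >= window[1] & times <= window[2]
  t <- times[keep]; y <- conc[keep]
  # window edges falling between samples are interpolated linearly, so the
  # metric is additive over adjacent windows; no extrapolation outside the
  # sampled range
  for (edge in window) {
    if (!edge %in% t && edge > min(times) && edge < max(times)) {
      yi <- stats::approx(times, conc, xout = edge)$y
      t <- c(t, edge); y <- c(y, yi)
    }
  }
  o <- order(t); t <- t[o]; y <- y[o]
  if (length(t) < 2L)
    stop("need at least 2 points inside the window", call. = FALSE)
  sum(diff(t) * (head_(y) + tail_(y)) / 2)
}

head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1L]

#' Fraction of dose excreted
#'
#' @param cumulative_amount cumulative excreted amount (nmol), >= 0
#' @param dose administered dose (nmol), > 0
#' @return amount/dose; a value > 1 carries attribute
#'   `violation = TRUE` (molar bookkeeping violation) and a warning
#' @export
fraction_dose_excreted <- function(cumulative_amount, dose) {
  if (!is.finite(dose) || dose <= 0) stop("dose must be > 0", call. = FALSE)
  if (any(cumulative_amount < 0)) stop("amount must be >= 0", call. = FALSE)
  f <- cumulative_amount / dose
  if (any(f > 1)) {
    warning("excreted fraction exceeds 1: molar bookkeeping violation", call. = FALSE)
    attr(f, "violation") <- TRUE
  }
  f
}

#' Two-fold-range goodness of fit
#'
#' Percentage of predicted/observed pairs whose observed value lies within
#' half to twice the prediction; the boundary counts as inside. This is the
#' standard PBPK validation summary.
#'
#' @param predicted,observed positive numeric vectors of equal length
#' @return percentage in \[0, 100\]
#' @export
twofold_fraction <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed lengths differ", call. = FALSE)
  if (!length(predicted)) stop("empty pair list", call. = FALSE)
  if (any(predicted <= 0) || any(observed <= 0))
    stop("all predicted and observed values must be > 0", call. = FALSE)
  inside <- observed >= predicted / 2 & observed <= 2 * predicted
  100 * sum(inside) / length(inside)
}

#' Pair observations with simulated values
#'
#' Matches every observation row to the simulated quantity of the same
#' species, kind and time: plasma concentrations to the plasma compartment
#' concentration, cumulative urine/bile amounts to the corresponding sink.
#' The time course must contain every observation time exactly.
#'
#' @param tc a `time_course`
#' @param obs an observation data frame (see [validate_observations()])
#' @return `obs` with a `predicted` column appended
#' @export
pair_pred_obs <- function(tc, obs) {
  validate_observations(obs)
  if (!nrow(obs)) {
    obs$predicted <- numeric(0)
    return(obs)
  }
  misses <- character()
  pred <- numeric(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    k <- match(obs$time_min[i], tc$times)
    st_ok <- obs$species[i] %in% tc$species
    if (is.na(k) || !st_ok) {
      misses <- c(misses, sprintf("%s/%s@%g", obs$species[i], obs$kind[i],
                                  obs$time_min[i]))
      next
    }
    pred[i] <- switch(obs$kind[i],
      plasma_conc = tc_concentration(tc, "plasma", obs$species[i])[k],
      urine_cumulative = tc_amount(tc, "urine", obs$species[i])[k],
      bile_cumulative = tc_amount(tc, "bile", obs$species[i])[k]
    )
  }
  if (length(misses))
    stop("observations without matching simulated value: ",
         paste(unique(misses), collapse = ", "), call. = FALSE)
  obs$predicted <- pred
  obs
}

#' Ratio of group means
#'
#' mean(group_a) / mean(group_b). By package convention group_a is the
#' cirrhosis group and group_b the control group (the source tables do not
#' fix a direction; this orientation is documented here once).
#'
#' @param group_a,group_b non-empty numeric vectors
#' @return scalar ratio
#' @export
ratio_of_means <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty", call. = FALSE)
  mb <- mean(group_b)
  if (mb == 0) stop("denominator group has zero mean", call. = FALSE)
  mean(group_a) / mb
}
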