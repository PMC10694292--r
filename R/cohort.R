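#' Measurement-noise and variability model for synthetic cohorts
#'
#' Multiplicative lognormal measurement noise with coefficient of variation
#' `cv` (sdlog = sqrt(log(1 + cv^2)), median-unbiased), per-kind lower
#' limits of quantification, and lognormal inter-individual variability
#' (`iiv_cv`) applied to hepatic process parameters (first-order clearances
#' and transporter capacities), independently per subject and process.
#'
#' @param cv measurement CV (default 0.2, typical bioanalytical precision)
#' @param loq named lower limits of quantification per observation kind
#'   (plasma_conc in nmol/L, urine/bile cumulative in nmol); values below
#'   LOQ are censored to LOQ/2 and flagged
#' @param iiv_cv inter-individual CV on hepatic parameters (default 0.3)
#' @return an object of class `noise_model`
#' @export
noise_model <- function(cv = 0.2,
                        loq = c(plasma_conc = 0.1, urine_cumulative = 0.01,
                                bile_cumulative = 0.01),
                        iiv_cv = 0.3) {
  if (!is.finite(cv) || cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (!is.finite(iiv_cv) || iiv_cv < 0) stop("iiv_cv must be >= 0", call. = FALSE)
  kinds <- c("plasma_conc", "urine_cumulative", "bile_cumulative")
  full <- stats::setNames(rep(0, 3), kinds)
  full[names(loq)] <- loq
  if (any(full < 0)) stop("loq must be >= 0", call. = FALSE)
  structure(list(cv = cv, loq = full, iiv_cv = iiv_cv), class = "noise_model")
}

#' Sparse sampling design of the cocktail study
#'
#' Plasma samples at 15/30/60/120 min, one cumulative 24-h urine amount
#' and one cumulative 2-h bile amount per subject.
#'
#' @param plasma_times plasma sampling times (min)
#' @param urine_time end of cumulative urine collection (min)
#' @param bile_time end of cumulative bile collection (min)
#' @return an object of class `sampling_design`
#' @export
sampling_design <- function(plasma_times = c(15, 30, 60, 120),
                            urine_time = 1440, bile_time = 120) {
  if (any(plasma_times <= 0) || urine_time <= 0 || bile_time <= 0)
    stop("design times must be > 0", call. = FALSE)
  structure(list(plasma_times = sort(plasma_times), urine_time = urine_time,
                 bile_time = bile_time), class = "sampling_design")
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

.HEPATIC_KINDS <- c("enzymatic_first_order", "total_hepatic_clearance",
                    "mm_transport", "biliary_clearance")

perturb_hepatic_params <- function(model, sdlog) {
  model$processes <- lapply(model$processes, function(p) {
    if (p$kind %in% .HEPATIC_KINDS) {
      f <- exp(stats::rnorm(1, 0, sdlog))
      if (!is.null(p$params$vmax)) p$params$vmax <- p$params$vmax * f
      else p$params$cl <- p$params$cl * f
    }
    p
  })
  model
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Generate a synthetic observation set from a ground-truth model
#'
#' Emulates the cocktail study design: per subject, inter-individual
#' multipliers are drawn for the hepatic parameters, the model is simulated
#' under the given doses, evaluated at the sampling design (plasma
#' concentrations of every species at the plasma times; cumulative urine
#' and bile sink amounts at the collection ends), multiplied by lognormal
#' measurement noise, and censored at the LOQ. Reproducible per seed.
#'
#' @param model ground-truth [model_definition()]
#' @param doses list of [dose_event()]s
#' @param design a [sampling_design()]
#' @param noise a [noise_model()]
#' @param n_subjects number of animals (>= 1)
#' @param group group label, "control" or "cirrhosis"
#' @param seed integer seed
#' @return list with elements `observations` (data frame, see
#'   [validate_observations()]) and `ground_truth` (sufficient to regenerate
#'   the set bit-exactly via [regenerate()])
#' @export
generate_observations <- function(model, doses, design = sampling_design(),
                                  noise = noise_model(), n_subjects, group,
                                  seed) {
  stopifnot(inherits(model, "model_definition"), inherits(design, "sampling_design"),
            inherits(noise, "noise_model"))
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  group <- match.arg(group, c("control", "cirrhosis"))
  t_eval <- sort(unique(c(design$plasma_times, design$urine_time, design$bile_time)))
  sd_meas <- cv_to_sdlog(noise$cv)
  sd_iiv <- cv_to_sdlog(noise$iiv_cv)
  sp_names <- names(model$species)

  obs <- with_preserved_rng({
    set.seed(seed)
    rows <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      m_i <- if (sd_iiv > 0) perturb_hepatic_params(model, sd_iiv) else model
      tc <- simulate_model(build_ode_system(m_i), doses, t_eval)
      sub <- do.call(rbind, lapply(sp_names, function(s) {
        kp <- match(design$plasma_times, t_eval)
        data.frame(
          subject_id = sprintf("%s_%02d", group, i),
          group = group,
          species = s,
          kind = c(rep("plasma_conc", length(kp)), "urine_cumulative",
                   "bile_cumulative"),
          time_min = c(design$plasma_times, design$urine_time, design$bile_time),
          value = c(tc_concentration(tc, "plasma", s)[kp],
                    tc_amount(tc, "urine", s)[match(design$urine_time, t_eval)],
                    tc_amount(tc, "bile", s)[match(design$bile_time, t_eval)]),
          stringsAsFactors = FALSE
        )
      }))
      if (sd_meas > 0)
        sub$value <- sub$value * exp(stats::rnorm(nrow(sub), 0, sd_meas))
      rows[[i]] <- sub
    }
    do.call(rbind, rows)
  })

  loq <- noise$loq[obs$kind]
  below <- obs$value < loq
  obs$value[below] <- loq[below] / 2
  obs$below_loq <- unname(below)
  rownames(obs) <- NULL
  validate_observations(obs)

  gt <- structure(
    list(kind = "single", model = model, doses = doses, design = design,
         noise = noise, n_subjects = n_subjects, group = group, seed = seed),
    class = "ground_truth"
  )
  list(observations = obs, ground_truth = gt)
}

#' Generate paired control and cirrhosis cohorts
#'
#' The control group is generated from the healthy reference model, the
#' cirrhosis group from the same model transformed by the scenario and the
#' true hypothesis (the ground truth of the recovery experiments). Both
#' groups share the sampling design; sub-seeds are derived deterministically
#' from `seed`.
#'
#' @param model healthy reference model
#' @param scenario a [cirrhosis_scenario()]
#' @param hypothesis_truth a [hypothesis_spec()] with the true fold change
#' @param doses dose list
#' @param design a [sampling_design()]
#' @param noise a [noise_model()]
#' @param n_per_group animals per group
#' @param seed integer seed
#' @return list of class `cohort_bundle`: `control`, `cirrhosis`
#'   (observation data frames) and `ground_truth`
#' @export
generate_paired_cohorts <- function(model, scenario, hypothesis_truth, doses,
                                    design = sampling_design(),
                                    noise = noise_model(), n_per_group, seed) {
  model_cirr <- apply_scenario(model, scenario, hypothesis_truth)
  seeds <- with_preserved_rng({
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, 2L)
  })
  ctrl <- generate_observations(model, doses, design, noise, n_per_group,
                                "control", seeds[1L])
  cirr <- generate_observations(model_cirr, doses, design, noise, n_per_group,
                                "cirrhosis", seeds[2L])
  gt <- structure(
    list(kind = "paired", model = model, scenario = scenario,
         hypothesis = hypothesis_truth, doses = doses, design = design,
         noise = noise, n_per_group = n_per_group, seed = seed),
    class = "ground_truth"
  )
  structure(list(control = ctrl$observations, cirrhosis = cirr$observations,
                 ground_truth = gt),
            class = "cohort_bundle")
}

#' Regenerate a dataset from its ground-truth record
#'
#' @param gt a `ground_truth` object
#' @return the same structure the original generator returned, bit-identical
#' @export
regenerate <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  if (gt$kind == "single")
    generate_observations(gt$model, gt$doses, gt$design, gt$noise,
                          gt$n_subjects, gt$group, gt$seed)
  else
    generate_paired_cohorts(gt$model, gt$scenario, gt$hypothesis, gt$doses,
                            gt$design, gt$noise, gt$n_per_group, gt$seed)
}

#' Read or write an observation table as tab-delimited text
#'
#' @param obs observation data frame
#' @param path file path
#' @return `read_observations` returns the validated data frame
#' @export
write_observations <- function(obs, path) {
  validate_observations(obs)
  utils::write.table(obs, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  obs <- utils::read.delim(path, stringsAsFactors = FALSE)
  obs$below_loq <- as.logical(obs$below_loq)
  validate_observations(obs)
  obs
}
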