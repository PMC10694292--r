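#' Assemble the state equations of a model definition
#'
#' Turns a [model_definition()] into a solvable ODE system. The state vector
#' holds amounts (nmol) of every species in every compartment, ordered
#' species-major: for the j-th species the eight consecutive states are
#' plasma, liver_blood, hepatocyte, kidney, rest_of_body, urine, bile,
#' unknown_sink, named `"<species>.<compartment>"`. All linear transfers
#' (blood flows, passive exchange, first-order clearances, filtration) are
#' collected into one rate matrix; Michaelis-Menten transports contribute
#' the only nonlinearity, with rate vmax * Cu / (km + Cu) on the unbound
#' concentration Cu at the source compartment.
#'
#' @param model a validated [model_definition()]
#' @return an object of class `ode_system` carrying the right-hand side,
#'   state names and indexing metadata
#' @export
build_ode_system <- function(model) {
  validate_model(model)
  phys <- model$physiology
  sp_names <- names(model$species)
  n_sp <- length(sp_names)
  n <- 8L * n_sp
  state_names <- as.vector(t(outer(sp_names, .COMPARTMENTS, paste, sep = ".")))
  V <- phys$compartment_volumes
  Q <- phys$blood_flows

  idx <- function(sp, comp) (match(sp, sp_names) - 1L) * 8L + match(comp, .COMPARTMENTS)

  M <- matrix(0, n, n)
  add <- function(i_from, i_to, k) {
    # first-order transfer at rate k (1/min) from state i_from to i_to
    M[i_from, i_from] <<- M[i_from, i_from] - k
    M[i_to, i_from] <<- M[i_to, i_from] + k
  }

  for (sp in model$species) {
    s <- sp$name
    fu <- sp$fraction_unbound
    i_p <- idx(s, "plasma"); i_lb <- idx(s, "liver_blood"); i_h <- idx(s, "hepatocyte")
    i_k <- idx(s, "kidney"); i_r <- idx(s, "rest_of_body")
    # blood-flow distribution (total drug travels with blood)
    add(i_p, i_lb, Q[["liver"]] / V[["plasma"]])
    add(i_lb, i_p, Q[["liver"]] / V[["liver_blood"]])
    add(i_p, i_k, Q[["kidney"]] / V[["plasma"]])
    add(i_k, i_p, Q[["kidney"]] / (V[["kidney"]] * sp$partition[["kidney"]]))
    add(i_p, i_r, Q[["rest_of_body"]] / V[["plasma"]])
    add(i_r, i_p, Q[["rest_of_body"]] / (V[["rest_of_body"]] * sp$partition[["rest_of_body"]]))
    # passive liver_blood <-> hepatocyte diffusion on the unbound gradient
    if (sp$passive_exchange_cl > 0) {
      add(i_lb, i_h, sp$passive_exchange_cl * fu / V[["liver_blood"]])
      add(i_h, i_lb, sp$passive_exchange_cl * fu / V[["hepatocyte"]])
    }
  }

  mm <- list(i_src = integer(), i_tgt = integer(), vmax = numeric(),
             km = numeric(), fu = numeric(), v_src = numeric())
  for (p in model$processes) {
    fu <- model$species[[p$substrate]]$fraction_unbound
    switch(p$kind,
      enzymatic_first_order = {
        k <- p$params$cl * fu / V[["hepatocyte"]]
        add(idx(p$substrate, "hepatocyte"), idx(p$product, "hepatocyte"), k)
      },
      total_hepatic_clearance = {
        k <- p$params$cl * fu / V[["hepatocyte"]]
        add(idx(p$substrate, "hepatocyte"), idx(p$substrate, "unknown_sink"), k)
      },
      glomerular_filtration = {
        add(idx(p$substrate, "plasma"), idx(p$substrate, "urine"),
            p$params$cl * fu / V[["plasma"]])
      },
      biliary_clearance = {
        add(idx(p$substrate, "hepatocyte"), idx(p$substrate, "bile"),
            p$params$cl * fu / V[["hepatocyte"]])
      },
      passive_exchange = {
        add(idx(p$substrate, p$source), idx(p$substrate, p$target),
            p$params$cl * fu / V[[p$source]])
        add(idx(p$substrate, p$target), idx(p$substrate, p$source),
            p$params$cl * fu / V[[p$target]])
      },
      mm_transport = {
        mm$i_src <- c(mm$i_src, idx(p$substrate, p$source))
        mm$i_tgt <- c(mm$i_tgt, idx(p$substrate, p$target))
        mm$vmax <- c(mm$vmax, p$params$vmax)
        mm$km <- c(mm$km, p$params$km)
        mm$fu <- c(mm$fu, fu)
        mm$v_src <- c(mm$v_src, V[[p$source]])
      }
    )
  }

  n_mm <- length(mm$i_src)
  rhs <- function(t, y, parms) {
    dy <- M %*% y
    if (n_mm) {
      cu <- mm$fu * y[mm$i_src] / mm$v_src
      cu[cu < 0] <- 0
      r <- mm$vmax * cu / (mm$km + cu)
      for (q in seq_len(n_mm)) {
        dy[mm$i_src[q]] <- dy[mm$i_src[q]] - r[q]
        dy[mm$i_tgt[q]] <- dy[mm$i_tgt[q]] + r[q]
      }
    }
    list(as.vector(dy))
  }
  # analytic Jacobian: the system is linear apart from the MM transports,
  # whose derivative vmax*km*(fu/V)/(km+Cu)^2 only touches the source column
  jac <- function(t, y, parms) {
    J <- M
    if (n_mm) {
      cu <- mm$fu * y[mm$i_src] / mm$v_src
      cu[cu < 0] <- 0
      dr <- mm$vmax * mm$km * (mm$fu / mm$v_src) / (mm$km + cu)^2
      for (q in seq_len(n_mm)) {
        J[mm$i_src[q], mm$i_src[q]] <- J[mm$i_src[q], mm$i_src[q]] - dr[q]
        J[mm$i_tgt[q], mm$i_src[q]] <- J[mm$i_tgt[q], mm$i_src[q]] + dr[q]
      }
    }
    J
  }

  structure(
    list(model = model, rhs = rhs, jac = jac, state_names = state_names,
         species = sp_names, compartments = .COMPARTMENTS,
         n_states = n, rate_matrix = M, mm = mm),
    class = "ode_system"
  )
}

#' Simulate a dosing scenario
#'
#' Integrates an [build_ode_system()] system over a requested output grid
#' with i.v. bolus dose events added to plasma. Integration uses
#' `deSolve::lsoda` (stiff-capable); dose times are inserted as solver event
#' times so the integrator restarts cleanly at each bolus. Results are
#' deterministic for fixed inputs and tolerances.
#'
#' @param system an `ode_system`
#' @param doses list of [dose_event()]s (empty list gives an all-zero
#'   time course)
#' @param t_eval strictly increasing output times (min)
#' @param rel_tol,abs_tol solver tolerances (defaults 1e-8 / 1e-10 nmol)
#' @return an object of class `time_course`: amounts (nmol) per state on
#'   exactly `t_eval`
#' @export
simulate_model <- function(system, doses = list(), t_eval,
                           rel_tol = 1e-8, abs_tol = 1e-10) {
  stopifnot(inherits(system, "ode_system"))
  if (!is.numeric(t_eval) || length(t_eval) < 1L || any(diff(t_eval) <= 0))
    stop("t_eval must be strictly increasing", call. = FALSE)
  if (!(rel_tol > 0) || !(abs_tol > 0))
    stop("tolerances must be > 0", call. = FALSE)
  for (d in doses) {
    if (!inherits(d, "dose_event")) stop("doses must be dose_event objects", call. = FALSE)
    if (!d$species %in% system$species)
      stop("dose references undeclared species '", d$species, "'", call. = FALSE)
  }

  dose_times <- vapply(doses, `[[`, 0, "time")
  t0 <- min(c(t_eval, dose_times, 0))
  times <- sort(unique(c(t0, t_eval, dose_times)))

  y0 <- stats::setNames(numeric(system$n_states), system$state_names)
  ev <- NULL
  if (length(doses)) {
    plasma_state <- function(sp) paste0(sp, ".plasma")
    at_start <- dose_times == t0
    for (d in doses[at_start])
      y0[plasma_state(d$species)] <- y0[plasma_state(d$species)] + d$amount
    later <- doses[!at_start]
    if (length(later)) {
      ev <- data.frame(
        var = vapply(later, function(d) plasma_state(d$species), ""),
        time = vapply(later, `[[`, 0, "time"),
        value = vapply(later, `[[`, 0, "amount"),
        method = "add", stringsAsFactors = FALSE
      )
      ev <- stats::aggregate(value ~ var + time + method, ev, sum)
    }
  }

  out <- deSolve::lsoda(
    y = y0, times = times, func = system$rhs, parms = NULL,
    jacfunc = system$jac, jactype = "fullusr",
    rtol = rel_tol, atol = abs_tol,
    events = if (!is.null(ev)) list(data = ev) else NULL
  )
  istate <- attr(out, "istate")[1L]
  if (is.null(istate) || istate < 0 || nrow(out) < length(times))
    stop("integration failed; last successful time ", out[nrow(out), 1L], call. = FALSE)

  amounts <- out[match(t_eval, out[, 1L]), -1L, drop = FALSE]
  if (anyNA(amounts)) stop("solver did not report all requested times", call. = FALSE)
  low <- min(amounts)
  if (low < -abs_tol * 100)
    stop("negative state beyond tolerance: ", signif(low, 4), " nmol", call. = FALSE)
  amounts[amounts < 0] <- 0

  vols <- model_state_volumes(system$model)
  structure(
    list(times = as.numeric(t_eval),
         amounts = matrix(amounts, nrow = length(t_eval),
                          dimnames = list(NULL, system$state_names)),
         species = system$species, compartments = system$compartments,
         state_volumes = vols, model_name = system$model$name),
    class = "time_course"
  )
}

model_state_volumes <- function(model) {
  V <- model$physiology$compartment_volumes
  v <- rep(NA_real_, length(.COMPARTMENTS))
  names(v) <- .COMPARTMENTS
  v[.VOLUMETRIC] <- V[.VOLUMETRIC]
  out <- rep(v, times = length(model$species))
  names(out) <- as.vector(t(outer(names(model$species), .COMPARTMENTS, paste, sep = ".")))
  out
}

#' Extract amounts or concentrations from a time course
#'
#' @param tc a `time_course`
#' @param compartment compartment name
#' @param species species name
#' @return numeric vector along `tc$times`; concentrations are
#'   amount / compartment volume (nmol/L) and are undefined for sinks
#' @export
tc_amount <- function(tc, compartment, species) {
  st <- paste0(species, ".", compartment)
  if (!st %in% colnames(tc$amounts))
    stop("no state '", st, "' in time course", call. = FALSE)
  as.vector(tc$amounts[, st])
}

#' @rdname tc_amount
#' @export
tc_concentration <- function(tc, compartment, species) {
  if (!compartment %in% .VOLUMETRIC)
    stop("concentration undefined for sink compartment '", compartment, "'", call. = FALSE)
  tc_amount(tc, compartment, species) /
    tc$state_volumes[[paste0(species, ".", compartment)]]
}

#' @export
as.data.frame.time_course <- function(x, ...) {
  states <- colnames(x$amounts)
  parts <- strsplit(states, ".", fixed = TRUE)
  # species names may themselves contain no '.', compartment is the last part
  comp <- vapply(parts, function(p) p[length(p)], "")
  sp <- vapply(seq_along(parts), function(i)
    sub(paste0("\\.", comp[i], "$"), "", states[i]), "")
  data.frame(
    time_min = rep(x$times, times = length(states)),
    compartment = rep(comp, each = length(x$times)),
    species = rep(sp, each = length(x$times)),
    amount_nmol = as.vector(x$amounts),
    conc_nmol_per_L = as.vector(x$amounts) /
      rep(unname(x$state_volumes[states]), each = length(x$times)),
    stringsAsFactors = FALSE
  )
}

#' Molar balance of a simulation
#'
#' Every metabolite counts as one mole of parent equivalent, so the summed
#' amount over all compartments and sinks must equal the cumulative
#' administered dose at every output time.
#'
#' @param tc a `time_course` produced by [simulate_model()]
#' @param doses the dose list used for the simulation
#' @return data frame with per-time total amount, cumulative dose, relative
#'   deviation, and a consistency flag
#' @export
mass_balance_report <- function(tc, doses = list()) {
  stopifnot(inherits(tc, "time_course"))
  total <- rowSums(tc$amounts)
  dose_t <- vapply(doses, `[[`, 0, "time")
  dose_a <- vapply(doses, `[[`, 0, "amount")
  cum_dose <- vapply(tc$times, function(t) sum(dose_a[dose_t <= t]), 0)
  rel_dev <- ifelse(cum_dose > 0, (total - cum_dose) / cum_dose, total)
  flag <- abs(rel_dev) > 1e-6 | (cum_dose == 0 & total > 1e-9)
  data.frame(time_min = tc$times, total_nmol = total, cum_dose_nmol = cum_dose,
             rel_deviation = rel_dev, inconsistent = flag)
}

#' Write a time course as long-format delimited text
#'
#' Columns: time_min, compartment, species, amount_nmol, conc_nmol_per_L
#' (NA for sinks). Tab-separated.
#'
#' @param tc a `time_course`
#' @param path output file
#' @export
write_timecourse <- function(tc, path) {
  utils::write.table(as.data.frame(tc), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
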