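#' Normalized local sensitivity coefficient
#'
#' `SC = ((C' - C) / (P' - P)) * P / C`: the one-at-a-time finite-difference
#' sensitivity of output `C` to parameter `P`, normalized so it is invariant
#' to the units of both.
#'
#' @param C baseline model output (non-zero)
#' @param C_prime output after perturbing the parameter
#' @param P baseline parameter value
#' @param P_prime perturbed parameter value (`!= P`)
#' @return dimensionless sensitivity coefficient
#' @export
sensitivity_coefficient <- function(C, C_prime, P, P_prime) {
  if (any(P_prime == P)) stop("domain error: P' must differ from P")
  if (any(C == 0)) stop("undefined-normalization error: baseline output C is 0")
  (C_prime - C) / (P_prime - P) * P / C
}

# perturbable scalar parameter paths per model. Derived quantities (fecal
# excretion tied to synthesis, liver weight from VLc x BW) are perturbed only
# through their independent parents.
sensitivity_paths <- function(model) {
  phys <- c("physiology.BW", "physiology.Hep", "physiology.QCc",
            "physiology.VBc", "physiology.VLc", "physiology.VRc",
            "physiology.VSc", "physiology.VFc",
            "physiology.QLac", "physiology.QRc", "physiology.QSc",
            "physiology.QFc", "physiology.QITc")
  if (model == "ba") {
    c("ba.Gdose", "ba.CBfs", "ba.synthesis", "ba.QIb", "ba.ka",
      "ba.Km_BSEP", "ba.VmaxBSEPc", "ba.aBSEP", "ba.MW_BSEP",
      "physchem.ba.BP",
      "ba.partition.liver", "ba.partition.intestine", "ba.partition.rapid",
      "ba.partition.slow", "ba.partition.fat",
      "physiology.VITc", phys)
  } else {
    c("drug.ODOSEmg", "drug.Fa", "drug.ka_drug", "drug.Km_met",
      "drug.VmaxMc", "drug.CLMc", "drug.frm", "drug.kbile_bosentan",
      "drug.kbile_ro",
      "physchem.bosentan.BP", "physchem.ro.BP",
      "drug.partition_bosentan.liver", "drug.partition_bosentan.rapid",
      "drug.partition_bosentan.slow", "drug.partition_bosentan.fat",
      "drug.partition_ro.liver", "drug.partition_ro.rapid",
      "drug.partition_ro.slow", "drug.partition_ro.fat",
      phys)
  }
}

# endpoint evaluators; the BA endpoint is the day-1 plasma Cmax after an
# overnight fast, drug endpoints are the Cmax over the first dosing interval
sensitivity_endpoint <- function(model, ps, endpoint, dt_out, rtol, atol) {
  if (model == "ba") {
    if (ps$ba$fecal_excretion != ps$ba$synthesis)
      ps$ba$fecal_excretion <- ps$ba$synthesis  # keep mass balance tied
    validate_parameter_set(ps)
    traj <- simulate_ba(ps, days = 1, dt_out = dt_out, rtol = rtol, atol = atol)
    series <- sub("^cmax_", "", endpoint)
    extract_cmax(traj, series, window = c(0, 24))$cmax
  } else {
    validate_parameter_set(ps)
    traj <- simulate_drug(ps, days = 1, dt_out = dt_out, rtol = rtol, atol = atol)
    series <- switch(model,
                     bosentan = "plasma_bosentan",
                     ro = "plasma_ro")
    extract_cmax(traj, series, window = c(ps$schedule$dose_times[1],
                                          ps$schedule$dose_times[2]))$cmax
  }
}

#' One-at-a-time local sensitivity analysis
#'
#' Perturbs every scalar model parameter by +5% (one at a time, all others at
#' their baseline), recomputes the endpoint, and reports the normalized
#' sensitivity coefficient of Eq.-style form `SC = ((C'-C)/(P'-P)) * P/C`.
#' Derived parameters are perturbed through their independent parents only
#' (fecal excretion follows synthesis; liver weight follows `VLc` and `BW`).
#'
#' @param model `"ba"` (endpoint: day-1 plasma bile-acid Cmax), `"bosentan"`
#'   or `"ro"` (endpoint: plasma Cmax over the first dosing interval)
#' @param ps baseline `ba_parameter_set`
#' @param endpoint endpoint selector for the BA model (`"cmax_plasma"`,
#'   `"cmax_blood"` or `"cmax_hepatic"`)
#' @param threshold |SC| display cutoff (default 0.1, matching the published
#'   figure convention); the full table is always returned
#' @param delta relative perturbation (default 0.05)
#' @param dt_out,rtol,atol solver controls (a coarser grid than the
#'   production default is enough for a finite-difference endpoint)
#' @return object of class `sensitivity_report`: data.frame with columns
#'   `parameter`, `P`, `P_prime`, `C`, `C_prime`, `SC`, `above_threshold`,
#'   `failed`, sorted by |SC| descending; attributes `threshold`, `endpoint`
#' @export
run_sensitivity <- function(model = c("ba", "bosentan", "ro"),
                            ps = default_parameters(),
                            endpoint = "cmax_plasma", threshold = 0.1,
                            delta = 0.05, dt_out = 0.01,
                            rtol = 1e-8, atol = 1e-10) {
  model <- match.arg(model)
  paths <- sensitivity_paths(model)
  C0 <- sensitivity_endpoint(model, ps, endpoint, dt_out, rtol, atol)
  rows <- lapply(paths, function(pp) {
    P <- get_path(unclass(ps), pp)
    Pp <- P * (1 + delta)
    psi <- ps
    psi <- set_path_ps(psi, pp, Pp)
    Cp <- tryCatch(sensitivity_endpoint(model, psi, endpoint, dt_out, rtol, atol),
                   error = function(e) NA_real_)
    data.frame(parameter = pp, P = P, P_prime = Pp, C = C0, C_prime = Cp,
               SC = if (is.na(Cp)) NA_real_
                    else sensitivity_coefficient(C0, Cp, P, Pp),
               failed = is.na(Cp))
  })
  rep <- do.call(rbind, rows)
  rep$above_threshold <- !is.na(rep$SC) & abs(rep$SC) > threshold
  rep <- rep[order(-abs(ifelse(is.na(rep$SC), -Inf, rep$SC))), ]
  rownames(rep) <- NULL
  structure(rep, class = c("sensitivity_report", "data.frame"),
            threshold = threshold, endpoint = endpoint, model = model)
}

set_path_ps <- function(ps, path, value) {
  cls <- class(ps)
  ps <- set_path(unclass(ps), path, value)
  class(ps) <- cls
  ps
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> model '%s', endpoint '%s', |SC| > %g:\n",
              attr(x, "model"), attr(x, "endpoint"), attr(x, "threshold")))
  shown <- x[x$above_threshold, c("parameter", "SC")]
  print.data.frame(shown, row.names = FALSE, digits = 3)
  if (any(x$failed))
    cat("flagged (simulation failed):",
        paste(x$parameter[x$failed], collapse = ", "), "\n")
  invisible(x)
}
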