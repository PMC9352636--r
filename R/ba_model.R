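# canonical state names for the coupled model (order matches the compiled RHS)
.state_names <- c(
  "liver", "gallbladder", "lumen", "intestine", "blood", "rapid", "slow",
  "fat", "feces",
  "bos_depot", "bos_blood", "bos_liver", "bos_rapid", "bos_slow", "bos_fat",
  "bos_metabolized", "bos_bile",
  "ro_blood", "ro_liver", "ro_rapid", "ro_slow", "ro_fat", "ro_bile"
)
.ba_states <- .state_names[1:9]
.drug_states <- .state_names[10:23]

#' In vitro-to-in vivo scaling factor for BSEP transport capacity
#'
#' `SF = aBSEP x MW_BSEP x Hep x WL x 60 x 1e-9`, converting a vesicular-assay
#' maximum transport rate expressed per mg BSEP and per minute into a
#' whole-liver, per-hour capacity: whole-liver Vmax (µmol/h) =
#' Vmax_in-vitro (µmol/min/mg BSEP) x SF.
#'
#' @param aBSEP BSEP abundance, pmol per 10^6 hepatocytes
#' @param MW_BSEP BSEP molecular weight, g/mol (140,000 for the 140 kDa
#'   protein)
#' @param Hep hepatocellularity, 10^6 cells per g liver
#' @param WL liver weight, g
#' @return scaling factor (mg BSEP per entire liver, with the min-to-h
#'   conversion folded in)
#' @export
bsep_scaling_factor <- function(aBSEP, MW_BSEP, Hep, WL) {
  if (any(c(MW_BSEP, Hep, WL) <= 0) || any(aBSEP < 0))
    stop("domain error: bsep_scaling_factor arguments must be positive (aBSEP >= 0)")
  aBSEP * MW_BSEP * Hep * WL * 60 * 1e-9
}

#' Michaelis-Menten BSEP-mediated biliary efflux
#'
#' `E = Vmax * CVL / (Km + CVL)`, the saturable canalicular export of bile
#' acids from hepatocytes driven by the free intrahepatic concentration.
#'
#' @param CVL free liver concentration, µM (>= 0)
#' @param Vmax whole-liver maximum efflux rate, µmol/h
#' @param Km Michaelis constant, µM (> 0)
#' @return efflux rate, µmol/h (strictly below `Vmax`, monotone in `CVL`)
#' @export
bsep_efflux <- function(CVL, Vmax, Km) {
  if (any(CVL < 0)) stop("domain error: negative free liver concentration")
  if (any(Vmax < 0) || any(Km <= 0)) stop("domain error: Vmax >= 0 and Km > 0 required")
  Vmax * CVL / (Km + CVL)
}

# flatten a parameter set into the named numeric vector consumed by the
# compiled RHS; sens scaling must already have been applied to ps
engine_params <- function(ps, ba_on = TRUE, drug_on = FALSE,
                          inhibition = FALSE, n_doses = 0) {
  phys <- derived_physiology(ps)
  pc <- ps$physchem
  ba <- ps$ba
  dr <- ps$drug
  SF <- bsep_scaling_factor(ba$aBSEP, ba$MW_BSEP, ps$physiology$Hep, phys$WL)
  dose_umol <- mg_to_umol(dr$ODOSEmg, pc$bosentan$MW) * dr$Fa
  scale <- max(1, total_pool_size(ps), n_doses * dose_umol)
  c(
    VB = phys$VB, VL = phys$VL, VIT = phys$VIT, VR = phys$VR, VS = phys$VS,
    VF = phys$VF,
    QLa = phys$QLa, QIT = phys$QIT, QR = phys$QR, QS = phys$QS, QF = phys$QF,
    KL = ba$partition$liver / pc$ba$BP,
    KIT = ba$partition$intestine / pc$ba$BP,
    KR = ba$partition$rapid / pc$ba$BP,
    KS = ba$partition$slow / pc$ba$BP,
    KF = ba$partition$fat / pc$ba$BP,
    PL = ba$partition$liver,
    synth = ba$synthesis, qfec = ba$fecal_excretion, kfec_clamp = 0.1,
    QIb = ba$QIb, ka = ba$ka,
    VmaxB = ba$VmaxBSEPc * SF, KmB = ba$Km_BSEP,
    kad = dr$ka_drug,
    VmaxM = dr$VmaxMc * ps$physiology$MPPGL * phys$WL * 60,
    KmM = dr$Km_met,
    CLM = dr$CLMc * ps$physiology$Hep * phys$WL,
    frm = dr$frm, kbb = dr$kbile_bosentan,
    KLb = dr$partition_bosentan$liver / pc$bosentan$BP,
    KRb = dr$partition_bosentan$rapid / pc$bosentan$BP,
    KSb = dr$partition_bosentan$slow / pc$bosentan$BP,
    KFb = dr$partition_bosentan$fat / pc$bosentan$BP,
    PLb = dr$partition_bosentan$liver,
    kbm = dr$kbile_ro,
    KLm = dr$partition_ro$liver / pc$ro$BP,
    KRm = dr$partition_ro$rapid / pc$ro$BP,
    KSm = dr$partition_ro$slow / pc$ro$BP,
    KFm = dr$partition_ro$fat / pc$ro$BP,
    PLm = dr$partition_ro$liver,
    Kib = dr$Ki_bosentan, Kim = dr$Ki_ro,
    ba_on = as.numeric(ba_on), drug_on = as.numeric(drug_on),
    inhib_on = as.numeric(inhibition),
    negtol = 1e-9 * scale
  )
}

# initial amounts: gall bladder full, blood at the fasting level, everything
# else empty (the published model's stated initial condition)
initial_state <- function(ps, ba_on = TRUE) {
  phys <- derived_physiology(ps)
  y0 <- stats::setNames(numeric(length(.state_names)), .state_names)
  if (ba_on) {
    y0["gallbladder"] <- ps$ba$Gdose
    y0["blood"] <- ps$ba$CBfs * ps$physchem$ba$BP * phys$VB
  }
  y0
}

#' Bile-acid model right-hand side (reference R implementation)
#'
#' Derivatives (µmol/h) of the eight bile-acid compartments plus the fecal
#' sink: zero-order hepatic synthesis, perfusion-limited exchange of all
#' non-lumen tissues with blood, saturable BSEP efflux from the liver split
#' `QIb` to the intestinal lumen and `1 - QIb` to the gall bladder,
#' first-order lumen-to-intestinal-tissue absorption, portal routing of
#' intestinal venous blood into the liver, and zero-order fecal loss from the
#' lumen (smoothly limited to the available amount). The gall bladder changes
#' only through biliary inflow and emptying events.
#'
#' This mirrors the compiled production RHS and is used as the independent
#' route in engine cross-checks; an optional inhibition context supplies free
#' liver inhibitor concentrations for the non-competitive modulation factor.
#'
#' @param state named amounts vector (µmol) over
#'   `liver, gallbladder, lumen, intestine, blood, rapid, slow, fat, feces`
#' @param params a `ba_parameter_set` (sens scaling already applied)
#' @param inhibition optional `list(CVL_bosentan =, CVL_ro =)` free liver
#'   inhibitor concentrations in µM
#' @return named derivative vector, µmol/h
#' @export
ba_rhs <- function(state, params, inhibition = NULL) {
  ep <- engine_params(params, ba_on = TRUE)
  y <- state[.ba_states]
  CA <- y["blood"] / ep["VB"]
  CVL <- y["liver"] / (ep["VL"] * ep["KL"])
  CVIT <- y["intestine"] / (ep["VIT"] * ep["KIT"])
  CVR <- y["rapid"] / (ep["VR"] * ep["KR"])
  CVS <- y["slow"] / (ep["VS"] * ep["KS"])
  CVF <- y["fat"] / (ep["VF"] * ep["KF"])
  Cfree <- y["liver"] / (ep["VL"] * ep["PL"])
  vmax_eff <- ep["VmaxB"]
  if (!is.null(inhibition))
    vmax_eff <- vmax_eff / (1 + inhibition$CVL_bosentan / params$drug$Ki_bosentan +
                              inhibition$CVL_ro / params$drug$Ki_ro)
  E <- bsep_efflux(max(Cfree, 0), vmax_eff, ep["KmB"])
  absr <- ep["ka"] * y["lumen"]
  fec <- ep["qfec"] * y["lumen"] / (y["lumen"] + ep["kfec_clamp"])
  QLtot <- ep["QLa"] + ep["QIT"]
  QC <- QLtot + ep["QR"] + ep["QS"] + ep["QF"]
  d <- c(
    liver = ep["QLa"] * CA + ep["QIT"] * CVIT - QLtot * CVL + ep["synth"] - E,
    gallbladder = (1 - ep["QIb"]) * E,
    lumen = ep["QIb"] * E - absr - fec,
    intestine = ep["QIT"] * (CA - CVIT) + absr,
    blood = QLtot * CVL + ep["QR"] * CVR + ep["QS"] * CVS + ep["QF"] * CVF - QC * CA,
    rapid = ep["QR"] * (CA - CVR),
    slow = ep["QS"] * (CA - CVS),
    fat = ep["QF"] * (CA - CVF),
    feces = fec
  )
  stats::setNames(as.numeric(d), .ba_states)
}

# derived concentration series shared by all model wrappers
derive_series <- function(time, amounts, ps, which = c("ba", "drug")) {
  phys <- derived_physiology(ps)
  d <- data.frame(time = time)
  if ("ba" %in% which) {
    blood <- amounts[, "blood"] / phys$VB
    d$blood <- blood
    d$plasma <- blood / ps$physchem$ba$BP
    d$hepatic <- amounts[, "liver"] * 1000 / phys$WL  # nmol/g tissue
  }
  if ("drug" %in% which) {
    d$blood_bosentan <- amounts[, "bos_blood"] / phys$VB
    d$plasma_bosentan <- d$blood_bosentan / ps$physchem$bosentan$BP
    d$free_liver_bosentan <- amounts[, "bos_liver"] /
      (phys$VL * ps$drug$partition_bosentan$liver)
    d$blood_ro <- amounts[, "ro_blood"] / phys$VB
    d$plasma_ro <- d$blood_ro / ps$physchem$ro$BP
    d$free_liver_ro <- amounts[, "ro_liver"] / (phys$VL * ps$drug$partition_ro$liver)
  }
  d
}

run_compiled <- function(ps, y0, events_df, horizon, dt_out, rtol, atol,
                         ba_on, drug_on, inhibition, which_states) {
  ev <- matrix(0, 0, 3)
  if (!is.null(events_df) && nrow(events_df)) {
    type <- ifelse(events_df$kind == "gallbladder-emptying", 1, 2)
    ev <- cbind(events_df$time, type,
                ifelse(is.na(events_df$amount), 0, events_df$amount))
  }
  n_doses <- if (is.null(events_df)) 0 else sum(events_df$kind == "oral-dose")
  ep <- engine_params(ps, ba_on = ba_on, drug_on = drug_on,
                      inhibition = inhibition, n_doses = n_doses)
  tout <- seq(0, horizon, by = dt_out)
  if (tout[length(tout)] < horizon) tout <- c(tout, horizon)
  m <- cpp_simulate(as.numeric(y0), ep, ev, tout, rtol, atol)
  colnames(m) <- .state_names
  m <- m[, which_states, drop = FALSE]
  list(time = tout, amounts = m)
}

#' Simulate the bile-acid model
#'
#' Runs the GCDCA homeostasis model for a virtual individual over `days`
#' simulated days: overnight fast, gall-bladder emptying at each meal
#' (default 8:00, 12:00, 16:00), enterohepatic recycling, BSEP-mediated
#' biliary efflux and fecal loss. Optionally applies the empirical pool
#' scaling factor `sens` first.
#'
#' @param ps a `ba_parameter_set` (default: reference individual)
#' @param days simulated days (default from `ps$schedule`)
#' @param sens empirical pool scaling factor applied before simulation
#'   (default 1)
#' @param dt_out output grid in h (default 0.01)
#' @param rtol,atol solver tolerances
#' @param engine `"cpp"` (production) or `"R"` (reference implementation of
#'   the same Dormand-Prince scheme via the generic [simulate()] engine)
#' @return `pbk_trajectory` with derived `blood` / `plasma` (µM) and
#'   `hepatic` (nmol/g) series
#' @export
simulate_ba <- function(ps = default_parameters(), days = NULL, sens = 1,
                        dt_out = 0.01, rtol = 1e-8, atol = 1e-10,
                        engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  days <- days %||% ps$schedule$simulation_days
  if (sens != 1) ps <- apply_sens_scaling(ps, sens)
  horizon <- 24 * days
  events <- build_event_schedule(days, meal_times = ps$schedule$meal_times)
  y0 <- initial_state(ps)
  if (engine == "cpp") {
    res <- run_compiled(ps, y0, events, horizon, dt_out, rtol, atol,
                        ba_on = TRUE, drug_on = FALSE, inhibition = FALSE,
                        which_states = .ba_states)
  } else {
    transforms <- list(
      "gallbladder-emptying" = function(state, amount) {
        state["lumen"] <- state["lumen"] + state["gallbladder"]
        state["gallbladder"] <- 0
        state
      }
    )
    tr <- simulate(function(t, y) ba_rhs(y, ps), y0[.ba_states], events,
                   horizon, dt_out = dt_out, rtol = rtol, atol = atol,
                   transforms = transforms,
                   neg_tol = 1e-9 * total_pool_size(ps))
    res <- list(time = tr$time, amounts = tr$amounts)
  }
  traj <- new_trajectory(res$time, res$amounts,
                         derived = derive_series(res$time, res$amounts, ps, "ba"),
                         params = ps, model = "ba", schedule = events)
  attr(traj, "source_rate") <- ps$ba$synthesis
  traj
}
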