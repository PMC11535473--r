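#' Kinetic parameters of the mechanistic fed-batch model
#'
#' Assembles the parameter vector of the mechanistic kinetic model (MMK):
#' unstructured Monod growth on glucose, Luedeking--Piret antibody
#' production, Michaelis--Menten membrane transport of glucose, glutamine and
#' galactose into the cytosol, nucleotide-sugar-donor (NSD) synthesis by
#' uni-uni and bi-ternary enzyme kinetics, constant-flux Golgi NSD transport,
#' and sequential G0F -> G1F -> G2F glycan maturation over a fixed Golgi
#' residence time.
#'
#' The defaults are synthetic fixture values chosen to produce trajectories
#' qualitatively matching a galactose-fed GS CHO culture (peak VCD of order
#' 1e7 cells/mL, titer of order 1e2 mg/L, sub-mM NSD pools that respond to
#' galactose boluses). They are not literature estimates.
#'
#' Units: times in h, concentrations in mM (culture-volume basis, including
#' the intracellular pools), VCD in cells/mL, titer in mg/L. Yields
#' `Y_xglc` in cells/mmol; `m_glc`, `V_gal`, `alpha_mab`, `beta_mab` per
#' cell; transport and synthesis Vmax in mM/h.
#'
#' @param ... Named overrides of any default parameter.
#' @return A named list with class `kinetic_params`.
#' @examples
#' p <- kinetic_params(mu_max = 0.045)
#' p$mu_max
#' @export
kinetic_params <- function(...) {
  p <- list(
    # growth / death / glucose
    mu_max = 0.035,     # 1/h
    K_glc  = 2.0,       # mM
    k_d    = 0.0035,    # 1/h
    Y_xglc = 4e8,       # cells/mmol
    m_glc  = 1e-12,     # mmol/(cell h)
    # mAb production (growth-associated + basal)
    alpha_mab = 3e-8,   # mg/cell
    beta_mab  = 5e-11,  # mg/(cell h)
    # galactose uptake (optional glucose inhibition, Inf disables)
    V_gal = 2.5e-11,    # mmol/(cell h)
    K_gal = 5,          # mM
    Ki_glc_gal = Inf,   # mM
    # membrane transport into the cytosol (bulk mM/h)
    Vt_glc = 0.10, Kt_glc = 5,
    Vt_gln = 0.05, Kt_gln = 2,
    Vt_gal = 0.018, Kt_gal = 5,
    # NSD synthesis
    Vmax_udpglc = 0.05,  Km_udpglc = 0.3,     # Glc_in -> UDP-Glc
    Vmax_epim   = 0.04,  Km_epim   = 0.3,     # UDP-Glc -> UDP-Gal (epimerase)
    Vmax_salv   = 0.03,  Km_salv   = 0.5,     # Gal_in -> UDP-Gal (salvage)
    Vmax_udpglcnac = 0.08, Km_udpglcnac = 0.3, Km2_udpglcnac = 0.3,
    Vmax_udpgalnac = 0.01, Km_udpgalnac = 0.3, # UDP-GlcNAc -> UDP-GalNAc
    # constant-flux Golgi transport per NSD (mM/h)
    f_udpglc = 0.010, f_udpgal = 0.014,
    f_udpglcnac = 0.005, f_udpgalnac = 0.004,
    # galactosyltransferase pseudo-rates and Golgi residence time
    k_gal1 = 0.9, K_gal1 = 0.5,   # G0F -> G1F
    k_gal2 = 0.6, K_gal2 = 0.5,   # G1F -> G2F
    tau_G  = 1.0,                 # h
    # byproduct yields (data-generation extension)
    Y_lac = 1.4, Y_nh4 = 0.6, Y_glu = 0.3
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) {
    stop("unknown kinetic parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(dots)] <- dots
  vals <- unlist(p)
  if (any(vals < 0)) {
    stop("kinetic parameters must be non-negative", call. = FALSE)
  }
  structure(p, class = "kinetic_params")
}

#' Initial state of the fed-batch model
#'
#' The ODE state: culture volume, viable cells, six extracellular species,
#' antibody titer, three intracellular sugar pools, four NSD pools, and the
#' secreted antibody mass carried by each glycoform (mg/L). Defaults give a
#' fresh 70 mL shake-flask inoculated at 0.3e6 cells/mL.
#'
#' @param ... Named overrides of any state component.
#' @return Named numeric state vector.
#' @export
initial_state <- function(...) {
  s <- c(
    V = 70, Xv = 0.3e6,
    GLC = 45, GLN = 6, GLU = 1, LAC = 0.5, NH4 = 0.5, GAL = 0.5,
    mAb = 1,
    Glc_in = 0.2, Gln_in = 0.2, Gal_in = 0.05,
    UDP_Glc = 0.30, UDP_Gal = 0.15, UDP_GlcNAc = 0.60, UDP_GalNAc = 0.15,
    M_G0F = 0.8, M_G1F = 0.15, M_G2F = 0.05
  )
  dots <- unlist(list(...))
  unknown <- setdiff(names(dots), names(s))
  if (length(unknown) > 0) {
    stop("unknown state component(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  s[names(dots)] <- dots
  if (s[["V"]] <= 0) stop("volume must be positive", call. = FALSE)
  s
}

#' Elementary rate laws
#'
#' `monod_mu()` is the Monod specific growth rate on glucose; `mm_uni()` is
#' single-substrate (uni-uni) Michaelis--Menten kinetics; `mm_bi_ternary()`
#' is the two-substrate bi-ternary complex rate, symmetric under exchange of
#' the (substrate, constant) pairs.
#'
#' @param Glc,S,S1,S2 Substrate concentrations (mM), non-negative.
#' @param p A [kinetic_params()] object.
#' @param Vmax Maximal rate.
#' @param Km,K1,K2 Half-saturation constants (mM), positive.
#' @return Rate (same units as `Vmax`; `monod_mu` in 1/h).
#' @examples
#' monod_mu(9, kinetic_params(mu_max = 0.04, K_glc = 1)) # 0.036
#' mm_uni(1.5, Vmax = 2, Km = 0.5)                       # 1.5
#' @export
monod_mu <- function(Glc, p) {
  p$mu_max * Glc / (p$K_glc + Glc)
}

#' @rdname monod_mu
#' @export
mm_uni <- function(S, Vmax, Km) {
  Vmax * S / (Km + S)
}

#' @rdname monod_mu
#' @export
mm_bi_ternary <- function(S1, S2, Vmax, K1, K2) {
  Vmax * S1 * S2 / ((K1 + S1) * (K2 + S2))
}

#' Instantaneous glycoform split of newly secreted antibody
#'
#' Sequential maturation G0F -> G1F -> G2F by galactosyltransferase, with
#' pseudo-first-order rates saturating in the UDP-Gal donor, applied over the
#' Golgi residence time `tau_G`: kappa1 = k_gal1 U/(K_gal1+U), kappa2 =
#' k_gal2 U/(K_gal2+U). The closed form of the two-step first-order chain
#' gives the fraction of molecules leaving the Golgi in each glycoform; the
#' kappa1 = kappa2 degenerate case uses the analytic limit
#' kappa tau exp(-kappa tau).
#'
#' @param udp_gal UDP-Gal concentration (mM), non-negative.
#' @param p A [kinetic_params()] object.
#' @return Numeric vector `c(phi_G0F, phi_G1F, phi_G2F)`, each in \[0, 1\],
#'   summing to 1.
#' @export
glycan_instantaneous_fractions <- function(udp_gal, p) {
  u <- max(udp_gal, 0)
  k1 <- p$k_gal1 * u / (p$K_gal1 + u)
  k2 <- p$k_gal2 * u / (p$K_gal2 + u)
  tau <- p$tau_G
  phi0 <- exp(-k1 * tau)
  if (abs(k1 - k2) < 1e-12 * max(k1, k2, 1e-300)) {
    phi1 <- k1 * tau * exp(-k1 * tau)
  } else {
    phi1 <- k1 / (k2 - k1) * (exp(-k1 * tau) - exp(-k2 * tau))
  }
  phi2 <- 1 - phi0 - phi1
  c(phi_G0F = phi0, phi_G1F = phi1, phi_G2F = max(phi2, 0))
}

# Smooth non-negativity gate: multiplies consumption fluxes so they vanish
# continuously as the pool empties (keeps the RHS smooth for the stiff solver).
# eps = 1e-6 mM (1 nM) is physically negligible yet wide enough that the
# boundary layer at an emptied pool stays resolvable at the default tolerances.
.gate <- function(S, eps = 1e-6) {
  if (S > 0) S / (S + eps) else 0
}

#' Right-hand side of the fed-batch ODE system
#'
#' Derivatives of all 19 state components between feed/sampling events.
#' Growth is Monod on glucose with a constant death rate (no byproduct
#' toxicity); antibody production is growth-associated plus basal; galactose
#' uptake is Michaelis--Menten with an optional glucose-inhibition factor
#' 1/(1 + Glc/Ki); intracellular pools receive membrane-transport influx and
#' lose synthesis consumption plus growth dilution; NSDs gain enzymatic
#' synthesis and lose a constant Golgi efflux (gated at zero) plus dilution;
#' newly secreted antibody mass is split across glycoforms by
#' [glycan_instantaneous_fractions()], so the glycoform masses sum to titer
#' by construction.
#'
#' @param t Time (h); the system is autonomous, `t` is unused.
#' @param state Named state vector as from [initial_state()].
#' @param p A [kinetic_params()] object.
#' @return List of derivatives (deSolve convention).
#' @export
fedbatch_rhs <- function(t, state, p) {
  if (any(!is.finite(state))) {
    bad <- names(state)[!is.finite(state)][1]
    stop("non-finite state component during integration: ", bad, call. = FALSE)
  }
  # positional access against the canonical state order (initial_state());
  # this function sits in the integrator's inner loop
  s <- state # rate laws evaluated on clipped pools
  neg <- state < 0
  if (any(neg)) s[neg] <- 0
  Xv <- s[2]; GLC <- s[3]; GLN <- s[4]; GAL <- s[8]
  Glc_in <- s[10]; Gln_in <- s[11]; Gal_in <- s[12]
  UDP_Glc <- s[13]; UDP_Gal <- s[14]; UDP_GlcNAc <- s[15]; UDP_GalNAc <- s[16]
  Xv_L <- Xv * 1e3 # cells/mL -> cells/L, so per-cell rates give mM/h

  mu <- p$mu_max * GLC / (p$K_glc + GLC)

  q_glc <- (mu / p$Y_xglc + p$m_glc) * Xv_L * .gate(GLC)
  inhib <- if (is.finite(p$Ki_glc_gal)) 1 / (1 + GLC / p$Ki_glc_gal) else 1
  q_gal <- p$V_gal * GAL / (p$K_gal + GAL) * inhib * Xv_L * .gate(GAL)

  t_glc <- p$Vt_glc * GLC / (p$Kt_glc + GLC) * .gate(GLC)
  t_gln <- p$Vt_gln * GLN / (p$Kt_gln + GLN) * .gate(GLN)
  t_gal <- p$Vt_gal * GAL / (p$Kt_gal + GAL) * .gate(GAL)

  d_mab <- (p$alpha_mab * mu + p$beta_mab) * Xv_L

  v_udpglc <- p$Vmax_udpglc * Glc_in / (p$Km_udpglc + Glc_in) * .gate(Glc_in)
  v_epim <- p$Vmax_epim * UDP_Glc / (p$Km_epim + UDP_Glc) * .gate(UDP_Glc)
  v_salv <- p$Vmax_salv * Gal_in / (p$Km_salv + Gal_in) * .gate(Gal_in)
  v_udpglcnac <- p$Vmax_udpglcnac * Glc_in * Gln_in /
    ((p$Km_udpglcnac + Glc_in) * (p$Km2_udpglcnac + Gln_in)) *
    .gate(Glc_in) * .gate(Gln_in)
  v_udpgalnac <- p$Vmax_udpgalnac * UDP_GlcNAc /
    (p$Km_udpgalnac + UDP_GlcNAc) * .gate(UDP_GlcNAc)

  phi <- glycan_instantaneous_fractions(UDP_Gal, p)

  list(c(
    0,                                       # V
    (mu - p$k_d) * Xv,                       # Xv
    -q_glc,                                  # GLC
    -t_gln,                                  # GLN
    p$Y_glu * t_gln,                         # GLU
    p$Y_lac * q_glc,                         # LAC
    p$Y_nh4 * t_gln,                         # NH4
    -q_gal,                                  # GAL
    d_mab,                                   # mAb
    t_glc - v_udpglc - v_udpglcnac - mu * Glc_in,
    t_gln - v_udpglcnac - mu * Gln_in,
    t_gal - v_salv - mu * Gal_in,
    v_udpglc - v_epim - p$f_udpglc * .gate(UDP_Glc) - mu * UDP_Glc,
    v_epim + v_salv - p$f_udpgal * .gate(UDP_Gal) - mu * UDP_Gal,
    v_udpglcnac - v_udpgalnac - p$f_udpglcnac * .gate(UDP_GlcNAc) -
      mu * UDP_GlcNAc,
    v_udpgalnac - p$f_udpgalnac * .gate(UDP_GalNAc) - mu * UDP_GalNAc,
    d_mab * phi[[1]],                        # M_G0F
    d_mab * phi[[2]],                        # M_G1F
    d_mab * (1 - phi[[1]] - phi[[2]])        # M_G2F: exact mass closure
  ))
}

#' Feed and sampling schedule
#'
#' Discrete events of a fed-batch run: bolus feeds (by default interpreted as
#' a direct concentration increment of the fed species, volume unchanged;
#' `mode = "stock"` instead mixes a feed stock of concentration `conc_mM` and
#' volume `volume_mL` into the culture) and sampling events that remove
#' volume without changing any intensive quantity.
#'
#' @param feed_events Tibble/data frame with columns `time_h`, `species`,
#'   `dose_mM` (increment mode) and optionally `conc_mM`, `volume_mL`
#'   (stock mode). May be empty.
#' @param sample_events Tibble/data frame with columns `time_h`,
#'   `volume_mL_removed`. May be empty.
#' @param initial_volume_mL Starting culture volume (mL), positive.
#' @param mode `"increment"` (default) or `"stock"`.
#' @return A list with class `feed_schedule`.
#' @export
feed_schedule <- function(feed_events = NULL, sample_events = NULL,
                          initial_volume_mL = 70, mode = c("increment", "stock")) {
  mode <- match.arg(mode)
  empty_feed <- tibble::tibble(time_h = numeric(), species = character(),
                               dose_mM = numeric())
  empty_samp <- tibble::tibble(time_h = numeric(), volume_mL_removed = numeric())
  fe <- if (is.null(feed_events)) empty_feed else
    dplyr::arrange(tibble::as_tibble(feed_events), .data$time_h)
  se <- if (is.null(sample_events)) empty_samp else
    dplyr::arrange(tibble::as_tibble(sample_events), .data$time_h)
  if (initial_volume_mL <= 0) stop("initial volume must be positive", call. = FALSE)
  if (nrow(fe) > 0 && any(fe$dose_mM < 0)) {
    stop("feed doses must be non-negative", call. = FALSE)
  }
  structure(list(feed_events = fe, sample_events = se,
                 initial_volume_mL = initial_volume_mL, mode = mode),
            class = "feed_schedule")
}

#' Apply a bolus feed event to a model state
#'
#' @param state Named state vector.
#' @param species State name of the fed species (e.g. `"GAL"`).
#' @param dose_mM Concentration increment (increment mode).
#' @param mode `"increment"` or `"stock"`.
#' @param conc_mM,volume_mL Stock concentration and volume (stock mode).
#' @return Updated state vector.
#' @examples
#' s <- initial_state(GAL = 0.5)
#' apply_feed_event(s, "GAL", 25)[["GAL"]] # 25.5
#' @export
apply_feed_event <- function(state, species, dose_mM, mode = "increment",
                             conc_mM = NULL, volume_mL = NULL) {
  if (!species %in% names(state)) {
    stop("unknown fed species: ", species, call. = FALSE)
  }
  if (mode == "increment") {
    state[[species]] <- state[[species]] + dose_mM
  } else {
    v <- state[["V"]]
    vf <- volume_mL
    if (is.null(vf) || is.null(conc_mM)) {
      stop("stock mode needs conc_mM and volume_mL", call. = FALSE)
    }
    # dilute every dissolved species, add the fed one, then grow the volume
    dissolved <- setdiff(names(state), c("V"))
    for (nm in dissolved) state[[nm]] <- state[[nm]] * v / (v + vf)
    state[[species]] <- state[[species]] + conc_mM * vf / (v + vf)
    state[["V"]] <- v + vf
  }
  state
}

#' Apply a sampling event (volume removal) to a model state
#'
#' Removes culture volume; all intensive quantities (concentrations, VCD,
#' glycoform masses per litre) are unchanged.
#'
#' @param state Named state vector.
#' @param volume_mL_removed Volume removed (mL), less than the current volume.
#' @return Updated state vector.
#' @export
apply_sample_event <- function(state, volume_mL_removed) {
  if (volume_mL_removed >= state[["V"]]) {
    stop("sampling would remove the whole culture volume", call. = FALSE)
  }
  state[["V"]] <- state[["V"]] - volume_mL_removed
  state
}

#' Simulate a fed-batch culture
#'
#' Integrates [fedbatch_rhs()] between scheduled events with a stiff-capable
#' adaptive solver (`deSolve::lsoda`), applying feed and sampling events
#' instantaneously at their scheduled times (sampling first, then feeding,
#' when both fall on the same time). States reported at an event time are
#' post-event. Output states are clipped at zero (the smooth consumption
#' gates keep any undershoot at integrator-tolerance scale).
#'
#' @param p A [kinetic_params()] object.
#' @param init Named state vector from [initial_state()]. Its `V` is
#'   overridden by the schedule's initial volume.
#' @param schedule A [feed_schedule()].
#' @param t_eval Strictly increasing time grid (h) spanning all event times.
#' @param rtol,atol Solver tolerances.
#' @param maxsteps Maximum internal solver steps per output interval.
#' @return A `fedbatch_trajectory` tibble: `time_h`, one column per state,
#'   plus derived `G0F`, `G1F`, `G2F` percent fractions.
#' @export
simulate_fedbatch <- function(p, init = initial_state(),
                              schedule = feed_schedule(), t_eval,
                              rtol = 1e-8, atol = 1e-10, maxsteps = 50000) {
  t_eval <- sort(unique(t_eval))
  if (length(t_eval) < 2) stop("t_eval needs at least two times", call. = FALSE)
  canon <- names(initial_state())
  stopifnot(setequal(names(init), canon))
  init <- init[canon] # fedbatch_rhs indexes the state positionally
  init[["V"]] <- schedule$initial_volume_mL
  ev_times <- sort(unique(c(schedule$feed_events$time_h,
                            schedule$sample_events$time_h)))
  ev_times <- ev_times[ev_times > min(t_eval) & ev_times <= max(t_eval)]
  if (length(ev_times) > 0 && !all(ev_times %in% t_eval)) {
    stop("t_eval must contain every feed/sample event time", call. = FALSE)
  }
  breaks <- sort(unique(c(min(t_eval), ev_times, max(t_eval))))

  rhs_desolve <- function(t, y, parms) fedbatch_rhs(t, y, parms)
  state <- init
  rows <- list()
  record <- function(t, s) {
    rows[[length(rows) + 1]] <<- c(time_h = t, s)
  }
  record(breaks[1], state)

  for (k in seq_len(length(breaks) - 1)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1]
    seg_times <- sort(unique(c(t0, t_eval[t_eval > t0 & t_eval <= t1], t1)))
    sol <- deSolve::lsoda(y = state, times = seg_times, func = rhs_desolve,
                          parms = p, rtol = rtol, atol = atol,
                          maxsteps = maxsteps)
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE integration failed near t = ",
           signif(sol[nrow(sol), "time"], 6), " h", call. = FALSE)
    }
    for (i in seq(2, nrow(sol))) {
      s_i <- pmax(sol[i, -1], 0)
      if (sol[i, "time"] < t1 || !(t1 %in% ev_times)) {
        record(sol[i, "time"], s_i)
      }
    }
    state <- pmax(sol[nrow(sol), -1], 0)
    if (t1 %in% ev_times) {
      samp <- schedule$sample_events[schedule$sample_events$time_h == t1, ]
      for (i in seq_len(nrow(samp))) {
        state <- apply_sample_event(state, samp$volume_mL_removed[i])
      }
      feeds <- schedule$feed_events[schedule$feed_events$time_h == t1, ]
      for (i in seq_len(nrow(feeds))) {
        state <- apply_feed_event(
          state, feeds$species[i], feeds$dose_mM[i], mode = schedule$mode,
          conc_mM = feeds$conc_mM[i], volume_mL = feeds$volume_mL[i]
        )
      }
      record(t1, state)
    }
  }

  traj <- tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
  traj <- traj[traj$time_h %in% t_eval, , drop = FALSE]
  m_tot <- traj$M_G0F + traj$M_G1F + traj$M_G2F
  traj$G0F <- 100 * traj$M_G0F / m_tot
  traj$G1F <- 100 * traj$M_G1F / m_tot
  traj$G2F <- 100 * traj$M_G2F / m_tot
  structure(traj, class = c("fedbatch_trajectory", class(traj)),
            params = p, schedule = schedule)
}

#' Convert a simulated trajectory to a long culture table
#'
#' Maps state columns to measurement channels (`Xv` -> `VCD`, `mAb` ->
#' `TITER`, NSD pools to `UDP_*`, derived glycan percentages to
#' `G0F`/`G1F`/`G2F`) so simulated output can flow through the same tooling
#' as observed data.
#'
#' @param traj A `fedbatch_trajectory`.
#' @param batch_id,condition,replicate Identifiers for the output rows.
#' @return A culture-table tibble.
#' @export
trajectory_to_culture_table <- function(traj, batch_id = "sim",
                                        condition = "Control", replicate = 1L) {
  map <- c(VCD = "Xv", TITER = "mAb",
           GLC = "GLC", GLN = "GLN", GLU = "GLU", LAC = "LAC",
           NH4 = "NH4", GAL = "GAL",
           UDP_GLC = "UDP_Glc", UDP_GAL = "UDP_Gal",
           UDP_GLCNAC = "UDP_GlcNAc", UDP_GALNAC = "UDP_GalNAc",
           G0F = "G0F", G1F = "G1F", G2F = "G2F")
  purrr::imap_dfr(map, function(col, chan) {
    tibble::tibble(
      batch_id = batch_id, condition = condition,
      replicate = as.integer(replicate),
      time_h = traj$time_h, channel = chan, value = traj[[col]]
    )
  }) |>
    dplyr::arrange(.data$time_h, .data$channel)
}

#' @describeIn simulate_fedbatch Plot the main trajectory variables.
#' @param object A `fedbatch_trajectory`.
#' @param vars State/derived columns to plot.
#' @param ... Unused.
#' @export
autoplot.fedbatch_trajectory <- function(object, vars = c("Xv", "mAb", "GLC",
                                                          "GAL", "UDP_Gal",
                                                          "G0F", "G1F", "G2F"),
                                         ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select(dplyr::all_of(c("time_h", vars))) |>
    tidyr::pivot_longer(-"time_h", names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL)
}
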