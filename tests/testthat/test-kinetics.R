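test_that("elementary rate laws match their closed forms", {
  p <- kinetic_params(mu_max = 0.04, K_glc = 1)
  expect_equal(monod_mu(1, p), 0.02)   # half saturation
  expect_equal(monod_mu(0, p), 0)
  expect_equal(monod_mu(9, p), 0.036)
  expect_true(monod_mu(1e6, p) <= p$mu_max)

  expect_equal(mm_uni(0.5, 2, 0.5), 1)     # S = Km -> Vmax/2
  expect_equal(mm_uni(0, 2, 0.5), 0)
  expect_equal(mm_uni(1.5, 2, 0.5), 1.5)

  expect_equal(mm_bi_ternary(0, 3, 4, 1, 1), 0)
  expect_equal(mm_bi_ternary(1, 2, 4, 1, 2), 1) # both at half saturation
  expect_equal(mm_bi_ternary(1, 1, 4, 1, 1), 1)
  # symmetry under (S1,K1) <-> (S2,K2) exchange
  for (seed in 1:10) {
    v <- withr::with_seed(seed, stats::runif(5, 0.1, 5))
    expect_equal(mm_bi_ternary(v[1], v[2], v[3], v[4], v[5]),
                 mm_bi_ternary(v[2], v[1], v[3], v[5], v[4]))
  }
})

test_that("glycan maturation closed form covers limits and degenerate case", {
  p <- kinetic_params()
  expect_equal(unname(glycan_instantaneous_fractions(0, p)), c(1, 0, 0))

  # saturating donor with huge rates: everything matures to G2F
  p_hi <- kinetic_params(k_gal1 = 1e4, k_gal2 = 1e4, K_gal1 = 1e-6,
                         K_gal2 = 1e-6, tau_G = 10)
  phi <- glycan_instantaneous_fractions(5, p_hi)
  expect_equal(unname(phi), c(0, 0, 1), tolerance = 1e-10)

  # kappa1*tau = kappa2*tau = 1 analytic limit
  p_eq <- kinetic_params(k_gal1 = 2, k_gal2 = 2, K_gal1 = 1, K_gal2 = 1,
                         tau_G = 1)
  phi_eq <- glycan_instantaneous_fractions(1, p_eq) # kappa = 2*1/(1+1) = 1
  expect_equal(unname(phi_eq), c(exp(-1), exp(-1), 1 - 2 * exp(-1)),
               tolerance = 1e-12)

  # simplex membership over a donor grid
  for (u in c(0, 0.01, 0.1, 0.5, 1, 5, 50)) {
    f <- glycan_instantaneous_fractions(u, p)
    expect_true(all(f >= 0 & f <= 1))
    expect_equal(sum(f), 1, tolerance = 1e-12)
  }
})

test_that("RHS honors zero-biomass and mass-closure identities", {
  p <- kinetic_params()
  s0 <- initial_state(Xv = 0)
  d <- fedbatch_rhs(0, s0, p)[[1]]
  names(d) <- names(s0)
  # cell-driven derivatives vanish without biomass
  for (nm in c("Xv", "GLC", "GAL", "LAC", "mAb", "M_G0F", "M_G1F", "M_G2F")) {
    expect_equal(d[[nm]], 0)
  }
  # glycoform mass split always sums to the production rate exactly
  for (seed in 1:10) {
    s <- withr::with_seed(seed, {
      st <- initial_state()
      st["UDP_Gal"] <- stats::runif(1, 0, 2)
      st["Xv"] <- stats::runif(1, 1e5, 1e7)
      st
    })
    dv <- fedbatch_rhs(0, s, p)[[1]]
    names(dv) <- names(s)
    expect_equal(dv[["M_G0F"]] + dv[["M_G1F"]] + dv[["M_G2F"]], dv[["mAb"]])
  }
  expect_error(fedbatch_rhs(0, replace(s0, "GLC", NaN), p), "non-finite")
})

test_that("extracellular subsystem matches an independent RK4 oracle", {
  # all transport/NSD machinery off: pure Monod batch with production
  p <- kinetic_params(Vt_glc = 0, Vt_gln = 0, Vt_gal = 0, V_gal = 0,
                      Vmax_udpglc = 0, Vmax_epim = 0, Vmax_salv = 0,
                      Vmax_udpglcnac = 0, Vmax_udpgalnac = 0,
                      f_udpglc = 0, f_udpgal = 0, f_udpglcnac = 0,
                      f_udpgalnac = 0)
  sched <- feed_schedule(initial_volume_mL = 70)
  t_rec <- seq(0, 48, by = 12)
  traj <- simulate_fedbatch(p, schedule = sched, t_eval = t_rec)
  oracle <- rk4_fedbatch(p, initial_state(), sched, t_end = 48, dt = 0.01,
                         t_record = t_rec)
  for (col in c("Xv", "GLC", "GLN", "LAC", "mAb")) {
    expect_equal(traj[[col]], oracle[[col]], tolerance = 1e-6)
  }
})

test_that("full default simulation matches fixed-step RK4 within 1e-5", {
  p <- kinetic_params()
  sched <- feed_schedule(
    tibble::tibble(time_h = 72, species = "GAL", dose_mM = 25),
    initial_volume_mL = 70
  )
  t_rec <- seq(0, 96, by = 24)
  traj <- simulate_fedbatch(p, schedule = sched, t_eval = t_rec)
  oracle <- rk4_fedbatch(p, initial_state(), sched, t_end = 96, dt = 0.01,
                         t_record = t_rec)
  for (col in c("Xv", "GLC", "GAL", "mAb", "UDP_Gal", "UDP_GlcNAc",
                "M_G0F", "M_G1F", "M_G2F")) {
    expect_equal(traj[[col]], oracle[[col]], tolerance = 1e-5)
  }
})

test_that("feed events implement increment and stock-mixing semantics", {
  s <- initial_state(GAL = 0.5)
  expect_equal(apply_feed_event(s, "GAL", 25)[["GAL"]], 25.5)
  expect_equal(apply_feed_event(s, "GAL", 0), s)
  expect_error(apply_feed_event(s, "XYZ", 1), "unknown fed species")

  # stock mode, equal concentrations: concentrations fixed, volume doubles
  s2 <- apply_feed_event(s, "GAL", dose_mM = 0, mode = "stock",
                         conc_mM = s[["GAL"]], volume_mL = s[["V"]])
  expect_equal(s2[["GAL"]], s[["GAL"]])
  expect_equal(s2[["GLC"]], s[["GLC"]] / 2) # other species diluted
  expect_equal(s2[["V"]], 2 * s[["V"]])
})

test_that("sampling removes volume but no intensive quantity", {
  s <- initial_state()
  expect_equal(apply_sample_event(s, 0), s)
  half <- apply_sample_event(s, s[["V"]] / 2)
  expect_equal(half[["V"]], s[["V"]] / 2)
  expect_equal(half[["GLC"]], s[["GLC"]])
  expect_equal(half[["Xv"]], s[["Xv"]])
  expect_error(apply_sample_event(s, s[["V"]]), "whole culture volume")
  # composition: sequence of removals equals one removal of the total
  seq_state <- apply_sample_event(apply_sample_event(s, 10), 15)
  expect_equal(seq_state, apply_sample_event(s, 25))
})

test_that("simulation respects conservation, events and restartability", {
  p <- kinetic_params()
  sched <- condition_feed_schedule(default_design()[2, ]) # A: feed at 72 h
  t_eval <- seq(0, 216, by = 12)
  traj <- simulate_fedbatch(p, schedule = sched, t_eval = t_eval)

  # zero-rate parameters freeze the trajectory
  p0names <- setdiff(names(kinetic_params()),
                     c("K_glc", "K_gal", "Ki_glc_gal", "Kt_glc", "Kt_gln",
                       "Kt_gal", "Km_udpglc", "Km_epim", "Km_salv",
                       "Km_udpglcnac", "Km2_udpglcnac", "Km_udpgalnac",
                       "K_gal1", "K_gal2", "tau_G",
                       # yields multiply already-zero fluxes and Y_xglc
                       # divides the growth demand: they stay positive
                       "Y_xglc", "Y_lac", "Y_nh4", "Y_glu"))
  frozen <- do.call(kinetic_params,
                    as.list(stats::setNames(rep(0, length(p0names)), p0names)))
  const <- simulate_fedbatch(frozen, schedule = feed_schedule(),
                             t_eval = c(0, 24, 48))
  expect_equal(const$GLC, rep(initial_state()[["GLC"]], 3))
  expect_equal(const$Xv, rep(initial_state()[["Xv"]], 3))

  # non-negativity and glycan closure at every output time
  states <- as.matrix(tibble::as_tibble(traj)[, names(initial_state())])
  expect_true(all(states >= 0))
  expect_equal(traj$G0F + traj$G1F + traj$G2F, rep(100, nrow(traj)),
               tolerance = 1e-9)
  expect_equal(traj$M_G0F + traj$M_G1F + traj$M_G2F, traj$mAb,
               tolerance = 1e-8)

  # restart equivalence: [0,T] equals [0,t1] then [t1,T] from the saved state
  t1 <- 96
  first <- simulate_fedbatch(p, schedule = sched, t_eval = seq(0, t1, by = 12))
  saved <- unlist(first[nrow(first), names(initial_state())])
  sched2 <- sched
  sched2$feed_events <- sched$feed_events[sched$feed_events$time_h > t1, ]
  sched2$sample_events <- sched$sample_events[sched$sample_events$time_h > t1, ]
  sched2$initial_volume_mL <- saved[["V"]]
  second <- simulate_fedbatch(p, init = saved, schedule = sched2,
                              t_eval = seq(t1, 216, by = 12))
  joint <- traj[traj$time_h >= t1, ]
  expect_equal(second$Xv, joint$Xv, tolerance = 1e-6)
  expect_equal(second$UDP_Gal, joint$UDP_Gal, tolerance = 1e-6)
})

test_that("larger galactose boluses never reduce cumulative UDP-Gal supply", {
  p <- kinetic_params()
  t_eval <- seq(0, 168, by = 6)
  auc <- vapply(c(0, 10, 25, 50), function(dose) {
    sched <- feed_schedule(
      tibble::tibble(time_h = 72, species = "GAL", dose_mM = dose),
      initial_volume_mL = 70
    )
    traj <- simulate_fedbatch(p, schedule = sched, t_eval = t_eval)
    # cumulative salvage + epimerase flux into UDP-Gal (trapezoid)
    v <- mm_uni(traj$Gal_in, p$Vmax_salv, p$Km_salv) +
      mm_uni(traj$UDP_Glc, p$Vmax_epim, p$Km_epim)
    sum(diff(t_eval) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  }, numeric(1))
  expect_true(all(diff(auc) >= -1e-9))
})

test_that("trajectories convert to culture tables on the standard channels", {
  p <- kinetic_params()
  traj <- simulate_fedbatch(p, schedule = feed_schedule(),
                            t_eval = c(0, 24, 48))
  tbl <- trajectory_to_culture_table(traj, batch_id = "sim1")
  expect_setequal(unique(tbl$channel), culture_channels()$channel)
  expect_equal(nrow(tbl), 3 * 15)
  expect_equal(tbl$value[tbl$channel == "VCD"], traj$Xv)
  expect_equal(tbl$value[tbl$channel == "G0F"], traj$G0F)
})
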