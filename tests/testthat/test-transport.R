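test_that("accumulation factors reproduce the published values", {
  expect_equal(signif(accumulation_factor_active(-150, 310), 3), 275)
  expect_equal(signif(accumulation_factor_active(-150, 303), 3), 313)
  expect_equal(signif(accumulation_factor_passive(7.0, 7.6), 2), 0.25)
  expect_equal(signif(accumulation_factor_passive(7.4, 7.6), 2), 0.63)
  # closed forms
  expect_equal(accumulation_factor_active(-150, 310),
               exp(96485 * 0.150 / (8.314 * 310)))
  expect_equal(accumulation_factor_passive(7.0, 7.6), 10^-0.6)
  expect_error(accumulation_factor_active(-150, -1), "temperature")
})

test_that("accumulation_factor dispatches on the physics mode", {
  pa <- transport_physics("active", delta_psi = -150, temperature = 310)
  pp <- transport_physics("passive", ph_ext = 7.0, ph_int = 7.6)
  expect_equal(accumulation_factor(pa), accumulation_factor_active(-150, 310))
  expect_equal(accumulation_factor(pp), accumulation_factor_passive(7.0, 7.6))
  # hyperpolarization increases active accumulation
  expect_true(accumulation_factor_active(-180, 310) >
                accumulation_factor_active(-150, 310))
})

test_that("speciation follows Henderson-Hasselbalch and conserves mass", {
  s <- speciate(c(0, 0.1, 10), ph = 7.0, pka = 9.25)
  expect_equal(s$nh4 + s$nh3, c(0, 0.1, 10))
  expect_equal(s$nh3[2:3] / s$nh4[2:3], rep(10^(7.0 - 9.25), 2),
               tolerance = 1e-12)
  # almost everything is NH4+ at pH well below the pKa
  expect_true(s$nh4[2] / 0.1 > 0.99)
  expect_error(speciate(-1, 7), "non-negative")
})

test_that("toy_rhs matches a term-by-term hand-evaluated oracle", {
  p <- fixture_params()
  cond <- fixture_condition(nhx_ext = 0.1)
  st <- fixture_state()
  r <- toy_rhs(st, p, cond)

  # independent arithmetic
  re <- 10^(7.0 - 9.25); ri <- 10^(7.6 - 9.25)
  nh4e <- 0.1 / (1 + re); nh3e <- 0.1 - nh4e
  nh4i <- st[["nhx"]] / (1 + ri); nh3i <- st[["nhx"]] - nh4i
  phi <- exp(96485 * 0.150 / (8.314 * 310))
  theta <- nh4i^2 / (0.02^2 + nh4i^2)
  v_amtb <- 150 * (1 - theta) * nh4e / (0.01 + nh4e) * (1 - nh4i / (phi * nh4e))
  v_diff <- 50 * (nh3e - nh3i)
  v_gs <- 5 * nh4i / (0.02 + nh4i)
  v_growth <- 4 * 5 / (1 + 5)
  mu <- log(2) / 60 * 5 / (1 + 5)

  expect_equal(unname(r$fluxes["v_amtb"]), v_amtb, tolerance = 1e-12)
  expect_equal(unname(r$fluxes["v_diff"]), v_diff, tolerance = 1e-12)
  expect_equal(unname(r$fluxes["v_gs"]), v_gs, tolerance = 1e-12)
  expect_equal(unname(r$fluxes["v_growth"]), v_growth, tolerance = 1e-12)
  expect_equal(unname(r$fluxes["growth_rate"]), mu, tolerance = 1e-12)
  expect_equal(unname(r$fluxes["theta_glnk"]), theta, tolerance = 1e-12)
  expect_equal(unname(r$derivatives["nhx"]), v_amtb + v_diff - v_gs,
               tolerance = 1e-12)
  expect_equal(unname(r$derivatives["gln"]), v_gs - v_growth - 0.05 * 5,
               tolerance = 1e-12)
  expect_equal(unname(r$derivatives["glu"]), v_growth - 0.05 * 50,
               tolerance = 1e-12)
  expect_error(toy_rhs(c(nhx = -1, gln = 1, glu = 1), p, cond), "non-negative")
})

test_that("passive-mode AmtB flux is driven by the NH3 gradient", {
  p <- fixture_params()
  cond <- fixture_condition(nhx_ext = 0.1, mode = "passive")
  st <- fixture_state()
  r <- toy_rhs(st, p, cond)
  re <- 10^(7.0 - 9.25); ri <- 10^(7.6 - 9.25)
  nh3e <- 0.1 * re / (1 + re)
  nh4i <- st[["nhx"]] / (1 + ri); nh3i <- st[["nhx"]] - nh4i
  theta <- nh4i^2 / (0.02^2 + nh4i^2)
  expect_equal(unname(r$fluxes["v_amtb"]),
               150 * (1 - theta) * nh3e / (0.01 + nh3e) * (1 - nh3i / nh3e),
               tolerance = 1e-12)
})

test_that("active AmtB flux vanishes exactly at transporter equilibrium", {
  p <- fixture_params()
  cond <- fixture_condition(nhx_ext = 0.1)
  phi <- accumulation_factor(cond$physics)
  re <- 10^(7.0 - 9.25); ri <- 10^(7.6 - 9.25)
  nh4e <- 0.1 / (1 + re)
  nhx_eq <- phi * nh4e * (1 + ri)  # internal total giving nh4_int = phi*nh4_ext
  r <- toy_rhs(c(nhx = nhx_eq, gln = 1, glu = 1), p, cond)
  expect_equal(unname(r$fluxes["v_amtb"]), 0, tolerance = 1e-12)
})

test_that("compiled and plain-R integration paths agree", {
  p <- fixture_params()
  cond <- fixture_condition(nhx_ext = 0.1)
  tc <- simulate_toy(p, cond, times = c(0, 1, 5, 20), compiled = TRUE)
  tr <- simulate_toy(p, cond, times = c(0, 1, 5, 20), compiled = FALSE)
  for (v in c("nhx", "gln", "glu", "v_amtb", "v_gs"))
    expect_equal(tc[[v]], tr[[v]], tolerance = 1e-6)
})

test_that("steady state agrees with a long-time simulation endpoint", {
  p <- fixture_params()
  cond <- fixture_condition(nhx_ext = 0.1)
  ss <- steady_state_toy(p, cond)
  long <- simulate_toy(p, cond, times = c(0, 5000))
  endpoint <- unlist(long[nrow(long), c("nhx", "gln", "glu")])
  expect_equal(unname(ss$state), unname(endpoint), tolerance = 1e-6)
  # at steady state the membrane net flux equals assimilation
  expect_equal(ss$fluxes[["v_net"]],
               ss$fluxes[["v_amtb"]] + ss$fluxes[["v_diff"]], tolerance = 1e-12)
  expect_equal(ss$fluxes[["v_net"]], ss$fluxes[["v_gs"]], tolerance = 1e-4)
})

test_that("halving solver tolerances moves endpoints by far less than 0.1%", {
  p <- fixture_params()
  cond <- fixture_condition(nhx_ext = 0.1)
  a <- simulate_toy(p, cond, times = c(0, 20), rtol = 1e-8, atol = 1e-10)
  b <- simulate_toy(p, cond, times = c(0, 20), rtol = 5e-9, atol = 5e-11)
  rel <- abs(unlist(a[2, c("nhx", "gln", "glu")]) /
               unlist(b[2, c("nhx", "gln", "glu")]) - 1)
  expect_true(all(rel < 1e-3))
})

test_that("GlnK removal unleashes AmtB and a futile cycle", {
  p <- fixture_params()
  cond <- fixture_condition(nhx_ext = 0.1)
  wt <- steady_state_toy(p, cond)
  ko <- steady_state_toy(glnk_knockout(p), cond)
  # wild type throttles AmtB; knockout transports at full force
  expect_true(ko$fluxes[["v_amtb"]] > 5 * wt$fluxes[["v_amtb"]])
  expect_true(wt$fluxes[["theta_glnk"]] > 0.5)
  expect_identical(ko$fluxes[["theta_glnk"]], 0)
  # knockout accumulates more ammonium and back-diffuses NH3 outward
  expect_true(ko$fluxes[["nh4_int"]] > 10 * wt$fluxes[["nh4_int"]])
  expect_true(ko$fluxes[["v_diff"]] < 0)
  expect_true(-ko$fluxes[["v_diff"]] > 100 * -wt$fluxes[["v_diff"]])
  # most of the knockout's uptake is immediately wasted; almost none in wt
  expect_true(-ko$fluxes[["v_diff"]] / ko$fluxes[["v_amtb"]] > 0.5)
  expect_true(-wt$fluxes[["v_diff"]] / wt$fluxes[["v_amtb"]] < 0.1)
  atp <- futile_cycle_atp_equivalent(-ko$fluxes[["v_diff"]])
  expect_true(atp > 0)
})

test_that("glnk_knockout is idempotent and leaves the input untouched", {
  p <- fixture_params()
  k1 <- glnk_knockout(p)
  k2 <- glnk_knockout(k1)
  expect_true(p$glnk_present)
  expect_false(k1$glnk_present)
  expect_identical(k1, k2)
  expect_identical(k1[names(k1) != "glnk_present"],
                   p[names(p) != "glnk_present"])
})

test_that("a knockout condition simulates as the mutant", {
  p <- fixture_params()
  cond_ko <- fixture_condition(nhx_ext = 0.1, glnk_present = FALSE)
  via_cond <- steady_state_toy(p, cond_ko)
  via_params <- steady_state_toy(glnk_knockout(p), fixture_condition(0.1))
  expect_equal(via_cond$state, via_params$state, tolerance = 1e-9)
})

test_that("active steady state stays strictly below the equilibrium ratio", {
  p <- fixture_params()
  for (ext in c(0.004, 0.05, 0.1)) {
    cond <- fixture_condition(nhx_ext = ext)
    phi <- accumulation_factor(cond$physics)
    ss <- steady_state_toy(p, cond)
    nh4_ext <- speciate(ext, 7.0)$nh4
    expect_true(ss$fluxes[["nh4_int"]] < phi * nh4_ext)
  }
})

test_that("futile-cycle energetics reproduce the published scale", {
  expect_equal(futile_cycle_atp_equivalent(1300), 1300 / 3)
  expect_true(futile_cycle_atp_equivalent(1300) >= 400)
  expect_true(futile_cycle_atp_equivalent(1300) / 500 >= 0.8)
  expect_error(futile_cycle_atp_equivalent(-1), ">= 0")
  expect_error(futile_cycle_atp_equivalent(1, h_per_atp = 0), "positive")
})

test_that("step inputs change the external ammonium at the step time", {
  steps <- rbind(c(0, 0.004), c(5, 0.1))
  cond <- fixture_condition(nhx_ext = steps)
  expect_equal(rubberband:::external_nhx_at(cond, 0), 0.004)
  expect_equal(rubberband:::external_nhx_at(cond, 4.99), 0.004)
  expect_equal(rubberband:::external_nhx_at(cond, 5), 0.1)
  p <- fixture_params()
  traj <- simulate_toy(p, cond, times = seq(0, 15, by = 0.5))
  nh4 <- traj$nh4_int
  before <- nh4[traj$time == 4.5]
  after <- nh4[traj$time == 10]
  expect_true(after > 1.5 * before)
  # after the step the trajectory approaches the high-ammonium steady state
  ss_high <- steady_state_toy(p, fixture_condition(nhx_ext = 0.1))
  expect_equal(after, ss_high$fluxes[["nh4_int"]], tolerance = 0.05)
})

test_that("condition construction validates its input", {
  phys <- transport_physics("active")
  expect_error(toy_condition("c", phys, -0.1), "non-negative")
  expect_error(toy_condition("c", phys, 0.1, initial_state = c(nhx = 1)),
               "initial_state")
  expect_error(toy_condition("c", phys, 0.1, tau0 = 0), "tau0")
  expect_error(toy_params(vmax_amtb = -1), "positive")
})
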