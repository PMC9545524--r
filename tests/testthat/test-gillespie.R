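test_that("cargo position is the force-balance point of the attached motors", {
  s <- pair_state(pos_k = 100, pos_d = 0)
  expect_equal(cargo_position(s, kin1, ddb), 50)
  # each motor then bears 0.2 * 50 = 10 pN
  expect_equal(abs(linkage_force(100, 50, 0.2)), 10)

  s1 <- pair_state(pos_k = 100, pos_d = 0, attached_d = FALSE)
  expect_equal(cargo_position(s1, kin1, ddb), 100)
  expect_equal(cargo_position(pair_state(), kin1, ddb), 0)
  expect_error(cargo_position(pair_state(attached_k = FALSE,
                                         attached_d = FALSE), kin1, ddb),
               "detached")
})

test_that("event rates compose the rate laws at the current linkage tension", {
  # both attached at the same position: zero force, unloaded rates
  r <- event_rates(pair_state(), kin1, ddb)
  expect_equal(unname(r), c(76.25, 3, 0.96, 0, 60, 5, 0.1, 0))

  # detached kinesin can only reattach
  r2 <- event_rates(pair_state(attached_k = FALSE), kin1, ddb)
  expect_equal(unname(r2[1:4]), c(0, 0, 0, 100))

  # 60 nm separation: each motor hindered by 6 pN; Kin1 is at stall,
  # its detach rate Bell-boosted by e^(6/6.8)
  r3 <- event_rates(pair_state(pos_k = 60, pos_d = 0), kin1, ddb)
  expect_equal(unname(r3["forward_k"]), 3)
  expect_equal(unname(r3["detach_k"]), 0.96 * exp(6 / 6.8))
  expect_equal(unname(r3["detach_d"]), 0.1)
})

test_that("draw_event samples the SSA distribution", {
  expect_error(draw_event(c(a = 0, b = 0)), "total rate")

  # single possible event is always drawn
  r <- c(forward_k = 0, back_k = 2.5, detach_k = 0, reattach_k = 0)
  set.seed(1)
  out <- replicate(50, draw_event(r)$event)
  expect_true(all(out == "back_k"))

  # two equal rates are drawn with frequency 1/2
  set.seed(2)
  out2 <- replicate(4000, draw_event(c(a = 1, b = 1))$event)
  expect_equal(mean(out2 == "a"), 0.5, tolerance = 0.05)

  # frozen pair-state rates: event frequencies follow the rate
  # proportions and waiting times the total-rate exponential
  rates <- c(76.25, 3, 0.96, 60, 5, 0.1)
  names(rates) <- paste0("e", seq_along(rates))
  set.seed(3)
  draws <- replicate(20000, unlist(draw_event(rates)), simplify = FALSE)
  evs <- vapply(draws, `[[`, "", "event")
  dts <- as.numeric(vapply(draws, `[[`, "", "dt"))
  counts <- table(factor(evs, levels = names(rates)))
  chi <- suppressWarnings(
    stats::chisq.test(counts, p = rates / sum(rates)))
  expect_gt(chi$p.value, 0.01)
  expect_equal(mean(dts), 1 / sum(rates), tolerance = 0.03)
})

test_that("SSA event stream matches a fine-timestep brute-force simulation", {
  # Independent oracle: discretise time at dt = 1e-5 s and fire one
  # reaction per step with probability rate_total * dt. Waiting times
  # are then geometric, which converges to the SSA exponential.
  rates <- c(5, 1, 0.5)
  total <- sum(rates)
  dt <- 1e-5
  set.seed(4)
  n_steps <- 6e6
  fire <- which(stats::runif(n_steps) < total * dt)
  types_bf <- sample.int(3, length(fire), replace = TRUE,
                         prob = rates / total)
  waits_bf <- diff(fire) * dt

  names(rates) <- c("a", "b", "c")
  set.seed(5)
  draws <- replicate(length(fire), draw_event(rates), simplify = FALSE)
  types_ssa <- vapply(draws, `[[`, "", "event")
  waits_ssa <- vapply(draws, function(d) d$dt, numeric(1))

  tab <- rbind(table(types_bf), table(factor(types_ssa, levels = names(rates))))
  expect_gt(suppressWarnings(stats::chisq.test(tab))$p.value, 0.01)
  expect_equal(mean(waits_ssa), mean(waits_bf), tolerance = 0.15)
  expect_equal(stats::sd(waits_ssa), stats::sd(waits_bf), tolerance = 0.2)
})

test_that("apply_event moves, detaches and reattaches correctly", {
  s <- pair_state()
  s1 <- apply_event(s, "forward_k", kin1, ddb, dt = 0.1)
  expect_equal(s1$pos_k, 8)
  expect_equal(s1$t, 0.1)
  # minus-end motor steps toward the minus end
  s2 <- apply_event(s, "forward_d", kin1, ddb)
  expect_equal(s2$pos_d, -8)
  expect_equal(apply_event(s, "back_k", kin1, ddb)$pos_k, -8)

  # kinesin detaches: cargo snaps to DDB
  s3 <- pair_state(pos_k = 100, pos_d = 0)
  s4 <- apply_event(s3, "detach_k", kin1, ddb)
  expect_false(s4$attached_k)
  expect_equal(cargo_position(s4, kin1, ddb), 0)
  # reattachment places the motor at the cargo
  s5 <- apply_event(s4, "reattach_k", kin1, ddb)
  expect_equal(s5$pos_k, 0)

  expect_error(apply_event(s4, "forward_k", kin1, ddb), "detached")
  expect_error(apply_event(s, "reattach_k", kin1, ddb), "attached")
})

test_that("compiled and reference engines produce identical trajectories", {
  for (seed in c(1, 7)) {
    a <- simulate_pair(kin1, ddb, t_max = 2, seed = seed, engine = "cpp")
    b <- simulate_pair(kin1, ddb, t_max = 2, seed = seed, engine = "R")
    expect_identical(a$events, b$events)
    expect_equal(a$times, b$times)
    expect_equal(a$cargo, b$cargo)
    expect_equal(a$pos_k, b$pos_k)
    expect_equal(a$pos_d, b$pos_d)
  }
})

test_that("trajectories respect the structural invariants", {
  tr <- simulate_pair(kin1, ddb, t_max = 20, seed = 11)
  expect_true(all(diff(tr$times) > 0))
  expect_lte(max(tr$times), 20)
  # every stepping event moves that motor by exactly one step size
  dk <- diff(tr$pos_k)
  step_ev <- which(tr$events %in% c("forward_k", "back_k")) - 1L
  expect_true(all(abs(dk[step_ev]) == 8))
  # while both motors are attached, spring forces are equal and opposite
  both <- tr$attached_k & tr$attached_d
  f_k <- 0.2 * (tr$cargo - tr$pos_k)[both]
  f_d <- 0.2 * (tr$cargo - tr$pos_d)[both]
  expect_equal(f_k, -f_d)
  # single-motor intervals have the cargo on the attached motor
  only_k <- tr$attached_k & !tr$attached_d
  expect_equal(tr$cargo[only_k], tr$pos_k[only_k])
})

test_that("ensembles are reproducible and respect the run protocol", {
  e1 <- simulate_ensemble(kin1, ddb, n_runs = 5, t_max = 3, seed = 99)
  e2 <- simulate_ensemble(kin1, ddb, n_runs = 5, t_max = 3, seed = 99)
  expect_equal(lapply(e1, `[[`, "times"), lapply(e2, `[[`, "times"))
  expect_equal(lapply(e1, `[[`, "cargo"), lapply(e2, `[[`, "cargo"))
  e3 <- simulate_ensemble(kin1, ddb, n_runs = 5, t_max = 3, seed = 100)
  expect_false(identical(lapply(e1, `[[`, "times"),
                         lapply(e3, `[[`, "times")))
  expect_length(e1, 5)
  # runs end at t_max or when both motors are detached
  for (tr in e1) {
    n <- length(tr$times)
    expect_true(tr$times[n] == 3 ||
                  (!tr$attached_k[n] && !tr$attached_d[n]))
  }
})

test_that("unloaded single motor recovers its closed-form velocity and run length", {
  # kinesin alone (DDB absent, no reattachment): biased walk with
  # exponential lifetime; E[v] = (kf0 - kb) * L, E[run] = v / kdetach0
  solo <- kin1
  solo$k_reattach <- 0
  ghost <- ddb
  ghost$k_reattach <- 0
  runs <- simulate_ensemble(solo, ghost, n_runs = 1000, t_max = 200,
                            seed = 123, attached = c(TRUE, FALSE),
                            FUN = function(tr) {
                              n <- length(tr$times)
                              c(x = tr$pos_k[n], t = tr$times[n])
                            })
  m <- do.call(rbind, runs)
  v_hat <- sum(m[, "x"]) / sum(m[, "t"])
  run_hat <- mean(m[, "x"])
  expect_equal(v_hat, (76.25 - 3) * 8, tolerance = 0.02)
  expect_equal(run_hat, 586 / 0.96, tolerance = 0.05)
})

test_that("a permanently engaged pair settles at the two-motor force balance", {
  # With detachment disabled for both motors, the pair crawls at the
  # velocity where the kinesin's load-dependent net stepping equals the
  # net backward slip of the super-stall-loaded DDB. For Kin1/DDB
  # parameters the balance force is F* = 6 * (1 - 40/586) = 5.59 pN,
  # where DDB's forward rate has floored at 0 so its net drift is
  # +k_back * L = +40 nm/s (hand algebra).
  k <- kin1
  k$k_detach0 <- 0
  d <- ddb
  d$k_detach0 <- 0
  trs <- simulate_ensemble(k, d, n_runs = 20, t_max = 50, seed = 17,
                           FUN = function(tr) {
                             n <- length(tr$times)
                             tr$cargo[n] / tr$times[n]
                           })
  expect_equal(mean(unlist(trs)), 40, tolerance = 0.2)
})
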