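test_that("cell-type parameter sets match the published table", {
  rs <- neuron_params("RS")
  expect_equal(c(rs$a, rs$b, rs$c, rs$d), c(0.02, 0.2, -65, 8))
  fs <- neuron_params("FS")
  expect_equal(c(fs$a, fs$b, fs$c, fs$d), c(0.1, 0.2, -65, 2))
  lts <- neuron_params("LTS")
  expect_equal(c(lts$a, lts$b, lts$c, lts$d), c(0.02, 0.25, -65, 2))
  expect_true(rs$excitatory)
  expect_false(fs$excitatory)
  expect_error(neuron_params("chattering"), "unknown cell_type")
})

test_that("the analytic resting state is a fixed point of the step map", {
  for (tp in c("RS", "FS", "LTS")) {
    p <- neuron_params(tp)
    st <- resting_state(p)
    state <- list(v = st$v, u = st$u)
    for (i in 1:1e4) {
      out <- izhikevich_step(state, p, I = 0, dt = 0.5)
      state <- out$state
      expect_false(out$spiked)
    }
    expect_equal(state$v, st$v, tolerance = 1e-12)
    expect_equal(state$u, st$u, tolerance = 1e-12)
  }
  # RS rests at exactly -70 mV, u = -14 (roots of 0.04 v^2 + 4.8 v + 140)
  rs <- resting_state(neuron_params("RS"))
  expect_equal(rs$v, -70)
  expect_equal(rs$u, -14)
})

test_that("threshold crossing sets the spike flag and applies the reset", {
  p <- neuron_params("RS")
  out <- izhikevich_step(list(v = 29.9, u = 0), p, I = 200, dt = 0.5)
  expect_true(out$spiked)
  expect_equal(out$state$v, -65)
  expect_gt(out$v_peak, 30)          # peak recorded before the reset
  expect_equal(out$state$u, 0 + p$a * (p$b * 29.9 - 0) * 0.5 + p$d)
  expect_error(izhikevich_step(list(v = 0, u = 0), p, I = NaN, dt = 0.5),
               "non-finite")
})

test_that("reset count equals recorded spike count in a driven run", {
  p <- neuron_params("RS")
  state <- list(v = -70, u = -14)
  nsp <- 0L; nreset <- 0L
  for (i in seq_len(4000)) {
    out <- izhikevich_step(state, p, I = 10, dt = 0.5)
    nsp <- nsp + as.integer(out$spiked)
    if (out$state$v == p$c && out$spiked) nreset <- nreset + 1L
    state <- out$state
  }
  expect_gt(nsp, 0)
  expect_identical(nsp, nreset)
})

test_that("tonic firing at dt = 0.5 ms matches a dt = 0.01 ms reference", {
  p <- neuron_params("RS")
  ref <- izh_reference_spikes(p$a, p$b, p$c, p$d, I = 6,
                              duration = 2000, dt = 0.01)
  state <- list(v = -65, u = p$b * -65)
  nsp <- 0L
  for (i in seq_len(4000)) {
    out <- izhikevich_step(state, p, I = 6, dt = 0.5)
    nsp <- nsp + as.integer(out$spiked)
    state <- out$state
  }
  expect_gt(ref, 20)
  expect_lt(abs(nsp - ref) / ref, 0.02)
})

test_that("FI curve is zero below rheobase and non-decreasing above", {
  p <- neuron_params("RS")
  expect_equal(rheobase(p), (5 - 0.2)^2 / 0.16 - 140)   # analytic: 4
  fi <- fi_curve(p, currents = c(0, 2, 3.9, 4.5, 6, 10, 15),
                 duration = 1000)
  expect_equal(fi$rate_hz[fi$current < rheobase(p)], c(0, 0, 0))
  expect_true(all(diff(fi$rate_hz) >= 0))
  expect_gt(fi$rate_hz[fi$current == 10], 0)
  expect_error(fi_curve(p, numeric(0)), "empty")
})

test_that("connectivity bounds, signs and exclusions hold on every seed", {
  b <- connectivity_bounds()
  expect_equal(unname(b["RS", "RS"]), 0.0375)
  expect_equal(unname(b["RS", "FS"]), -0.25)
  expect_equal(unname(b["LTS", "LTS"]), 0)
  for (seed in 1:10) {
    conn <- build_connectivity(c(RS = 30, FS = 8, LTS = 5), seed = seed)
    w <- conn$weights; tp <- conn$types
    expect_true(all(diag(w) == 0))
    expect_true(all(w[, tp == "RS"] >= 0))
    expect_true(all(w[, tp != "RS"] <= 0))
    for (pre in c("RS", "FS", "LTS")) for (post in c("RS", "FS", "LTS")) {
      blk <- w[tp == post, tp == pre]
      expect_true(all(abs(blk) <= abs(b[post, pre]) + 1e-12))
    }
    expect_true(all(w[tp == "LTS", tp == "LTS"] == 0))
  }
})

test_that("uniform weight draws fill the stated range per type pair", {
  conn <- build_connectivity(c(RS = 200, FS = 40, LTS = 10), seed = 42)
  rs_rs <- conn$weights[conn$types == "RS", conn$types == "RS"]
  rs_rs <- rs_rs[rs_rs != 0]
  expect_gt(max(rs_rs), 0.9 * 0.0375)
  expect_lt(min(rs_rs), 0.1 * 0.0375)
  fs_rs <- conn$weights[conn$types == "RS", conn$types == "FS"]
  expect_true(all(fs_rs >= -0.25 & fs_rs <= 0))
})

test_that("synaptic accumulators decay exactly exponentially", {
  conn <- build_connectivity(c(RS = 5, FS = 2, LTS = 1), seed = 1)
  n <- length(conn$types)
  syn <- list(psc_e = rep(1, n), psc_i = rep(-1, n))
  no_spikes <- rep(FALSE, n)
  cur <- syn
  for (k in 1:200) cur <- update_synaptic_currents(cur, no_spikes, conn, 0.5)
  expect_equal(cur$psc_e, rep(exp(-100 / 2.5), n), tolerance = 1e-12)
  expect_equal(cur$psc_i, rep(-exp(-100 / 6), n), tolerance = 1e-12)
  # one 0.5 ms step scales the excitatory accumulator by exp(-0.2)
  one <- update_synaptic_currents(syn, no_spikes, conn, 0.5)
  expect_equal(one$psc_e[1], exp(-0.2), tolerance = 1e-12)
  # value w read tau_e later equals w / e
  tau_later <- syn
  for (k in 1:5) tau_later <- update_synaptic_currents(tau_later, no_spikes,
                                                       conn, 0.5)
  expect_equal(tau_later$psc_e[1], exp(-1), tolerance = 1e-12)
  # zero stays zero
  z <- update_synaptic_currents(list(psc_e = rep(0, n), psc_i = rep(0, n)),
                                no_spikes, conn, 0.5)
  expect_true(all(z$psc_e == 0) && all(z$psc_i == 0))
  # a spike adds the source column to its targets
  spikes <- c(TRUE, rep(FALSE, n - 1))
  s <- update_synaptic_currents(list(psc_e = rep(0, n), psc_i = rep(0, n)),
                                spikes, conn, 0.5)
  expect_equal(s$psc_e, conn$weights[, 1])
})
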