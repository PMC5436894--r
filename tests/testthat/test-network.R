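test_that("identical seeds give bit-identical spike trains", {
  spec <- tiny_area_spec(n_rs = 80, n_fs = 15, n_lts = 5)
  r1 <- run_simulation(spec, alpha_config(), duration = 300, seed = 11)
  r2 <- run_simulation(spec, alpha_config(), duration = 300, seed = 11)
  expect_identical(r1$spikes, r2$spikes)
  r3 <- run_simulation(spec, alpha_config(), duration = 300, seed = 12)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("a drive-free network stays silent from rest", {
  nz <- default_noise(); nz[, "mu"] <- 0; nz[, "sd"] <- 0
  spec <- tiny_area_spec(n_rs = 40, n_fs = 8, n_lts = 4, noise = nz)
  r <- run_simulation(spec, NULL, duration = 200, seed = 3)
  expect_equal(nrow(r$spikes), 0)
})

test_that("the spike-time histogram counts every spike exactly once", {
  res <- fake_result(times = c(5.5, 5.5, 6.0, 120.5, 200.0),
                     neurons = c(1, 2, 3, 1, 2), area = 1, type = "RS",
                     duration = 200)
  sth <- compute_sth(res, 1, "RS")
  expect_length(sth, 200)
  expect_equal(sum(sth), 5)
  expect_equal(sth[6], 3)             # bin (5, 6] catches 5.5, 5.5, 6.0
  expect_equal(sth[200], 1)           # boundary spike stays in range
  expect_equal(sum(compute_sth(res, 2, "RS")), 0)
})

test_that("mean rate formula r = sum n_i / (N T)", {
  counts <- table(area = rep(1, 400), type = rep("RS", 400))
  res <- fake_result(times = runif(6000, 0, 2000),
                     neurons = sample(400, 6000, TRUE),
                     area = 1, type = "RS", duration = 2000,
                     counts = table(factor(rep(1, 400)),
                                    factor(rep("RS", 400))))
  dimnames(res$counts) <- list(area = "1", type = "RS")
  fr <- mean_firing_rates(res)
  expect_equal(fr$rate_hz, 7.5)
  res$spikes <- res$spikes[0, ]
  expect_equal(mean_firing_rates(res)$rate_hz, 0)
})

test_that("subpopulation wiring keeps feedforward channels disjoint", {
  spec <- network_spec(
    areas = list(area_spec(n_rs = 40, n_fs = 8, n_lts = 4, n_subpops = 2),
                 area_spec(n_rs = 40, n_fs = 8, n_lts = 4, n_subpops = 2)),
    subpop_wiring = TRUE, ff_prob = 0.5)
  net <- build_network(spec, seed = 2)
  ff <- net$ff[["1->2"]]
  for (src in names(ff)) {
    s <- as.integer(src)
    tg <- ff[[src]]
    rs_tg <- tg[net$type[tg] == "RS"]
    if (length(rs_tg))
      expect_true(all(net$subpop[rs_tg] == net$subpop[s]))
  }
})

test_that("projections originate from excitatory cells only", {
  spec <- network_spec(areas = list(
    area_spec(n_rs = 30, n_fs = 6, n_lts = 3),
    area_spec(n_rs = 30, n_fs = 6, n_lts = 3)))
  net <- build_network(spec, seed = 4)
  cross <- net$wt[net$area == 2, net$area == 1]
  from_i <- cross[, net$type[net$area == 1] != "RS"]
  expect_true(all(from_i == 0))
  expect_true(all(cross >= 0))        # RS source weights are excitatory
})

test_that("stimulus windows are honoured and validated", {
  spec <- tiny_area_spec(n_rs = 60, n_fs = 12, n_lts = 4)
  st <- stimulus_spec(area = 1, onset = 150, duration = 100, amplitude = 40)
  expect_error(run_simulation(spec, NULL, st, duration = 200, seed = 1),
               "past the end")
  r1 <- run_simulation(spec, NULL, st, duration = 300, seed = 5)
  r0 <- run_simulation(spec, NULL, NULL, duration = 300, seed = 5)
  resp <- stimulus_response(r1, r0, area = 1)
  expect_gt(resp, 5)                  # strong drive raises the rate
  # amplitude zero is indistinguishable from baseline
  st0 <- stimulus_spec(area = 1, onset = 150, duration = 100, amplitude = 0)
  rz <- run_simulation(spec, NULL, st0, duration = 300, seed = 5)
  expect_equal(stimulus_response(rz, r0, area = 1), 0)
  expect_error(stimulus_response(r0, r0), "no stimulus")
})

test_that("baseline rates and gamma peak sit in the physiological bands", {
  spec <- network_spec(areas = list(area_spec()), directionality = "none")
  res <- run_trials(spec, NULL, duration = 2000, n_trials = 2, seed = 9)
  fr <- do.call(rbind, lapply(res, mean_firing_rates))
  e <- mean(fr$rate_hz[fr$type == "RS"])
  i <- sum(fr$rate_hz[fr$type != "RS"] * fr$n_neurons[fr$type != "RS"]) /
    sum(fr$n_neurons[fr$type != "RS"])
  expect_gt(e, 5); expect_lt(e, 10)
  expect_gt(i, 25); expect_lt(i, 40)
  sth <- sapply(res, compute_sth, area = 1, types = "RS")
  pk <- band_metrics(multitaper_psd(sth), search = c(20, 80))$peak_freq
  expect_gt(pk, 30); expect_lt(pk, 50)
})
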