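# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantity they check.

# high-resolution reference integrator for a single Izhikevich neuron
izh_reference_spikes <- function(a, b, c, d, I, duration, dt = 0.01) {
  v <- -65; u <- b * v
  n <- round(duration / dt)
  nsp <- 0L
  for (i in seq_len(n)) {
    vn <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
    un <- u + dt * a * (b * v - u)
    if (vn >= 30) {
      nsp <- nsp + 1L
      vn <- c; un <- un + d
    }
    v <- vn; u <- un
  }
  nsp
}

# time-domain Granger causality from two nested OLS regressions
nested_gc <- function(x, y, p) {
  n <- length(x)
  idx <- (p + 1):n
  lag <- function(v, k) v[idx - k]
  xl <- sapply(seq_len(p), function(k) lag(x, k))
  yl <- sapply(seq_len(p), function(k) lag(y, k))
  full <- stats::lm.fit(cbind(1, xl, yl), x[idx])
  red <- stats::lm.fit(cbind(1, xl), x[idx])
  log(mean(red$residuals^2) / mean(full$residuals^2))
}

# quick two-channel VAR(1)/VAR(2) simulator independent of gen_var_process
sim_var2 <- function(a_list, sigma_chol, n, seed, burn = 200) {
  set.seed(seed)
  p <- length(a_list)
  nch <- nrow(a_list[[1]])
  tt <- n + burn
  e <- matrix(rnorm(tt * nch), tt, nch) %*% sigma_chol
  x <- matrix(0, tt, nch)
  for (i in (p + 1):tt) {
    acc <- e[i, ]
    for (k in seq_len(p)) acc <- acc + a_list[[k]] %*% x[i - k, ]
    x[i, ] <- acc
  }
  x[(burn + 1):tt, , drop = FALSE]
}

# small single-area spec reused by the simulation tests
tiny_area_spec <- function(...) {
  network_spec(areas = list(area_spec(...)), directionality = "none")
}

# fabricate a sim_result for analysis functions that only need spikes
fake_result <- function(times, neurons, area, type, duration,
                        subpop = 0L, counts = NULL, ff = NULL) {
  structure(list(
    spikes = data.frame(time = times, neuron = neurons, area = area,
                        type = type, subpop = subpop),
    duration = duration, dt = 0.5, counts = counts, ff = ff,
    stimulus = NULL, alpha = NULL, seed = 0),
    class = "sim_result")
}
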