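#' Fit a vector autoregressive model by multi-trial least squares
#'
#' Pools the regression over trials (each trial contributes rows p+1..T),
#' demeaning each trial and channel first. The order is selected by AIC up
#' to `max_order` unless `order` is given. The fit is rejected if the
#' companion matrix is unstable or the regressor matrix is numerically
#' singular (e.g. constant series). Residual whiteness is assessed by a
#' multivariate portmanteau test and reported as a diagnostic.
#'
#' @param x A T-by-nchannel matrix or a list of such matrices (trials).
#' @param max_order Maximum order scanned by AIC.
#' @param order Fixed order (skips selection).
#' @return List of class `var_model`: `A` (nch x nch x p coefficient
#'   array), `Sigma` (residual covariance), `order`, `nobs`, `aic`,
#'   `whiteness_p`, `stable`.
#' @export
fit_var <- function(x, max_order = 20, order = NULL) {
  trials <- if (is.list(x) && !is.data.frame(x)) x else list(x)
  trials <- lapply(trials, function(m) {
    m <- as.matrix(m)
    sweep(m, 2, colMeans(m))
  })
  nch <- ncol(trials[[1]])
  if (any(vapply(trials, ncol, integer(1)) != nch))
    stop("trials must share the channel count", call. = FALSE)
  sds <- vapply(trials, function(m) min(apply(m, 2, stats::sd)), numeric(1))
  if (any(sds == 0))
    stop("constant channel: singular covariance", call. = FALSE)

  design <- function(p) {
    ylist <- list(); xlist <- list()
    for (m in trials) {
      tt <- nrow(m)
      if (tt <= p) stop("trial shorter than the order", call. = FALSE)
      ylist[[length(ylist) + 1]] <- m[(p + 1):tt, , drop = FALSE]
      xl <- lapply(seq_len(p), function(k)
        m[(p + 1 - k):(tt - k), , drop = FALSE])
      xlist[[length(xlist) + 1]] <- do.call(cbind, xl)
    }
    list(y = do.call(rbind, ylist), x = do.call(rbind, xlist))
  }
  fit_p <- function(p) {
    d <- design(p)
    xtx <- crossprod(d$x)
    if (rcond(xtx) < 1e-12)
      stop("singular regressor matrix in VAR fit", call. = FALSE)
    beta <- solve(xtx, crossprod(d$x, d$y))   # (nch*p) x nch
    resid <- d$y - d$x %*% beta
    nobs <- nrow(d$y)
    sigma <- crossprod(resid) / (nobs - nch * p)
    ldet <- determinant(sigma, logarithm = TRUE)$modulus
    aic <- as.numeric(ldet) + 2 * (nch^2 * p) / nobs
    list(beta = beta, sigma = sigma, resid = resid, nobs = nobs, aic = aic)
  }
  if (is.null(order)) {
    aics <- rep(NA_real_, max_order)
    fits <- vector("list", max_order)
    for (p in seq_len(max_order)) {
      fits[[p]] <- fit_p(p)
      aics[p] <- fits[[p]]$aic
    }
    order <- which.min(aics)
    f <- fits[[order]]
  } else {
    f <- fit_p(order)
    aics <- f$aic
  }
  a <- array(0, c(nch, nch, order))
  for (k in seq_len(order))
    a[, , k] <- t(f$beta[((k - 1) * nch + 1):(k * nch), , drop = FALSE])
  # companion-matrix stability
  comp <- matrix(0, nch * order, nch * order)
  for (k in seq_len(order))
    comp[1:nch, ((k - 1) * nch + 1):(k * nch)] <- a[, , k]
  if (order > 1)
    comp[(nch + 1):(nch * order), 1:(nch * (order - 1))] <-
      diag(nch * (order - 1))
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("unstable VAR fit (spectral radius %.3f)", rho),
         call. = FALSE)
  # portmanteau whiteness diagnostic
  h <- min(20, max(10, 2 * order))
  r <- f$resid
  c0i <- solve(crossprod(r) / nrow(r))
  q <- 0
  for (l in seq_len(h)) {
    cl <- crossprod(r[-seq_len(l), , drop = FALSE],
                    r[seq_len(nrow(r) - l), , drop = FALSE]) / nrow(r)
    q <- q + sum(diag(t(cl) %*% c0i %*% cl %*% c0i))
  }
  q <- q * nrow(r)
  dfq <- nch^2 * max(1, h - order)
  white_p <- stats::pchisq(q, dfq, lower.tail = FALSE)
  structure(list(A = a, Sigma = f$sigma, order = order, nobs = f$nobs,
                 aic = aics, whiteness_p = white_p, stable = rho < 1,
                 spectral_radius = rho),
            class = "var_model")
}

# transfer function H(lambda) = inv(I - sum_k A_k e^{-i k lambda})
var_transfer <- function(model, lambda) {
  nch <- nrow(model$A[, , 1, drop = FALSE])
  acc <- diag(nch) + 0i
  for (k in seq_len(model$order))
    acc <- acc - model$A[, , k] * exp(-1i * k * lambda)
  solve(acc)
}

#' Frequency-resolved (spectral) Granger causality of a bivariate VAR
#'
#' Geweke's spectral measure: the log ratio of the total spectral density of
#' the target channel to its intrinsic part, after rotating the residuals so
#' the residual cross-covariance vanishes (which leaves the causality
#' invariant).
#'
#' @param model A bivariate `var_model`.
#' @param freqs Frequencies, Hz.
#' @param fs Sampling rate the model was fitted at, Hz.
#' @return List of class `gc_spectrum`: `freq`, `gc` matrix with columns
#'   `x_to_y` and `y_to_x` (channels 1 = x, 2 = y), `conditioning = "none"`.
#' @export
spectral_gc <- function(model, freqs, fs = 1000) {
  if (dim(model$A)[1] != 2)
    stop("spectral_gc expects a bivariate model", call. = FALSE)
  s <- model$Sigma
  if (rcond(s) < 1e-12) stop("singular residual covariance", call. = FALSE)
  one_dir <- function(ix, iy, h) {
    # causality from channel iy to channel ix
    g <- s[iy, ix] / s[ix, ix]
    hxx <- h[ix, ix] + g * h[ix, iy]
    hxy <- h[ix, iy]
    syy_c <- s[iy, iy] - s[iy, ix]^2 / s[ix, ix]
    sxx <- Mod(hxx)^2 * s[ix, ix] + Mod(hxy)^2 * syy_c
    log(sxx / (Mod(hxx)^2 * s[ix, ix]))
  }
  gc <- matrix(NA_real_, length(freqs), 2,
               dimnames = list(NULL, c("x_to_y", "y_to_x")))
  for (i in seq_along(freqs)) {
    h <- var_transfer(model, 2 * pi * freqs[i] / fs)
    gc[i, "y_to_x"] <- one_dir(1, 2, h)
    gc[i, "x_to_y"] <- one_dir(2, 1, h)
  }
  gc[gc < 0] <- 0   # clip tiny negative values from finite samples
  structure(list(freq = freqs, gc = gc, conditioning = "none",
                 order = model$order),
            class = "gc_spectrum")
}

# block transform making the residual covariance block-diagonal in the
# ordering given by idx blocks; returns P with P %*% sigma %*% t(P) block-diag
block_normalise <- function(sigma, blocks) {
  n <- nrow(sigma)
  p <- diag(n)
  s <- sigma
  for (b in seq_along(blocks)[-1]) {
    i <- blocks[[b]]
    for (a in seq_len(b - 1)) {
      j <- blocks[[a]]
      pb <- diag(n)
      pb[i, j] <- -s[i, j, drop = FALSE] %*% solve(s[j, j, drop = FALSE])
      p <- pb %*% p
      s <- pb %*% s %*% t(pb)
    }
  }
  list(P = p, Sigma = s)
}

#' Conditional spectral Granger causality
#'
#' Granger causality from y to x conditioned on z, via the dual-VAR
#' construction: a reduced model on (x, z) and a full model on (x, y, z) are
#' fitted, both residual covariances are block-normalised, and the causal
#' part of the target spectrum is isolated through
#' Q(lambda) = G(lambda)^{-1} H(lambda). With z independent of x and y this
#' reduces to the unconditional measure; a common driver z shared by x and y
#' is discounted.
#'
#' @param x,y,z Trials per channel: vectors, time-by-trial matrices or
#'   lists of equal-length vectors. `z` is the conditioning series (e.g.
#'   the common alpha drive).
#' @param freqs Frequencies, Hz.
#' @param fs Sampling rate, Hz.
#' @param order VAR order (NULL: AIC on the full model, reused for the
#'   reduced one).
#' @param max_order Cap for AIC selection.
#' @return `gc_spectrum` with columns `x_to_y`, `y_to_x`,
#'   `conditioning = "z"`.
#' @export
conditional_spectral_gc <- function(x, y, z, freqs, fs = 1000,
                                    order = NULL, max_order = 20) {
  xm <- as_trial_matrix(x); ym <- as_trial_matrix(y)
  zm <- as_trial_matrix(z)
  m <- ncol(xm)
  if (ncol(ym) != m || ncol(zm) != m)
    stop("x, y, z must have matching trial counts", call. = FALSE)
  if (stats::sd(as.vector(zm)) == 0 ||
      abs(stats::cor(as.vector(zm), as.vector(xm))) > 0.999 ||
      abs(stats::cor(as.vector(zm), as.vector(ym))) > 0.999)
    stop("z is degenerate or collinear with x or y", call. = FALSE)
  full_trials <- lapply(seq_len(m), function(i)
    cbind(xm[, i], ym[, i], zm[, i]))
  full <- fit_var(full_trials, max_order = max_order, order = order)
  p <- full$order
  one_dir <- function(ti, si) {
    # causality from source channel si to target ti, given z (channel 3)
    red_trials <- lapply(seq_len(m), function(i)
      cbind(full_trials[[i]][, ti], full_trials[[i]][, 3]))
    red <- fit_var(red_trials, order = p)
    # reorder full model channels to (target, source, z)
    ord <- c(ti, si, 3)
    af <- full$A[ord, ord, , drop = FALSE]
    sf <- full$Sigma[ord, ord]
    fullr <- list(A = af, Sigma = sf, order = p)
    nf <- block_normalise(sf, list(1, 2, 3))
    nr <- block_normalise(red$Sigma, list(1, 2))
    sxx_red <- nr$Sigma[1, 1]
    sxx_full <- nf$Sigma[1, 1]
    vapply(freqs, function(f) {
      lam <- 2 * pi * f / fs
      h <- var_transfer(fullr, lam) %*% solve(nf$P)
      g <- var_transfer(red, lam) %*% solve(nr$P)
      g3 <- diag(3) + 0i
      g3[c(1, 3), c(1, 3)] <- g
      q <- solve(g3, h)
      val <- log(sxx_red / (Mod(q[1, 1])^2 * sxx_full))
      max(val, 0)
    }, numeric(1))
  }
  gc <- cbind(x_to_y = one_dir(2, 1), y_to_x = one_dir(1, 2))
  structure(list(freq = freqs, gc = gc, conditioning = "z", order = p),
            class = "gc_spectrum")
}

#' Sliding-window directed gamma-band Granger causality
#'
#' Fits a bivariate VAR in overlapping windows and reports the band-averaged
#' spectral causality in both directions plus the dominant direction label
#' per window.
#'
#' @param x,y Single-trial numeric series.
#' @param window Window length, ms (>= 200).
#' @param step Window step, ms.
#' @param band Frequency band to average, Hz.
#' @param fs Sampling rate, Hz.
#' @param order VAR order (NULL: AIC up to 12 on the full series, reused per
#'   window).
#' @return Data frame with `t_start`, `t_mid`, `gc_xy`, `gc_yx`,
#'   `dominant` ("x->y" or "y->x").
#' @export
sliding_gc <- function(x, y, window = 500, step = 100, band = c(30, 50),
                       fs = 1000, order = NULL) {
  stopifnot(window >= 200, step > 0)
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  wlen <- round(window * fs / 1000)
  if (wlen > n) stop("window longer than the data", call. = FALSE)
  if (is.null(order))
    order <- fit_var(cbind(x, y), max_order = 12)$order
  slen <- round(step * fs / 1000)
  starts <- seq(1, n - wlen + 1, by = slen)
  freqs <- seq(band[1], band[2], by = 1)
  out <- lapply(starts, function(s0) {
    seg <- cbind(x[s0:(s0 + wlen - 1)], y[s0:(s0 + wlen - 1)])
    g <- tryCatch(spectral_gc(fit_var(seg, order = order), freqs, fs),
                  error = function(e) NULL)
    if (is.null(g)) return(NULL)
    data.frame(t_start = (s0 - 1) / fs * 1000,
               t_mid = (s0 - 1 + wlen / 2) / fs * 1000,
               gc_xy = mean(g$gc[, "x_to_y"]),
               gc_yx = mean(g$gc[, "y_to_x"]))
  })
  out <- do.call(rbind, out)
  out$dominant <- ifelse(out$gc_xy >= out$gc_yx, "x->y", "y->x")
  out
}
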