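# Independent fixed-step reference integrator: classical 4th-order
# Runge-Kutta at a fixed step, restarted at every forcing breakpoint, with a
# self-contained right-hand side (no use of the package's derivative code or
# of deSolve). Used as the oracle for integrator-agreement checks.
rk4_reference <- function(spec, h = 0.001) {
  params <- spec$params
  cal <- spec$calendar
  yl <- cal$year_length
  q <- 2^(params$temp_shift_x / 10)
  eb <- params$eps_base
  ew <- params$eps_winter_F1
  m <- params$m; K <- params$K; kk <- params$k; f <- params$f
  cc <- params$c; e <- params$e; hmax <- params$h_max

  in_any <- function(doy, windows) {
    for (w in windows) if (doy >= w[1] && doy < w[2]) return(TRUE)
    FALSE
  }
  phi_fun <- function(S1, S2, S3) {
    T <- S1 + S2 + S3
    if (T <= 0) return(numeric(6))
    c(S1 * (S1 + cc * (T - S1)) / (2 * T),
      S2 * (S2 + cc * (T - S2)) / (2 * T),
      (1 - cc) * S1 * S2 / T,
      (1 - cc) * S1 * S3 / T,
      (1 - cc) * S2 * S3 / T,
      S3 * (S3 + cc * (S1 + S2)) / (2 * T))
  }

  bp <- breakpoints(spec)
  y <- unname(spec$initial_state)
  rec_t <- 0
  rec_y <- list(y)
  two_pi <- 2 * pi

  for (i in seq_len(length(bp) - 1L)) {
    t0 <- bp[i]; t1 <- bp[i + 1L]
    if (nrow(spec$introductions) > 0) {
      hit <- which(abs(spec$introductions$time_days - t0) < 1e-9)
      for (ev in hit) {
        y[spec$introductions$class_index[ev]] <-
          y[spec$introductions$class_index[ev]] + spec$introductions$density[ev]
      }
    }
    tm <- (t0 + t1) / 2
    doy <- tm %% yl
    s_now <- if (in_any(doy, cal$sexual_windows)) params$s_max else 0
    h_on <- in_any(doy, list(cal$hatching_window))
    h_now <- if (h_on) hmax else numeric(6)
    winter <- in_any(doy, cal$winter_window)
    eps3 <- if (winter) ew else eb
    r <- vapply(1:6, function(j) growth_rate_at(spec$schedule, j, tm),
                numeric(1))

    rhs <- function(t, y) {
      A <- y[1:6]; S <- y[7:12]; E <- y[13:18]
      co <- cos(two_pi * t / yl)
      sigb <- (1 - eb * co) / (1 + eb)
      sig <- rep(sigb, 6)
      sig[3] <- (1 - eps3 * co) / (1 + eps3)
      tot <- sum(A) + sum(S)
      dA <- q * r * sig * A * (1 - tot / (sigb * K)) - s_now * A +
        2 * h_now * E
      dS <- s_now * A - m * S
      dE <- (1 - e) * f * kk * phi_fun(S[1], S[2], S[3]) - h_now * E
      c(dA, dS, dE)
    }

    n <- max(1L, round((t1 - t0) / h))
    hh <- (t1 - t0) / n
    per_day <- round(1 / hh)
    tt <- t0
    for (k in seq_len(n)) {
      k1 <- rhs(tt, y)
      k2 <- rhs(tt + hh / 2, y + hh / 2 * k1)
      k3 <- rhs(tt + hh / 2, y + hh / 2 * k2)
      k4 <- rhs(tt + hh, y + hh * k3)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tt <- t0 + k * hh
      if (k %% per_day == 0 || k == n) {
        rec_t <- c(rec_t, tt)
        rec_y[[length(rec_y) + 1L]] <- y
      }
    }
  }
  states <- do.call(rbind, rec_y)
  colnames(states) <- state_names()
  keep <- !duplicated(rec_t)
  list(time_days = rec_t[keep], states = states[keep, , drop = FALSE])
}
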