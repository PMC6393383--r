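# Independent reference integration of the same rate equations,
# written separately from the package internals: adaptive-step lsoda
# (deSolve) over segments on which the binary thalamic input is
# constant. Used as the numerical oracle for the Euler integrator.

oracle_rhs <- function(t, y, parms) {
  v <- y[1]; isahp <- y[2]; ih <- y[3]; da <- y[4]
  p <- parms
  heav <- function(x) as.numeric(x > 0)
  sig <- function(x) heav(x) * tanh(x)
  v_inf <- sig(p$w_thal * p$s + p$drv_tan + isahp + ih)
  sahp_inf <- -p$g_sahp * (v - p$theta_sahp) * heav(v - p$theta_sahp)
  h_inf <- -p$g_h * exp(-p$w_da * da) * (v - p$theta_h) *
    heav(p$theta_h - v)
  da_inf <- p$alpha *
    (p$rpe * (1 - v / p$theta_da) * heav(p$theta_da - v) + p$da0) +
    p$ldopa
  list(c((v_inf - v) / p$tau_tan,
         (sahp_inf - isahp) / p$tau_sahp,
         (h_inf - ih) / p$tau_h,
         (da_inf - da) / p$tau_da))
}

oracle_trace <- function(params, stimulus, context, dt_out = 0.5) {
  iv <- stimulus$intervals
  breaks <- sort(unique(c(0, iv$start_ms, iv$end_ms,
                          stimulus$total_duration_ms)))
  parms <- c(unclass(params), unclass(context))
  y <- with(as.list(steady_state(params, context)),
            c(v_tan, i_sahp, i_h, da))
  out <- NULL
  for (k in seq_len(length(breaks) - 1)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1]
    parms$s <- as.numeric(any(iv$start_ms <= t0 & t0 < iv$end_ms))
    times <- unique(c(seq(t0, t1, by = dt_out), t1))
    seg <- deSolve::lsoda(y, times, oracle_rhs, parms,
                          rtol = 1e-10, atol = 1e-12)
    y <- as.numeric(seg[nrow(seg), -1])
    out <- rbind(out, seg[if (is.null(out)) TRUE else -1, ])
  }
  tr <- tibble::tibble(t_ms = out[, 1], v_tan = out[, 2],
                       i_sahp = out[, 3], i_h = out[, 4],
                       da = pmax(out[, 5], 0))
  attr(tr, "params") <- params
  attr(tr, "stimulus") <- stimulus
  attr(tr, "context") <- context
  attr(tr, "dt") <- dt_out
  class(tr) <- c("tan_trace", class(tr))
  tr
}

# square synthetic trace for pause-detector unit tests
synthetic_trace <- function(t, v, da = rep(1, length(t)),
                            stimulus = stim_block(300,
                              total_duration_ms = max(t)),
                            params = model_params(),
                            context = scenario_context()) {
  tr <- tibble::tibble(t_ms = t, v_tan = v,
                       i_sahp = 0, i_h = 0, da = da)
  attr(tr, "params") <- params
  attr(tr, "stimulus") <- stimulus
  attr(tr, "context") <- context
  attr(tr, "dt") <- t[2] - t[1]
  class(tr) <- c("tan_trace", class(tr))
  tr
}
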