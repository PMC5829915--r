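# Independent oracles used by the tests. These deliberately take different
# algorithmic routes from the package implementation.

# Per-motor telegraph-clock simulation of a single-species filament run:
# every motor is an independent two-state process (alternating Exp(k_det)
# bound and Exp(k_att) unbound intervals, motor 1 starting bound); the run
# terminates when a zero-bound interval exceeds the rescue window, the
# position reaches the actin end, or the horizon runs out. Valid because
# independent exponential clocks and the event-driven ensemble chain describe
# the same Markov process.
oracle_run <- function(n, k_att, k_det, v_um_s, actin_length, tau,
                       horizon = 5000) {
  toggles <- vector("list", n)
  for (m in seq_len(n)) {
    state0 <- m == 1           # motor 1 initiates the run
    ts <- numeric(0); t <- 0; bound <- state0
    while (t < horizon) {
      dt <- stats::rexp(1, if (bound) k_det else k_att)
      t <- t + dt
      ts <- c(ts, t)
      bound <- !bound
    }
    toggles[[m]] <- list(t = ts, start_bound = state0)
  }
  ev_t <- unlist(lapply(toggles, `[[`, "t"))
  ev_d <- unlist(lapply(toggles, function(x) {
    k <- length(x$t)
    d <- rep(c(-1, 1), length.out = k)
    if (!x$start_bound) d <- -d
    d
  }))
  o <- order(ev_t)
  ev_t <- ev_t[o]; ev_d <- ev_d[o]
  nbound <- 1 + cumsum(ev_d)
  t_prev <- 0; moved <- 0; nb_prev <- 1
  for (i in seq_along(ev_t)) {
    dt <- ev_t[i] - t_prev
    if (nb_prev >= 1) {
      if (moved + v_um_s * dt >= actin_length)
        return(list(run_length = actin_length, termination = "reached_end"))
      moved <- moved + v_um_s * dt
    } else if (dt > tau) {
      return(list(run_length = moved, termination = "all_detached"))
    }
    nb_prev <- nbound[i]; t_prev <- ev_t[i]
  }
  list(run_length = moved, termination = "timeout")
}

# long-run bound-time fraction of a single two-state motor
telegraph_fraction <- function(k_att, k_det, total_time = 5000) {
  n <- ceiling(total_time * (k_att + k_det) / 2) + 100
  on_t <- stats::rexp(n, k_det)
  off_t <- stats::rexp(n, k_att)
  cum <- cumsum(on_t + off_t)
  k <- which(cum >= total_time)[1]
  sum(on_t[1:k]) / cum[k]
}

# brute-force optimal one-to-one matching (with unmatched allowed at cost
# cap^2 per point) by enumeration over all injections; for small sets only
brute_match_cost <- function(xy1, xy2, max_dist) {
  n <- nrow(xy1); m <- nrow(xy2)
  d2 <- outer(xy1[, 1], xy2[, 1], "-")^2 + outer(xy1[, 2], xy2[, 2], "-")^2
  best <- Inf
  cols <- c(seq_len(m), rep(NA, n))
  perms <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v)) {
      rest <- perms(v[-i], k - 1)
      for (r in rest) out[[length(out) + 1]] <- c(v[i], r)
    }
    out
  }
  # assignments: each row gets a distinct column or nothing
  subsets <- function(v) {
    if (!length(v)) return(list(integer(0)))
    rest <- subsets(v[-1])
    c(rest, lapply(rest, function(s) c(v[1], s)))
  }
  for (rows in subsets(seq_len(n))) {
    k <- length(rows)
    if (k > m) next
    for (asg in perms(seq_len(m), k)) {
      cost <- sum(d2[cbind(rows, asg)])
      if (k && any(d2[cbind(rows, asg)] > max_dist^2)) next
      cost <- cost + (n - k) * max_dist^2 + (m - k) * max_dist^2
      if (cost < best) best <- cost
    }
  }
  best
}

# small-field optics for fast rendering tests
test_optics <- function(frame_count = 30, shape = c(96, 96), ...) {
  optics_model(frame_count = frame_count, image_shape = shape, ...)
}

default_species <- function() {
  list(A = nm2_species("NM2A"), B = nm2_species("NM2B"))
}
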