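# Brute-force discontinuous-dynamics oracle for <= 4 beads: scans every
# pair at tiny time increments, bisects each surface crossing, and
# applies the hard-sphere / square-well / bond-window rules
# independently of the event-driven engine.
dmd_brute_oracle <- function(pos, vel, mass, sigma, wellr, eps, bonds,
                             t_end, dt = 5e-4) {
  n <- nrow(pos)
  p <- pos; v <- vel; t <- 0
  inwell <- matrix(FALSE, n, n)
  bonded <- matrix(FALSE, n, n)
  bwin <- list()
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1] + 1; j <- bonds[k, 2] + 1
    bonded[i, j] <- bonded[j, i] <- TRUE
    bwin[[paste(i, j)]] <- bonds[k, 3:4]
  }
  dd <- function(p, i, j) sqrt(sum((p[i, ] - p[j, ])^2))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!bonded[i, j] && wellr > 0 && dd(p, i, j) < wellr) {
      inwell[i, j] <- TRUE
    }
  }
  surface_gap <- function(p, i, j) {
    d <- dd(p, i, j)
    if (bonded[i, j]) {
      w <- bwin[[paste(i, j)]]
      c(lo = d - w[1], hi = w[2] - d)
    } else if (inwell[i, j]) {
      c(lo = d - sigma, hi = wellr - d)
    } else {
      c(lo = d - (if (wellr > 0) wellr else sigma), hi = Inf)
    }
  }
  ev <- list()
  while (t < t_end) {
    best <- NULL
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      g0 <- surface_gap(p, i, j)
      g1 <- surface_gap(p + v * dt, i, j)
      for (side in c("lo", "hi")) {
        if (g0[[side]] > 0 && g1[[side]] <= 0) {
          a <- 0; b <- dt
          for (k in 1:60) {
            m <- (a + b) / 2
            if (surface_gap(p + v * m, i, j)[[side]] > 0) a <- m else b <- m
          }
          tc <- (a + b) / 2
          if (is.null(best) || tc < best$tc) {
            best <- list(tc = tc, i = i, j = j, side = side)
          }
        }
      }
    }
    if (is.null(best)) { p <- p + v * dt; t <- t + dt; next }
    i <- best$i; j <- best$j
    p <- p + v * best$tc; t <- t + best$tc
    if (t >= t_end) break
    dr <- p[j, ] - p[i, ]
    d <- sqrt(sum(dr^2)); nrm <- dr / d
    vr <- sum((v[j, ] - v[i, ]) * nrm)
    mu <- mass[i] * mass[j] / (mass[i] + mass[j])
    apply_vr <- function(vr_new) {
      J <- mu * (vr_new - vr)
      v[i, ] <<- v[i, ] - J / mass[i] * nrm
      v[j, ] <<- v[j, ] + J / mass[j] * nrm
    }
    if (bonded[i, j]) {
      apply_vr(-vr); kind <- "bond"
    } else if (wellr > 0 && !inwell[i, j]) {
      apply_vr(-sqrt(vr^2 + 2 * eps / mu)); inwell[i, j] <- TRUE
      kind <- "capture"
    } else if (best$side == "lo") {
      apply_vr(-vr); kind <- "core"
    } else if (vr^2 >= 2 * eps / mu) {
      apply_vr(sqrt(vr^2 - 2 * eps / mu)); inwell[i, j] <- FALSE
      kind <- "escape"
    } else {
      apply_vr(-vr); kind <- "bounce"
    }
    ev[[length(ev) + 1]] <- data.frame(t = t, i = i - 1, j = j - 1,
                                       kind = kind)
  }
  do.call(rbind, ev)
}
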