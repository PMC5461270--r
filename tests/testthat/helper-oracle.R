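# Independent straight-line re-implementation of the switching mobility
# controller (axes, switching coefficients, local/residual split, mobility,
# cross requests, command mixing, proportional forces), kept free of any call
# into the package's own control path. Used to cross-check control_step().

oracle_control <- function(state, vd_x, p) {
  s <- as.numeric(state)
  pos <- list(trunk = s[2:3], rfoot = s[4:5], lfoot = s[6:7])
  vel <- list(trunk = s[8:9], rfoot = s[10:11], lfoot = s[12:13])
  dir <- if (vd_x < 0) -1 else 1
  vd <- c(vd_x, 0)

  gr <- c(r = pos$rfoot[2] <= 0, l = pos$lfoot[2] <= 0)
  n_gr <- sum(gr)
  pr <- dir * pos$rfoot[1]
  pl <- dir * pos$lfoot[1]
  ant <- if (pr > pl) "r" else if (pl > pr) "l" else if (dir > 0) "r" else "l"
  post <- if (ant == "r") "l" else "r"
  foot_pos <- list(r = pos$rfoot, l = pos$lfoot)
  foot_vel <- list(r = vel$rfoot, l = vel$lfoot)

  unit <- function(v) v / sqrt(sum(v^2))
  e <- list(
    unit(foot_pos[[ant]] - foot_pos[[post]]),    # inter-leg
    unit(pos$trunk - pos$rfoot),                 # right leg
    unit(pos$trunk - pos$lfoot)                  # left leg
  )
  len <- c(NA,
           sqrt(sum((pos$trunk - pos$rfoot)^2)),
           sqrt(sum((pos$trunk - pos$lfoot)^2)))

  # switching coefficients
  a <- numeric(3)
  for (f in c("r", "l")) {
    i <- if (f == "r") 2 else 3
    sign <- 1
    if (f == ant && abs(pos$trunk[1] - foot_pos[[f]][1]) < p$d_balance) {
      sign <- -1
    } else if (f == post && !gr[[f]] && len[i] > p$L0_leg) {
      sign <- -1
    }
    a[i] <- sign * (if (gr[[f]]) 1 else 0.5)
  }
  lpost <- len[if (post == "r") 2 else 3]
  long_post <- lpost > p$swing_ratio * p$L0_leg
  if (n_gr == 2) {
    a[1] <- 0
  } else if (n_gr == 0) {
    a[1] <- if (long_post) -0.5 else 0.5
  } else {
    a[1] <- if (gr[[ant]] && !gr[[post]] && long_post) -1 else 0
  }

  # produced velocities at the trunk
  vi <- list(c(0, 0),
             sum(vel$trunk * e[[2]]) * e[[2]],
             sum(vel$trunk * e[[3]]) * e[[3]])

  vdl <- vdr <- vector("list", 3)
  k <- numeric(3)
  for (i in 1:3) {
    vdl[[i]] <- a[i] * sum(e[[i]] * vd) * e[[i]]
    vdr[[i]] <- vd - vdl[[i]]
    num <- sum((vdl[[i]] - vi[[i]])^2) + p$eps1
    den <- sum(vdl[[i]]^2) + p$eps2
    k[i] <- exp(-4 * log(2) * num / den)
  }

  vtilde <- fvec <- vector("list", 3)
  for (i in 1:3) {
    js <- setdiff(1:3, i)
    req <- (k[js[1]] * sum(e[[i]] * vdr[[js[1]]]) +
            k[js[2]] * sum(e[[i]] * vdr[[js[2]]])) * e[[i]]
    vtilde[[i]] <- (1 - k[js[1]]) * (1 - k[js[2]]) * vdl[[i]] + req
    fvec[[i]] <- p$gain * sum((vtilde[[i]] - vi[[i]]) * e[[i]]) * e[[i]]
  }

  forces <- matrix(0, 3, 2, dimnames = list(c("trunk", "rfoot", "lfoot"),
                                            c("fx", "fz")))
  forces["trunk", ] <- fvec[[2]] + fvec[[3]]
  forces["rfoot", ] <- -fvec[[2]]
  forces["lfoot", ] <- -fvec[[3]]
  ant_row <- if (ant == "r") "rfoot" else "lfoot"
  post_row <- if (ant == "r") "lfoot" else "rfoot"
  forces[ant_row, ] <- forces[ant_row, ] + fvec[[1]]
  forces[post_row, ] <- forces[post_row, ] - fvec[[1]]

  list(a = a, k = k, forces = forces, vdl = vdl, vdr = vdr,
       vtilde = vtilde, anterior = ant)
}

# term-by-term passive-force oracle (leg + extension limit + inter-leg +
# ground + auxiliary trunk), independent of the package's assembly path
oracle_passive <- function(state, dir, p) {
  s <- as.numeric(state)
  pos <- list(trunk = s[2:3], rfoot = s[4:5], lfoot = s[6:7])
  vel <- list(trunk = s[8:9], rfoot = s[10:11], lfoot = s[12:13])
  out <- matrix(0, 3, 2, dimnames = list(c("trunk", "rfoot", "lfoot"),
                                         c("fx", "fz")))
  for (f in c("rfoot", "lfoot")) {
    d <- pos$trunk - pos[[f]]
    L <- sqrt(sum(d^2))
    u <- d / L
    grounded <- pos[[f]][2] <= 0
    kk <- if (grounded) p$k_leg_contact else p$k_leg_flight
    Lb <- p$ext_ratio * p$L0_leg
    fe <- if (L <= Lb) -kk * (L - p$L0_leg) else
      -kk * (Lb - p$L0_leg) - p$ext_mult * kk * (L - Lb)
    fa <- fe - p$b_leg * sum((vel$trunk - vel[[f]]) * u)
    out["trunk", ] <- out["trunk", ] + fa * u
    out[f, ] <- out[f, ] - fa * u
    # auxiliary trunk-foot separation keeper
    dx <- pos$trunk[1] - pos[[f]][1]
    if (abs(dx) < p$d_aux && dx != 0) {
      sgn <- sign(dx)
      fo <- p$k_aux * (p$d_aux - abs(dx)) -
        p$b_aux * sgn * (vel$trunk[1] - vel[[f]][1])
      out["trunk", 1] <- out["trunk", 1] + sgn * fo
      out[f, 1] <- out[f, 1] - sgn * fo
    }
    # ground
    if (pos[[f]][2] <= 0) {
      fz <- max(0, -p$k_ground * pos[[f]][2] - p$b_ground * vel[[f]][2])
      out[f, ] <- out[f, ] + c(-p$b_friction * vel[[f]][1], fz)
    }
  }
  d1 <- pos$rfoot - pos$lfoot
  L1 <- sqrt(sum(d1^2))
  u1 <- d1 / L1
  f1 <- -p$k_inter * (L1 - p$L0_inter) -
    p$b_inter * sum((vel$rfoot - vel$lfoot) * u1)
  out["rfoot", ] <- out["rfoot", ] + f1 * u1
  out["lfoot", ] <- out["lfoot", ] - f1 * u1
  out
}

random_state <- function() {
  sidestep_state(
    t = 0,
    trunk = c(stats::rnorm(1, 0, 0.4), stats::runif(1, 0.55, 1.05)),
    rfoot = c(stats::rnorm(1, 0.5, 0.35), stats::runif(1, -0.02, 0.4)),
    lfoot = c(stats::rnorm(1, -0.5, 0.35), stats::runif(1, -0.02, 0.4)),
    v_trunk = stats::rnorm(2, 0, 1.5),
    v_rfoot = stats::rnorm(2, 0, 1.5),
    v_lfoot = stats::rnorm(2, 0, 1.5)
  )
}

mirror_state <- function(s) {
  m <- s
  m["x_trunk"] <- -s[["x_trunk"]]
  m["x_rfoot"] <- -s[["x_lfoot"]]; m["z_rfoot"] <- s[["z_lfoot"]]
  m["x_lfoot"] <- -s[["x_rfoot"]]; m["z_lfoot"] <- s[["z_rfoot"]]
  m["vx_trunk"] <- -s[["vx_trunk"]]
  m["vx_rfoot"] <- -s[["vx_lfoot"]]; m["vz_rfoot"] <- s[["vz_lfoot"]]
  m["vx_lfoot"] <- -s[["vx_rfoot"]]; m["vz_lfoot"] <- s[["vz_rfoot"]]
  m
}

mirror_forces <- function(f) {
  rbind(trunk = f["trunk", ] * c(-1, 1),
        rfoot = f["lfoot", ] * c(-1, 1),
        lfoot = f["rfoot", ] * c(-1, 1))
}
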