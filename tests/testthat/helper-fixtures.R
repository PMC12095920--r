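# shared fixtures; everything is generated in code, no stored data

default_grid <- function(t_max = 24) seq(0, t_max, by = 5 / 60)

# noiseless two-baseline sigmoid as an averaged curve
sigmoid_curve <- function(k, t05, times = default_grid(),
                          m1 = 0, n1 = 0, m2 = 0, n2 = 1) {
  averaged_curve(times, eval_sigmoid(times, m1, n1, m2, n2, k, t05))
}

# fabricated fit carrying only what compare_halftimes needs
fake_fit <- function(t05, se) {
  list(t05 = t05, se = c(t05 = se), converged = TRUE)
}

# generator-default kinetic models: rate constants sit in the
# secondary-process-dominated regime (primary nucleation many decades
# down) so the textbook scaling exponents apply
frag_model <- function() kinetic_model("fragmentation", kn = 1e-18,
                                       kplus = 80, kminus = 0.01)
ne_model <- function() kinetic_model("nucleation_elongation", kn = 1e-6,
                                     kplus = 80)
sn_model <- function() kinetic_model("secondary_nucleation", kn = 1e-18,
                                     kplus = 80, k2 = 1e-3)
sat_model <- function() kinetic_model("saturating_elongation_fragmentation",
                                      kn = 1e-18, kplus = 80,
                                      kminus = 0.1, KS = 0.5)

scaling_m0s <- c(2.5, 5, 10, 20, 40)  # 16-fold range

model_halftimes <- function(model, m0s = scaling_m0s,
                            times = seq(0, 48, by = 0.02)) {
  vapply(m0s, function(m0)
    numeric_halftime(times, simulate_model(model, m0, times, atol = 1e-30),
                     target = 0.5), numeric(1))
}

series_to_curves <- function(df) {
  lapply(split(df, df$m0_uM), function(g)
    list(m0 = g$m0_uM[1], times = g$time_h, mass = g$mass_fraction))
}

# independent fixed-step RK4 oracle for the two-moment equations
rk4_oracle <- function(model, m0, times, dt = 1e-3) {
  rhs <- function(y) {
    m <- max(m0 - y[2], 0)
    dP <- model$kn * m^model$nc
    if (model$name %in% c("fragmentation",
                          "saturating_elongation_fragmentation"))
      dP <- dP + model$kminus * y[2]
    if (model$name == "secondary_nucleation")
      dP <- dP + model$k2 * m^model$n2 * y[2]
    dM <- 2 * model$kplus * m * y[1]
    if (model$name == "saturating_elongation_fragmentation")
      dM <- dM / (1 + m / model$KS)
    c(dP, dM)
  }
  y <- c(0, 0)
  out <- numeric(length(times))
  t <- 0
  for (i in seq_along(times)) {
    while (t < times[i] - 1e-12) {
      h <- min(dt, times[i] - t)
      k1 <- rhs(y)
      k2 <- rhs(y + h / 2 * k1)
      k3 <- rhs(y + h / 2 * k2)
      k4 <- rhs(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i] <- y[2] / m0
  }
  out
}

# small folded + disordered test system
mini_system <- function(box = 60, pbc = TRUE, idp = TRUE, seed = 3) {
  dom <- gen_mini_domain(24, "helix_hairpin", seed = 2)
  chains <- list(dom)
  if (idp) {
    ch <- build_idp_chain("KRDEGSAKDE", seed = seed, box = box)
    ch$positions <- sweep(ch$positions, 2,
                          colMeans(ch$positions) - colMeans(dom$positions) -
                            c(15, 0, 0))
    chains <- c(chains, list(ch))
  }
  cg_system(chains, force_field(), box = box, pbc = pbc)
}

numeric_forces <- function(sys, x, h = 1e-5, idx = NULL) {
  if (is.null(idx)) idx <- cbind(rep(seq_len(nrow(x)), each = 3),
                                 rep(1:3, nrow(x)))
  vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; a <- idx[r, 2]
    xp <- x; xm <- x
    xp[i, a] <- xp[i, a] + h
    xm[i, a] <- xm[i, a] - h
    -(compute_forces(sys, xp)$potential -
        compute_forces(sys, xm)$potential) / (2 * h)
  }, numeric(1))
}
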