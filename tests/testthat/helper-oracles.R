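# Independent oracles used across the test files. These deliberately do
# not share code with the package internals: fixed-step RK4 integration
# written directly from the model equations, and bracketing root finding
# for the stasis concentration.

# Fixed-step RK4 for dy/dt = f(t, y). `breaks` are extra grid points
# (e.g. infusion starts/ends) so no step straddles a derivative kink.
rk4_integrate <- function(f, y0, times, dt = 0.01, breaks = numeric(0)) {
  grid <- sort(unique(c(seq(times[1], times[length(times)], by = dt),
                        times, breaks)))
  grid <- grid[grid >= times[1] & grid <= times[length(times)]]
  out <- matrix(NA_real_, length(times), length(y0))
  y <- y0
  if (grid[1] %in% times) out[match(grid[1], times), ] <- y
  for (i in seq_len(length(grid) - 1)) {
    h <- grid[i + 1] - grid[i]
    t <- grid[i]
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    j <- match(grid[i + 1], times)
    if (!is.na(j)) out[j, ] <- y
  }
  out
}

# TGI right-hand side transcribed from the model definition.
tgi_rhs <- function(p, conc_fun) {
  function(t, y) {
    V1 <- max(y[1], 0); V2 <- y[2]; V3 <- y[3]; V4 <- y[4]
    TV <- V1 + V2 + V3 + V4
    cc <- max(conc_fun(t), 0)
    kkill <- if (cc > 0) {
      p$kkmax * cc^p$n / (p$kc50^p$n + cc^p$n)
    } else 0
    x <- (p$kgEx / p$kg) * TV
    den <- if (x > 0) (1 + x^p$psi)^(1 / p$psi) else 1
    if (!is.finite(den)) den <- x # x^psi overflow: limit is x
    G <- p$kgEx * (1 - TV / p$Vmax) / den
    c(G * V1 - kkill * V1,
      kkill * V1 - V2 / p$tau,
      (V2 - V3) / p$tau,
      (V3 - V4) / p$tau)
  }
}

# TMDD right-hand side transcribed from the model definition (4 states,
# nM). `infusion_fun(t)` gives the input rate in nM/day.
tmdd_rhs <- function(p, infusion_fun) {
  lin <- p$linear
  function(t, y) {
    CA <- y[1]; CP <- y[2]; CE <- y[3]; CX <- y[4]
    c(infusion_fun(t) - (lin$CL / lin$Vc) * CA - (lin$Q / lin$Vc) * CA +
        (lin$Q / lin$Vp) * CP * (lin$Vp / lin$Vc) -
        p$kon * CA * CE + p$koff * CX,
      (lin$Q / lin$Vc) * CA * (lin$Vc / lin$Vp) - (lin$Q / lin$Vp) * CP,
      p$kshed - p$kdeg * CE - p$kon * CA * CE + p$koff * CX,
      p$kon * CA * CE - p$koff * CX - p$kel_complex * CX)
  }
}

# Bracketing root finder for the stasis concentration:
# kill_rate(c) = growth_rate(v0).
tsc_by_root_finding <- function(p, v0 = 0) {
  G <- growth_rate(v0, p)
  f <- function(cc) kill_rate(cc, p) - G
  hi <- p$kc50
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(1e-12, hi), tol = 1e-14)$root
}

# Random valid TGI parameter sets with reachable stasis, for property
# loops (seeded by the caller).
random_tgi_params <- function() {
  kgEx <- runif(1, 0.01, 0.2)
  tgi_params(kgEx = kgEx,
             kg = runif(1, 10, 400),
             Vmax = runif(1, 2000, 9000),
             tau = runif(1, 0.5, 8),
             kkmax = kgEx * runif(1, 1.5, 20),
             kc50 = runif(1, 0.5, 100),
             n = runif(1, 0.5, 3),
             v0 = runif(1, 150, 300))
}

# Shared fixture parameter sets.
fx_mouse_pk <- function() two_cpt_params(61.0, 22.8, 56.2, 35.0)
fx_monkey_pk <- function() two_cpt_params(38.1, 7.2, 20.2, 19.2)
fx_jimt1 <- function() tgi_params(kgEx = 0.0883, kg = 47.5, Vmax = 4080,
                                  tau = 2.23, kkmax = 0.703, kc50 = 10.6,
                                  n = 2.4, v0 = 200)
fx_human_tmdd <- function() {
  tmdd_params(two_cpt_params(38.1, 5.52, 20.2, 14.9), KD = 0.1,
              kon = 61.3, kshed = 6.65, kdeg = 33.3, kel_complex = 32.6)
}
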