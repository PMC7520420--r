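# Internal glue around deSolve's compiled-model interface.
#
# Integration is restarted at every dose-event boundary (bolus jumps and
# infusion start/stop) so the stiff solver never steps across a
# discontinuity in the input function.

TGI_MAXP <- 400L
TGI_MAXEV <- 40L
TGI_EVOFF <- 13L          # 0-based offset in C; R index TGI_EVOFF + 1
TGI_GROFF <- 13L + 3L * 40L

TMDD_MAXP <- 160L
TMDD_MAXEV <- 40L
TMDD_EVOFF <- 10L

# Pack the TGI parameter vector for the compiled model.
# growth: matrix with columns kgEx, kg (one row per animal).
pack_tgi_parms <- function(p, growth, pk = NULL, regimen = NULL,
                           forced = FALSE) {
  n_anim <- nrow(growth)
  if (n_anim > (TGI_MAXP - TGI_GROFF) %/% 2) {
    stop_invalid("simulate_tgi: too many animals in one solver call")
  }
  parms <- numeric(TGI_MAXP)
  parms[1] <- n_anim
  parms[2:7] <- c(p$Vmax, p$tau, p$kkmax, p$kc50, p$n, p$psi)
  parms[8] <- as.numeric(forced)
  if (!forced) {
    stopifnot(inherits(pk, "two_cpt_params"), inherits(regimen, "dosing_regimen"))
    if (nrow(regimen) > TGI_MAXEV) {
      stop_invalid("simulate_tgi: at most ", TGI_MAXEV, " dose events supported")
    }
    e <- disposition_exponents(pk)
    parms[9:12] <- c(pk$Vc, e$alpha, e$beta, e$k21)
    parms[13] <- nrow(regimen)
    ev <- as.numeric(t(as.matrix(regimen[, c("time_day", "dose_mg_per_kg",
                                             "infusion_day")])))
    parms[TGI_EVOFF + seq_along(ev)] <- ev
  }
  parms[TGI_GROFF + seq_len(2 * n_anim)] <- as.numeric(t(growth))
  parms
}

# Event boundaries of a regimen (dose starts and infusion ends).
regimen_boundaries <- function(regimen) {
  sort(unique(c(regimen$time_day,
                regimen$time_day + regimen$infusion_day)))
}

# Piecewise integration with restarts at `boundaries`. `boluses` is an
# optional data.frame(time, state, amount) applied between segments.
piecewise_ode <- function(y0, times, parms, func, initfunc,
                          boundaries = numeric(0), boluses = NULL,
                          forcings = NULL, initforc = NULL,
                          rtol = 1e-8, atol = 1e-10, restart = TRUE) {
  t0 <- times[1]
  tend <- times[length(times)]
  bolus_times <- if (is.null(boluses)) numeric(0) else boluses$time
  # without restarts (cheaper; used inside fitting loops) the event
  # boundaries become plain grid points in a single solver call, and
  # lsoda steps over the input kinks adaptively
  if (!restart && is.null(boluses)) {
    times_aug <- sort(unique(c(times, boundaries[boundaries > t0 &
                                                   boundaries < tend])))
    sol <- deSolve::ode(y = y0, times = times_aug, func = func,
                        parms = parms, dllname = "adcpkpd",
                        initfunc = initfunc, forcings = forcings,
                        initforc = initforc, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop_invalid("ODE integration failed (lsoda istate = ",
                   attr(sol, "istate")[1], ")")
    }
    return(sol[sol[, 1] %in% times, , drop = FALSE])
  }
  cuts <- sort(unique(c(boundaries, bolus_times)))
  cuts <- cuts[cuts > t0 & cuts < tend]
  seg_edges <- c(t0, cuts, tend)

  out_rows <- vector("list", length(seg_edges) - 1)
  y <- y0
  for (k in seq_len(length(seg_edges) - 1)) {
    a <- seg_edges[k]; b <- seg_edges[k + 1]
    if (!is.null(boluses)) {
      hit <- abs(boluses$time - a) < 1e-12
      if (any(hit)) {
        for (j in which(hit)) {
          y[boluses$state[j]] <- y[boluses$state[j]] + boluses$amount[j]
        }
      }
    }
    seg_times <- sort(unique(c(a, times[times > a & times < b], b)))
    sol <- deSolve::ode(y = y, times = seg_times, func = func,
                        parms = parms, dllname = "adcpkpd",
                        initfunc = initfunc,
                        forcings = forcings, initforc = initforc,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop_invalid("ODE integration failed (lsoda istate = ",
                   attr(sol, "istate")[1], ") on segment [",
                   signif(a, 6), ", ", signif(b, 6), "]")
    }
    y <- as.numeric(sol[nrow(sol), -1])
    keep <- sol[, 1] %in% times
    # drop the segment start except for the very first segment (it belongs
    # to the previous segment's output)
    if (k > 1) keep[1] <- FALSE
    out_rows[[k]] <- sol[keep, , drop = FALSE]
  }
  out <- do.call(rbind, out_rows)
  # duplicate requested times (e.g. repeated values in `times`) are not
  # supported; callers pass unique grids
  out
}
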