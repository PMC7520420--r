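#' Tumor-static concentration
#'
#' The tumor-static concentration (TSC) is the constant plasma
#' concentration at which the drug-induced kill rate exactly balances the
#' net tumor growth rate, so tumor volume neither grows nor shrinks.
#' Setting `kill_rate(TSC) = G(v0)` and inverting the Hill function gives
#' `TSC = kc50 * (G / (kkmax - G))^(1/n)` with `G = growth_rate(v0)`.
#' The conventional reported value uses the small-tumor limit `v0 = 0`,
#' where `G = kgEx`.
#'
#' @param p A [tgi_params()] object.
#' @param v0_for_tsc Tumor volume (mm^3) at which stasis is evaluated;
#'   default 0 (small-tumor limit).
#' @return TSC in ug/mL.
#' @export
#' @examples
#' p <- tgi_params(kgEx = 0.0883, kg = 47.5, Vmax = 4080, tau = 2.23,
#'                 kkmax = 0.703, kc50 = 10.6, n = 2.4)
#' compute_tsc(p) # about 4.8 ug/mL
compute_tsc <- function(p, v0_for_tsc = 0) {
  stopifnot(inherits(p, "tgi_params"))
  if (v0_for_tsc < 0) stop_invalid("compute_tsc: v0_for_tsc must be >= 0")
  G <- growth_rate(v0_for_tsc, p)
  if (p$kkmax <= G) {
    stop_invalid("compute_tsc: stasis unreachable - maximum kill rate ",
                 "kkmax = ", signif(p$kkmax, 4),
                 " does not exceed the growth rate G(v0) = ",
                 signif(G, 4), "; no concentration holds the tumor static")
  }
  p$kc50 * (G / (p$kkmax - G))^(1 / p$n)
}

#' Parametric-bootstrap confidence interval on the TSC
#'
#' Resamples each uncertain parameter from a log-normal distribution with
#' median at the point estimate and log-scale standard deviation
#' `sqrt(log(1 + CV^2))`, recomputes the TSC for every draw, and reports
#' empirical percentiles. Draws for which stasis is unreachable
#' (`kkmax <= G`) are discarded and counted.
#'
#' @param p A [tgi_params()] object (point estimates).
#' @param cv Named numeric vector of relative standard errors as fractions
#'   (e.g. `c(kgEx = 0.08, kkmax = 0.09, kc50 = 0.09, n = 0.12)`).
#'   Parameters absent from `cv` (or with CV 0) are held fixed.
#' @param n_boot Number of bootstrap draws.
#' @param seed Integer seed for the resampling.
#' @param level Interval coverage (default 0.80: 10th-90th percentiles).
#' @param v0_for_tsc Volume at which stasis is evaluated (default 0).
#' @return An object of class `tsc_result`: list with `tsc`, `ci_low`,
#'   `ci_high`, `level`, `n_boot`, `n_unreachable`, `seed`.
#' @export
#' @examples
#' p <- tgi_params(0.0883, 47.5, 4080, 2.23, 0.703, 10.6, 2.4)
#' bootstrap_tsc_ci(p, cv = c(kgEx = 0.08, kkmax = 0.09, kc50 = 0.09,
#'                            n = 0.12), n_boot = 2000, seed = 1)
bootstrap_tsc_ci <- function(p, cv, n_boot = 10000, seed = 1, level = 0.80,
                             v0_for_tsc = 0) {
  stopifnot(inherits(p, "tgi_params"))
  if (n_boot < 1) stop_invalid("bootstrap_tsc_ci: n_boot must be >= 1")
  if (level <= 0 || level >= 1) {
    stop_invalid("bootstrap_tsc_ci: level must be in (0, 1)")
  }
  cv <- cv[cv > 0]
  allowed <- c("kgEx", "kg", "Vmax", "tau", "kkmax", "kc50", "n")
  if (length(cv) && !all(names(cv) %in% allowed)) {
    stop_invalid("bootstrap_tsc_ci: unknown parameter(s) in cv: ",
                 paste(setdiff(names(cv), allowed), collapse = ", "))
  }
  point <- compute_tsc(p, v0_for_tsc)

  set.seed(as.integer(seed))
  draws <- sapply(allowed, function(nm) {
    est <- p[[nm]]
    if (nm %in% names(cv)) {
      sdlog <- sqrt(log(1 + cv[[nm]]^2))
      rlnorm(n_boot, meanlog = log(est), sdlog = sdlog)
    } else {
      rep(est, n_boot)
    }
  })

  # vectorized growth factor and TSC over draws
  G <- growth_factor_vec(draws[, "kgEx"], draws[, "kg"], draws[, "Vmax"],
                         p$psi, rep(v0_for_tsc, n_boot))
  reachable <- draws[, "kkmax"] > G
  tsc_draws <- draws[reachable, "kc50"] *
    (G[reachable] / (draws[reachable, "kkmax"] - G[reachable]))^
    (1 / draws[reachable, "n"])
  if (!length(tsc_draws)) {
    stop_invalid("bootstrap_tsc_ci: stasis unreachable in every draw")
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- unname(quantile(tsc_draws, probs))
  structure(list(tsc = point, ci_low = ci[1], ci_high = ci[2],
                 level = level, n_boot = n_boot,
                 n_unreachable = sum(!reachable), seed = as.integer(seed)),
            class = "tsc_result")
}

#' @export
print.tsc_result <- function(x, ...) {
  cat(sprintf("TSC = %.3g ug/mL, %d%% CI [%.3g, %.3g] (%d draws, %d unreachable, seed %d)\n",
              x$tsc, round(100 * x$level), x$ci_low, x$ci_high,
              x$n_boot, x$n_unreachable, x$seed))
  invisible(x)
}
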