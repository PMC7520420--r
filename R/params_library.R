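#' Built-in model parameterizations
#'
#' The package ships the published parameterizations used throughout the
#' examples and the acceptance analysis: two-compartment mouse and
#' cynomolgus-monkey PK for PF-06804103, the fitted tumor-growth-inhibition
#' PD parameters (with their CV% and between-animal variability) for
#' PF-06804103 across seven xenograft models and for T-DM1 across three,
#' and the clinical shed-target TMDD parameterizations for both ADCs.
#'
#' @param agent `"PF-06804103"` or `"T-DM1"`.
#' @param species `"mouse"` or `"monkey"` (PF-06804103 only; T-DM1 mouse
#'   PK was not published - see [tdm1_mouse_pk_synthetic()]).
#' @return `adc_pk_params()`: a [two_cpt_params()] object.
#' @export
#' @examples
#' adc_pk_params("mouse")
#' adc_tgi_params("JIMT-1")$params
adc_pk_params <- function(species = c("mouse", "monkey"),
                          agent = "PF-06804103") {
  species <- match.arg(species)
  tab <- read.csv(system.file("extdata", "pk_2cpt_params.csv",
                              package = "adcpkpd"))
  row <- tab[tab$agent == agent & tab$species == species, ]
  if (!nrow(row)) {
    stop_invalid("adc_pk_params: no published ", species, " PK for ", agent)
  }
  two_cpt_params(Vc = row$Vc, CL = row$CL, Vp = row$Vp, Q = row$Q)
}

#' @param model Tumor-model label (e.g. `"JIMT-1"`, `"N87"`, `"BT474"`,
#'   `"24312"`, `"37622"`, `"144580"`, `"GA-3109"`, `"HCC-1954"`).
#' @param v0 Initial tumor volume (mm^3) attached to the returned
#'   parameter set (per-model values were not published; the default is
#'   the midpoint-ish of the 150-300 mm^3 randomization window).
#' @return `adc_tgi_params()`: a list with `params` (a [tgi_params()]),
#'   `cv` (named CV% vector as published, `NA` where not reported),
#'   `iiv` (an [iiv_spec()]), `err` (a [residual_error_model()]) and
#'   `doses_mg_per_kg` (the study dose levels).
#' @rdname adc_pk_params
#' @export
adc_tgi_params <- function(model, agent = c("PF-06804103", "T-DM1"),
                           v0 = 200) {
  agent <- match.arg(agent)
  tab <- read.csv(system.file("extdata", "tgi_pd_params.csv",
                              package = "adcpkpd"))
  row <- tab[tab$agent == agent & tab$model == model, ]
  if (!nrow(row)) {
    stop_invalid("adc_tgi_params: no parameter set for model '", model,
                 "' and agent '", agent, "' (available for ", agent, ": ",
                 paste(tab$model[tab$agent == agent], collapse = ", "), ")")
  }
  params <- tgi_params(kgEx = row$kgEx, kg = row$kg, Vmax = row$Vmax,
                       tau = row$tau, kkmax = row$kkmax, kc50 = row$kc50,
                       n = row$n, psi = row$psi, v0 = v0)
  cv <- c(kgEx = row$cv_kgEx, kg = row$cv_kg, Vmax = row$cv_Vmax,
          tau = row$cv_tau, kkmax = row$cv_kkmax, kc50 = row$cv_kc50,
          n = row$cv_n)
  list(params = params, cv = cv,
       iiv = iiv_spec(omega_kgEx = row$omega_kgEx, omega_kg = row$omega_kg),
       err = residual_error_model(
         additive = row$additive_error,
         proportional = ifelse(is.na(row$proportional_error), 0,
                               row$proportional_error)),
       doses_mg_per_kg = as.numeric(strsplit(row$doses_mg_per_kg,
                                             ";")[[1]]),
       model = model, agent = agent, model_type = row$model_type)
}

#' @return `adc_tmdd_params()`: a [tmdd_params()] object (clinical).
#' @rdname adc_pk_params
#' @export
adc_tmdd_params <- function(agent = c("PF-06804103", "T-DM1")) {
  agent <- match.arg(agent)
  cfg <- yaml::read_yaml(system.file("extdata", "tmdd_clinical_params.yaml",
                                     package = "adcpkpd"))[[agent]]
  lin <- two_cpt_params(cfg$pk$Vc, cfg$pk$CL, cfg$pk$Vp, cfg$pk$Q)
  tmdd_params(lin, KD = cfg$KD, kon = cfg$kon, kshed = cfg$kshed,
              kdeg = cfg$kdeg, kel_complex = cfg$kel_complex)
}

#' Synthetic placeholder mouse PK for T-DM1 demos
#'
#' The mouse two-compartment PK of T-DM1 was taken from the literature in
#' the original analysis and the numeric values were not published. This
#' synthetic placeholder (typical antibody-conjugate mouse disposition:
#' plasma-sized central volume, slow clearance) exists only so the T-DM1
#' demos run end-to-end; supply real parameters via [two_cpt_params()]
#' for any quantitative use.
#'
#' @return A [two_cpt_params()] object flagged with attribute
#'   `synthetic = TRUE`.
#' @export
tdm1_mouse_pk_synthetic <- function() {
  p <- two_cpt_params(Vc = 55, CL = 18, Vp = 50, Q = 30)
  attr(p, "synthetic") <- TRUE
  p
}
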