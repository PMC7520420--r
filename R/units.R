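#' Unit conventions for ADC and shed-target concentrations
#'
#' The ADC (a full-length IgG conjugate) is taken as 150 kDa and the shed
#' HER2 extracellular domain (ECD) as 100 kDa, so 1 nM of ADC is
#' 0.15 ug/mL and 1 nM of ECD is 100 ng/mL.
#'
#' @return A list with elements `MW_ADC` and `MW_ECD` (kDa).
#' @export
#' @examples
#' unit_conventions()
unit_conventions <- function() {
  list(MW_ADC = 150, MW_ECD = 100)
}

#' Convert between molar and mass concentration units
#'
#' `nm_to_ugml()` converts nM to ug/mL, `ugml_to_nm()` the reverse,
#' using a molecular weight in kDa (default: the ADC, 150 kDa).
#' `ecd_ngml_to_nm()` and `ecd_nm_to_ngml()` convert shed-target
#' concentrations between ng/mL and nM at 100 kDa.
#'
#' @param x Numeric vector of concentrations.
#' @param mw_kda Molecular weight in kDa.
#' @return Numeric vector in the target unit.
#' @export
#' @examples
#' nm_to_ugml(1)        # 0.15 ug/mL
#' ugml_to_nm(0.15)     # 1 nM
#' ecd_ngml_to_nm(20)   # 0.2 nM
nm_to_ugml <- function(x, mw_kda = unit_conventions()$MW_ADC) {
  x * mw_kda * 1e-3
}

#' @rdname nm_to_ugml
#' @export
ugml_to_nm <- function(x, mw_kda = unit_conventions()$MW_ADC) {
  x / (mw_kda * 1e-3)
}

#' @rdname nm_to_ugml
#' @export
ecd_ngml_to_nm <- function(x) {
  x / unit_conventions()$MW_ECD
}

#' @rdname nm_to_ugml
#' @export
ecd_nm_to_ngml <- function(x) {
  x * unit_conventions()$MW_ECD
}

# mg/kg -> nmol/kg for the ADC
dose_mgkg_to_nmolkg <- function(dose_mg_per_kg,
                                mw_kda = unit_conventions()$MW_ADC) {
  dose_mg_per_kg * 1000 / mw_kda
}

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}
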