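#' Reference tables for the erythrocyte inner-leaflet monolayer study
#'
#' Published per-species structural measurements for the three model
#' inner-leaflet compositions - with native cholesterol (`chol`),
#' without cholesterol (`nchol`) and with 7-ketocholesterol (`kchol`):
#'
#' * `"apl"` - mean area per lipid (Å²) of each species;
#' * `"thickness"` - mean tail, headgroup and total lipid thickness (Å);
#' * `"xray"` - in-plane Bragg peak position (Å⁻¹), coherence length
#'   (Å), fitted tail/head slab thicknesses (Å) and the position of the
#'   first reflectivity minimum (Å⁻¹);
#' * `"epsilon"` - static compression modulus at 30 mN/m (mN/m).
#'
#' These serve as realistic inputs for the reporting utilities and for
#' worked examples; they are not recomputed by this package.
#'
#' @param which One of `"apl"`, `"thickness"`, `"xray"`, `"epsilon"`.
#' @return A tibble.
#' @examples
#' rbc_table("apl")
#' @export
rbc_table <- function(which = c("apl", "thickness", "xray", "epsilon")) {
  which <- match.arg(which)
  file <- system.file("extdata",
    paste0("rbc_", if (which %in% c("apl", "thickness")) which else {
      if (which == "xray") "xray" else "epsilon"
    }, ".csv"),
    package = "leafletlab"
  )
  readr::read_csv(file, show_col_types = FALSE, na = "NA")
}

#' Sterol-induced thickness increase ratio
#'
#' Quantifies how much more a reference sterol thickens a lipid species
#' than a comparison sterol does, both measured against the sterol-free
#' composition: \eqn{(d_{chol} - d_{nchol}) / (d_{kchol} - d_{nchol})}.
#'
#' @param thickness A thickness table in the layout of
#'   `rbc_table("thickness")`.
#' @param species Lipid species name.
#' @param measure `"tail"`, `"head"` or `"total"`.
#' @param numerator,denominator Column names of the two sterol systems
#'   compared (both against `baseline`).
#' @param baseline Column name of the sterol-free system.
#' @return The increase ratio (dimensionless).
#' @examples
#' thickness_increase_ratio(rbc_table("thickness"), "PSM") # 3.0
#' @export
thickness_increase_ratio <- function(thickness, species, measure = "tail",
                                     numerator = "chol", denominator = "kchol",
                                     baseline = "nchol") {
  row <- thickness[thickness$species == species & thickness$measure == measure, ]
  if (nrow(row) != 1L) abort("species/measure not found in the table")
  num <- row[[numerator]] - row[[baseline]]
  den <- row[[denominator]] - row[[baseline]]
  if (den == 0) abort("zero denominator: comparison sterol has no effect")
  num / den
}

#' Area-per-lipid change between compositions
#'
#' Percentage change of a species' mean area per lipid between two
#' compositions, e.g. how much 7-ketocholesterol expands PSM relative
#' to the sterol-free monolayer.
#'
#' @param apl An area table in the layout of `rbc_table("apl")`.
#' @param species Lipid species name.
#' @param from,to Column names of the compositions compared.
#' @return Percentage change, 100·(to − from)/from.
#' @examples
#' apl_change_percent(rbc_table("apl"), "PSM") # ~6
#' @export
apl_change_percent <- function(apl, species, from = "nchol", to = "kchol") {
  row <- apl[apl$species == species, ]
  if (nrow(row) != 1L) abort("species not found in the table")
  100 * (row[[to]] - row[[from]]) / row[[from]]
}

#' Static stiffening ratio between compositions
#'
#' Ratio of static compression moduli of two compositions at the same
#' surface pressure.
#'
#' @param epsilon A modulus table in the layout of
#'   `rbc_table("epsilon")`.
#' @param numerator,denominator System labels.
#' @param pressure Surface pressure at which to compare, mN/m.
#' @return The modulus ratio.
#' @examples
#' stiffening_ratio(rbc_table("epsilon")) # ~1.7
#' @export
stiffening_ratio <- function(epsilon, numerator = "kchol",
                             denominator = "chol", pressure = 30) {
  num <- epsilon[epsilon$system == numerator & epsilon$pressure == pressure, ]
  den <- epsilon[epsilon$system == denominator & epsilon$pressure == pressure, ]
  if (nrow(num) != 1L || nrow(den) != 1L) abort("system/pressure not found")
  num$epsilon / den$epsilon
}

#' Lattice d-spacing from a Bragg peak position
#'
#' @param q0 Peak position, Å⁻¹.
#' @return d = 2π/q0, Å.
#' @examples
#' d_spacing(1.5036)
#' @export
d_spacing <- function(q0) {
  if (any(q0 <= 0)) abort("q0 must be positive")
  2 * pi / q0
}
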