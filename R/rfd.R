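#' Human equivalent dose by allometric body-weight scaling
#'
#' Daily oral doses scale across species as body weight to the 3/4 power,
#' so the per-kg dose converts by `(animal_bw / human_bw)^(1/4)`. The animal
#' body weight is a required input and should always be reported alongside
#' the result; `species_default_bw()` offers conventional values.
#'
#' @param pod Point of departure (e.g. a BMDL) in mg/kg/day.
#' @param animal_bw Animal body weight, kg.
#' @param human_bw Human body weight, kg (default 70).
#' @return HED in mg/kg/day.
#' @examples
#' hed(6.3, animal_bw = 0.29) # ~1.6
#' @export
hed <- function(pod, animal_bw, human_bw = 70) {
  stopifnot(pod > 0, animal_bw > 0, human_bw > 0)
  pod * (animal_bw / human_bw)^0.25
}

#' @rdname hed
#' @param species One of the tabulated study types.
#' @export
species_default_bw <- function(species = c("rat_chronic", "rat_subchronic",
                                           "rat_developmental", "mouse_chronic",
                                           "mouse_subchronic")) {
  species <- match.arg(species)
  c(rat_chronic = 0.25, rat_subchronic = 0.267, rat_developmental = 0.28,
    mouse_chronic = 0.035, mouse_subchronic = 0.0385)[[species]]
}

#' Composite uncertainty factor on the half-log convention
#'
#' Individual factors take values 1, 3 or 10, where "3" denotes a half-log
#' unit (10^0.5). The composite is assembled in log10 space: each 3
#' contributes 0.5 and each 10 contributes 1, so {3, 10, 3} composes to
#' 10^2 = 100 (not the literal product 90).
#'
#' @param ufs Numeric vector (or named vector, e.g.
#'   `c(a = 3, h = 10, d = 3)`) with elements in {1, 3, 10}.
#' @return The composite factor (a power of 10^0.5).
#' @examples
#' composite_uf(c(3, 10, 3)) # 100
#' @export
composite_uf <- function(ufs) {
  if (!all(ufs %in% c(1, 3, 10))) {
    abort("uncertainty factors must each be 1, 3 (half-log) or 10")
  }
  halves <- c(`1` = 0, `3` = 0.5, `10` = 1)[as.character(ufs)]
  10^sum(halves)
}

#' Deterministic reference dose
#'
#' `RfD = HED / (UF_A x UF_H x UF_S x UF_D)` with the composite built on the
#' half-log convention. Reference doses are conventionally reported to one
#' significant figure; both the raw and the reported value are returned.
#'
#' @param hed_value Human equivalent dose, mg/kg/day.
#' @param ufs Uncertainty factors, as for [composite_uf()].
#' @return A list with `raw`, `reported` (1 significant figure),
#'   `composite_uf` and the inputs.
#' @examples
#' derive_rfd(1.6, c(a = 3, h = 10, d = 3)) # raw 0.016, reported 0.02
#' @export
derive_rfd <- function(hed_value, ufs) {
  stopifnot(hed_value > 0)
  cu <- composite_uf(ufs)
  raw <- hed_value / cu
  list(raw = raw, reported = signif1(raw), composite_uf = cu,
       hed = hed_value, ufs = ufs)
}

#' Maximum contaminant level goal for drinking water
#'
#' `MCLG = RfD x BW x RSC / intake`, converted from mg/L to ug/L. Defaults
#' are the standard adult exposure assumptions: 70 kg body weight, 2 L/day
#' drinking water, 20% relative source contribution.
#'
#' @param rfd Reference dose, mg/kg/day.
#' @param body_weight Body weight, kg.
#' @param drinking_water_intake Intake, L/day.
#' @param rsc Relative source contribution, fraction in (0, 1].
#' @return MCLG in ug/L.
#' @examples
#' mclg(0.01) # 70
#' @export
mclg <- function(rfd, body_weight = 70, drinking_water_intake = 2, rsc = 0.2) {
  stopifnot(rfd > 0, body_weight > 0, drinking_water_intake > 0,
            rsc > 0, rsc <= 1)
  1000 * rfd * body_weight * rsc / drinking_water_intake
}
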