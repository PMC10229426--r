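#' Calcium-indicator brightness model
#'
#' One-site (Hill) binding model for a calcium-modulated bioluminescent
#' indicator: light output rises from the apo brightness (multiplier 1) to
#' `dynamic_range` times that at saturating calcium. Defaults correspond to
#' the CaMBI110 indicator: an eightfold response to calcium with a 110 nM
#' dissociation constant and one-site binding.
#'
#' @param kd Dissociation constant in nM (> 0).
#' @param dynamic_range Saturated-to-apo brightness ratio (>= 1).
#' @param hill_n Hill coefficient (> 0); 1 for one-site binding.
#' @return An object of class `calcium_indicator`.
#' @export
calcium_indicator <- function(kd = 110, dynamic_range = 8, hill_n = 1) {
  if (kd <= 0) stop("`kd` must be > 0")
  if (dynamic_range < 1) stop("`dynamic_range` must be >= 1")
  if (hill_n <= 0) stop("`hill_n` must be > 0")
  structure(list(kd = kd, dynamic_range = dynamic_range, hill_n = hill_n),
            class = "calcium_indicator")
}

#' Brightness multiplier at a given calcium concentration
#'
#' Evaluates `1 + (dynamic_range - 1) * ca^n / (ca^n + kd^n)`: the factor by
#' which indicator light output exceeds the calcium-free state. The result is
#' monotonically nondecreasing in `ca` and bounded in
#' `[1, dynamic_range]`; `ca = Inf` returns `dynamic_range` exactly.
#'
#' @param ca Calcium concentration(s) in nM (>= 0; `Inf` allowed).
#' @param model A [calcium_indicator()] object.
#' @return Brightness multiplier(s), same length as `ca`.
#' @examples
#' m <- calcium_indicator()
#' calcium_to_brightness(c(0, 110, Inf), m)  # 1, 4.5, 8
#' @export
calcium_to_brightness <- function(ca, model = calcium_indicator()) {
  stopifnot(inherits(model, "calcium_indicator"))
  if (any(is.na(ca)) || any(ca < 0)) {
    stop("calcium concentration must be nonnegative")
  }
  frac <- ifelse(is.infinite(ca), 1,
                 ca^model$hill_n / (ca^model$hill_n + model$kd^model$hill_n))
  1 + (model$dynamic_range - 1) * frac
}
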