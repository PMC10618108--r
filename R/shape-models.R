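#' Shape-conversion helpers for reporting organelle dimensions
#'
#' Small organelle volumes are conventionally communicated as the diameter
#' of the equivalent sphere, or as the length of an equivalent cylinder
#' with hemispherical caps at a stated cap diameter.
#'
#' `sphere_diameter_from_volume()` inverts `v = (pi/6) d^3`, giving
#' `d = (6 v / pi)^(1/3)`; with `round_nm = TRUE` it rounds to the nearest
#' integer nanometre as printed reports do (a 0.0001 um^3 organelle reads
#' as 58 nm).
#'
#' `spherocylinder_length_from_volume()` inverts the capped-cylinder volume
#' at fixed cap diameter `d`: `L = 2r + (v - (4/3) pi r^3) / (pi r^2)` with
#' `r = d/2`. The volume must be at least that of the cap sphere, otherwise
#' no such cylinder exists. Note that for a 50 nm cap diameter the formula
#' assigns 340 nm of length to a volume of about 0.000635 um^3, not to
#' 0.00025 um^3; the function exposes the exact closed form.
#'
#' @param v_nm3 Volume in nm^3, `> 0` (and at least the cap-sphere volume
#'   for the cylinder form). Vectorised.
#' @param d_nm Cap diameter in nm, `> 0`.
#' @param round_nm Round the reported diameter to whole nanometres?
#' @return Diameter or total tip-to-tip length, nm.
#' @examples
#' sphere_diameter_from_volume(um3_to_nm3(0.0001), round_nm = TRUE) # 58
#' spherocylinder_length_from_volume(634864, d_nm = 50) # 340 nm
#' @export
sphere_diameter_from_volume <- function(v_nm3, round_nm = FALSE) {
  if (any(!is.finite(v_nm3)) || any(v_nm3 <= 0)) {
    abort("volume must be finite and > 0")
  }
  d <- (6 * v_nm3 / pi)^(1 / 3)
  if (round_nm) round(d) else d
}

#' @rdname sphere_diameter_from_volume
#' @export
spherocylinder_length_from_volume <- function(v_nm3, d_nm) {
  if (any(!is.finite(d_nm)) || any(d_nm <= 0)) {
    abort("cap diameter must be finite and > 0")
  }
  r <- d_nm / 2
  v_cap <- 4 / 3 * pi * r^3
  if (any(!is.finite(v_nm3)) || any(v_nm3 < v_cap - 1e-9)) {
    abort("volume below the cap-sphere volume: no valid capped cylinder")
  }
  2 * r + pmax(0, v_nm3 - v_cap) / (pi * r^2)
}
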