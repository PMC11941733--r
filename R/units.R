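#' Unit conversion constants and helpers
#'
#' All geometry is carried in millimetres and pressures in mmHg at the user
#' interface; the finite-element core works in SI (m, Pa, N) to keep the
#' elasticity arithmetic free of mixed-unit bugs.
#'
#' @name units
NULL

# 1 mmHg in Pa; fixed, not a tunable
MMHG_TO_PA <- 133.322

#' Convert pressure between mmHg, kPa and Pa
#'
#' @param x numeric pressure values.
#' @param from,to one of `"mmHg"`, `"kPa"`, `"Pa"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_pressure(77, "mmHg", "Pa") # 10265.8 Pa
#' @export
convert_pressure <- function(x, from = "mmHg", to = "Pa") {
  from <- match.arg(from, c("mmHg", "kPa", "Pa"))
  to <- match.arg(to, c("mmHg", "kPa", "Pa"))
  pa <- switch(from, mmHg = x * MMHG_TO_PA, kPa = x * 1000, Pa = x)
  switch(to, mmHg = pa / MMHG_TO_PA, kPa = pa / 1000, Pa = pa)
}
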