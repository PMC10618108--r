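#' Unit conversions between cubic nanometres and cubic micrometres
#'
#' All lengths inside the package are nanometres and all volumes cubic
#' nanometres; micrometre-scale values appear only at input/output
#' boundaries, through these explicit converters (1 um^3 = 1e9 nm^3).
#'
#' @param x Numeric vector of volumes.
#' @return Numeric vector in the target unit.
#' @examples
#' nm3_to_um3(1e9) # 1
#' um3_to_nm3(0.0038)
#' @export
nm3_to_um3 <- function(x) x / 1e9

#' @rdname nm3_to_um3
#' @export
um3_to_nm3 <- function(x) x * 1e9

# format-version tag written into every CSV the pipeline emits
ms_format_version <- function() "1"

# Evaluate code under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never clobber the
# user's stream.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream derivation: every cell (or stack, or section)
# gets an independent seed keyed by an index, so generation order does not
# matter. Arithmetic in doubles stays exact (< 2^53) and the result fits a
# 32-bit integer as set.seed requires.
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(index) * 1299721) %% 2147483647)
}
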