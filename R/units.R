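## Unit conversion constants, pinned in one place.
## Internal energies are Hartree, internal lengths Bohr; geometry I/O is in
## Angstrom (the XYZ convention).

.BOHR_PER_ANGSTROM <- 1 / 0.529177210903

#' Bohr per Angstrom conversion constant
#'
#' The single pinned conversion constant used throughout the package
#' (CODATA 2018 Bohr radius, 0.529177210903 Angstrom).
#'
#' @return Number of Bohr in one Angstrom (about 1.8897).
#' @export
#' @examples
#' units_bohr_per_angstrom() * 0.529177210903  # = 1
units_bohr_per_angstrom <- function() .BOHR_PER_ANGSTROM

## Run an expression with a private RNG stream: the global .Random.seed is
## saved and restored, so library code never perturbs user random state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a per-member child seed from a base seed, kept inside 32-bit range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 7919) %% 2147483629)
}
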