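#' @keywords internal
"_PACKAGE"

## Physical constants used throughout the package.
## Units are SI at the computation boundary: J, mol, K, Pa, m3.

#' Ideal gas constant, J mol^-1 K^-1
#' @export
RGAS <- 8.314462

#' Atmospheric reference pressure, Pa
#' @export
P_ATM <- 101325

## IUPAC 2021 standard atomic weights (conventional values) for the elements
## that occur in small drug molecules.  Used to derive molar masses from
## empirical formulas so that property cards never carry a transcribed mass.
.ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998403163,
  P = 30.973761998, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.90447
)

#' Molar mass from an empirical formula
#'
#' Parses a Hill-style empirical formula such as `"C24H29N7O2"` and sums
#' IUPAC 2021 conventional atomic weights.
#'
#' @param formula character scalar, e.g. `"C24H29N7O2"`.
#' @return molar mass in g mol^-1.
#' @examples
#' molar_mass("CO2")      # 44.009
#' molar_mass("C24H29N7O2")
#' @export
molar_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop_scsolub("parse_error", sprintf("cannot parse formula '%s'", formula))
  }
  total <- 0
  for (tok in tokens) {
    el <- sub("[0-9]+$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.ATOMIC_WEIGHTS)) {
      stop_scsolub("parse_error", sprintf("unknown element '%s'", el))
    }
    w <- .ATOMIC_WEIGHTS[[el]]
    total <- total + n * w
  }
  total
}

## Pure-CO2 constants (standard literature values; the solvent card built from
## these is editable by the user -- see solvent_card()).
.CO2_CONSTANTS <- list(
  molar_mass = 44.01,          # g/mol
  critical_temperature = 304.21,  # K
  critical_pressure = 7.383,      # MPa
  acentric_factor = 0.2236
)
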