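#' Parse a dimensioned quantity to internal SI units
#'
#' Configuration values may carry a unit suffix (`"1 mM"`, `"1.45e7 /mL"`,
#' `"40 min"`); bare numbers are taken to be already in the internal
#' convention (mol/L, seconds, cells/L, litres). All model code works in
#' SI-molar and seconds; conversion happens only at this boundary.
#'
#' @param x a number, or a string `"<number> <unit>"`.
#' @param kind one of `"concentration"`, `"time"`, `"density"`, `"volume"`,
#'   `"rate"` — restricts which units are accepted.
#' @return a numeric scalar in mol/L, s, cells/L or L.
#' @examples
#' parse_quantity("1.5 uM", "concentration")   # 1.5e-06
#' parse_quantity("1.45e7 /mL", "density")     # 1.45e+10
#' parse_quantity("40 min", "time")            # 2400
#' @export
parse_quantity <- function(x, kind = c("concentration", "time", "density",
                                       "volume", "rate")) {
  kind <- match.arg(kind)
  if (is.numeric(x)) {
    if (length(x) != 1L || !is.finite(x))
      stop("quantity must be a single finite number", call. = FALSE)
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L)
    stop("quantity must be a number or a '<value> <unit>' string", call. = FALSE)
  s <- trimws(x)
  m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*(.*)$", s))[[1]]
  if (length(m) != 3L || is.na(suppressWarnings(as.numeric(m[2]))))
    stop("cannot parse quantity: '", x, "'", call. = FALSE)
  value <- as.numeric(m[2])
  unit <- m[3]
  if (unit == "") return(value)
  scale <- switch(kind,
    concentration = c("M" = 1, "mol/L" = 1, "mM" = 1e-3, "uM" = 1e-6,
                      "µM" = 1e-6, "nM" = 1e-9)[unit],
    time = c("s" = 1, "ms" = 1e-3, "min" = 60, "h" = 3600)[unit],
    density = c("/L" = 1, "cells/L" = 1, "/mL" = 1e3, "cells/mL" = 1e3,
                "/ml" = 1e3)[unit],
    volume = c("L" = 1, "mL" = 1e-3, "ml" = 1e-3, "uL" = 1e-6)[unit],
    rate = c("/s" = 1, "1/s" = 1, "s-1" = 1)[unit]
  )
  if (is.na(scale))
    stop("unknown ", kind, " unit '", unit, "' in '", x, "'", call. = FALSE)
  value * unname(scale)
}
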