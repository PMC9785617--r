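# Unit-suffixed quantity parsing for configuration files.
#
# Internally everything is SI (m, s, kg, Pa.s, K). Config files may carry the
# mixed units in which device dimensions and flows are usually quoted
# (um, mm/s, mPa.s, uL/min) to avoid transcription slips.

.unit_table <- c(
  "m" = 1, "mm" = 1e-3, "um" = 1e-6, "µm" = 1e-6, "nm" = 1e-9, "pm" = 1e-12,
  "m/s" = 1, "mm/s" = 1e-3, "um/s" = 1e-6,
  "s" = 1, "ms" = 1e-3, "min" = 60,
  "kg/m3" = 1, "kg/m^3" = 1,
  "Pa.s" = 1, "Pa*s" = 1, "mPa.s" = 1e-3, "mPa*s" = 1e-3,
  "K" = 1,
  "m/s2" = 1, "m/s^2" = 1,
  "J/(kg.K)" = 1, "J/(kg*K)" = 1, "J/kg/K" = 1
)

#' Parse a quantity with an optional unit suffix into SI
#'
#' Accepts a bare number (assumed SI) or a string such as `"100 um"`,
#' `"0.3 mm/s"` or `"0.718 mPa.s"`.
#'
#' @param x A number or a `"<value> <unit>"` string.
#' @param what Field name used in error messages.
#' @return A numeric scalar in SI units.
#' @examples
#' parse_quantity("100 um")   # 1e-4
#' parse_quantity("0.3 mm/s") # 3e-4
#' @export
parse_quantity <- function(x, what = "quantity") {
  if (is.numeric(x)) {
    if (length(x) != 1L || !is.finite(x)) {
      abort(sprintf("`%s` must be a single finite number.", what))
    }
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L) {
    abort(sprintf("`%s` must be a number or a '<value> <unit>' string.", what))
  }
  s <- trimws(x)
  m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*(.*)$", s))[[1]]
  if (length(m) != 3L || is.na(suppressWarnings(as.numeric(m[2])))) {
    abort(sprintf("Cannot parse `%s` value '%s'.", what, x))
  }
  val <- as.numeric(m[2])
  unit <- trimws(m[3])
  if (unit == "") return(val)
  if (!unit %in% names(.unit_table)) {
    abort(sprintf("Unknown unit '%s' in `%s`; known units: %s.",
                  unit, what, paste(names(.unit_table), collapse = ", ")))
  }
  val * .unit_table[[unit]]
}

# internal shorthand used by constructors
.q <- function(x, what) parse_quantity(x, what)

.check_pos <- function(x, what, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    abort(sprintf("`%s` must be a %s finite number (got %s).",
                  what, if (strict) "positive" else "non-negative",
                  format(x)))
  }
  invisible(x)
}
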