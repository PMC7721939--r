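# Classed conditions so callers (and the CLI) can branch on failure type.
y90Stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "y90Error")))
}

y90Warn <- function(fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...), class = "y90Warning"))
}

# scalar sanity used by most numeric entry points
assertScalar <- function(x, name, lower = -Inf, upper = Inf,
                         openLower = FALSE, openUpper = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && is.finite(x) &&
    (if (openLower) x > lower else x >= lower) &&
    (if (openUpper) x < upper else x <= upper)
  if (!ok)
    y90Stop("y90_invalid_argument",
            "%s must be a finite scalar in %s%g, %g%s (got %s)",
            name, if (openLower) "(" else "[", lower, upper,
            if (openUpper) ")" else "]",
            paste(format(x), collapse = ", "))
  invisible(x)
}

sameGeometry <- function(a, b, tolRel = 1e-6) {
  all(a@shape == b@shape) &&
    all(abs(a@spacingMM - b@spacingMM) <= tolRel * b@spacingMM)
}

checkMask <- function(mask, geom, name = "mask") {
  if (!is.logical(mask) || length(dim(mask)) != 3L ||
      !all(dim(mask) == geom@shape))
    y90Stop("y90_geometry_mismatch",
            "%s must be a logical array matching the grid (%s)",
            name, paste(geom@shape, collapse = "x"))
  invisible(mask)
}
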