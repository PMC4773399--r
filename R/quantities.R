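## Unit registry and conversions. A unit converts to its dimension's base
## unit affinely: base_value = value * factor + offset (offset is non-zero
## only for the absolute temperature scales). Symbols are case-sensitive
## UTF-8; "C" is deliberately not an alias for "°C".

.baseRegistry <- function() {
    data.frame(
        symbol = c("m", "mm", "µm", "nm",
                   "s", "ms", "µs",
                   "K", "°C", "°F",
                   "V", "mV", "Pa", "bar", "Hz",
                   "rad", "deg", ""),
        dimension = c(rep("length", 4), rep("time", 3), rep("temperature", 3),
                      "electric-potential", "electric-potential",
                      "pressure", "pressure", "frequency",
                      "angle", "angle", "dimensionless"),
        factor = c(1, 1e-3, 1e-6, 1e-9,
                   1, 1e-3, 1e-6,
                   1, 1, 5 / 9,
                   1, 1e-3, 1, 1e5, 1,
                   1, pi / 180, 1),
        offset = c(rep(0, 7), 0, 273.15, 459.67 * 5 / 9,
                   rep(0, 5), 0, 0, 0),
        stringsAsFactors = FALSE)
}

.chemistryRegistry <- function() {
    data.frame(symbol = c("M", "mM", "µM", "nM"),
               dimension = "amount-concentration",
               factor = c(1, 1e-3, 1e-6, 1e-9), offset = 0,
               stringsAsFactors = FALSE)
}

#' Unit registry
#'
#' The default registry covers SI base plus common microscopy units:
#' lengths (m, mm, µm, nm), times (s, ms, µs), absolute temperatures
#' (K, °C, °F), electric potential (V, mV), pressure (Pa, bar), frequency
#' (Hz), angle (rad, deg) and a dimensionless unit. Chemistry units
#' (molarity M, mM, µM, nM) are an optional extension, off by default.
#' A registry is a plain `data.frame` (symbol, dimension, factor, offset)
#' and can be written to / extended from a tab-separated table so
#' deployments can add units.
#'
#' @param chemistry Include the molarity extension.
#' @param path File path for reading/writing a registry table.
#' @param registry A registry `data.frame`.
#' @return A registry `data.frame`.
#' @examples
#' reg <- defaultUnitRegistry()
#' convertQuantity(quantity(37, "°C"), "K")   # 310.15 K
#' @export
defaultUnitRegistry <- function(chemistry = FALSE) {
    reg <- .baseRegistry()
    if (chemistry) reg <- rbind(reg, .chemistryRegistry())
    reg
}

#' @rdname defaultUnitRegistry
#' @export
writeUnitRegistry <- function(registry, path)
    utils::write.table(registry, path, sep = "\t", row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")

#' @rdname defaultUnitRegistry
#' @export
readUnitRegistry <- function(path) {
    reg <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = c("character", "character",
                                            "numeric", "numeric"),
                             quote = "", na.strings = character(),
                             fileEncoding = "UTF-8")
    stopifnot(identical(names(reg), c("symbol", "dimension", "factor", "offset")))
    reg
}

.lookupUnit <- function(unit, registry) {
    i <- which(registry$symbol == unit)
    if (length(i) != 1L)
        stop("registry error: unknown unit symbol '", unit, "'")
    registry[i, ]
}

#' Construct a quantity
#'
#' @param value Finite numeric value.
#' @param unit Unit symbol, resolved against the registry.
#' @param registry Unit registry (see [defaultUnitRegistry()]).
#' @return A [Quantity-class].
#' @export
quantity <- function(value, unit, registry = defaultUnitRegistry()) {
    row <- .lookupUnit(unit, registry)
    new("Quantity", value = as.numeric(value), unit = unit,
        dimension = row$dimension)
}

#' Parse a textual (value, unit) pair
#'
#' Whitespace-tolerant parsing of metadata like `("37", "°C")` into a
#' [Quantity-class].
#'
#' @param value_text Text that must parse as a real number.
#' @param unit_text Unit symbol (surrounding whitespace ignored).
#' @param registry Unit registry.
#' @return A [Quantity-class].
#' @export
parseQuantity <- function(value_text, unit_text, registry = defaultUnitRegistry()) {
    v <- suppressWarnings(as.numeric(trimws(value_text)))
    if (is.na(v)) stop("parse error: '", value_text, "' is not a number")
    quantity(v, trimws(unit_text), registry)
}

#' Convert a quantity to another unit
#'
#' Conversion goes through the dimension's base unit with the registry's
#' affine map `base = value * factor + offset`; cross-dimension conversion
#' is an error. The input quantity is unchanged.
#'
#' @param q A [Quantity-class].
#' @param target_unit Registered unit symbol of the same dimension.
#' @param registry Unit registry.
#' @return A new [Quantity-class] in `target_unit`.
#' @examples
#' convertQuantity(quantity(488, "nm"), "µm")  # 0.488 µm
#' @export
convertQuantity <- function(q, target_unit, registry = defaultUnitRegistry()) {
    from <- .lookupUnit(q@unit, registry)
    to <- .lookupUnit(target_unit, registry)
    if (from$dimension != to$dimension)
        stop("dimension error: cannot convert ", from$dimension, " to ",
             to$dimension)
    base <- q@value * from$factor + from$offset
    new("Quantity", value = (base - to$offset) / to$factor,
        unit = target_unit, dimension = to$dimension)
}
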