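#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Nearest-integer rounding with halves rounded away from zero, the rule used
#' for all lipid/solvent count roundings in this package. A small relative
#' guard (1e-9) snaps values that sit within floating-point noise of a .5
#' boundary onto it, so that quantities that are exactly half-integers in real
#' arithmetic (e.g. 36.3 / 0.6 = 60.5) round deterministically.
#'
#' @param x numeric vector
#' @return numeric vector of integers (as doubles)
#' @export
round_half_away <- function(x) {
  eps <- 1e-9 * pmax(1, abs(x))
  s <- ifelse(x < 0, -1, 1)
  s * floor(abs(x) + 0.5 + eps)
}

# floor with the same floating-point guard: values within 1e-9 (relative) below
# an integer are treated as that integer before flooring
floor_snap <- function(x) floor(x + 1e-9 * pmax(1, abs(x)))

#' Derive a stage seed from the master seed
#'
#' Each stochastic build stage draws its RNG seed from the master seed and the
#' stage name by a stable polynomial string hash, so the stage result does not
#' depend on which other stages run before it.
#'
#' @param master integer master seed
#' @param stage character stage name
#' @return integer seed in \[0, 2^31)
#' @export
child_seed <- function(master, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  h <- as.double(master) %% 2147483647
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

fmt_num <- function(x) sprintf("%.10g", x)

# diagnostic records used by validate_spec()
diagnostic <- function(level, field, message) {
  list(level = level, field = field, message = message)
}

is_fatal <- function(diags) {
  any(vapply(diags, function(d) identical(d$level, "fatal"), logical(1)))
}

stop_cg <- function(class, message) {
  stop(structure(class = c(class, "cgbuildr_error", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}
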