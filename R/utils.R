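# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# unit conversions used once at setup
PERM_M4NS_TO_MM4NS <- 1e12   # m^4/(N s)  ->  mm^4/(N s)
MM_S_TO_UM_S <- 1e3          # mm/s       ->  um/s
MONTH_DAYS <- 30             # "per month" rate constants -> per day

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE,
                         strict_hi = FALSE) {
  if (!is_number(x)) stopf("'%s' must be a single finite number", name)
  ok_lo <- if (strict_lo) x > lo else x >= lo
  ok_hi <- if (strict_hi) x < hi else x <= hi
  if (!ok_lo || !ok_hi) {
    stopf("'%s' = %g outside admissible range %s%g, %g%s", name, x,
          if (strict_lo) "(" else "[", lo, hi, if (strict_hi) ")" else "]")
  }
  invisible(x)
}
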