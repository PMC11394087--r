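# Internal helpers shared across modules.

# Half-up decimal rounding, matching how the study tables print percentages
# (R's round() rounds half to even, which disagrees with printed values such
# as 29.652 -> 29.7). The 1e-9 nudge absorbs binary-representation error in
# quantities like 100 * 3/24.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) & is.finite(x) & x >= 0 & abs(x - round(x)) < 1e-8

`%||%` <- function(a, b) if (is.null(a)) b else a
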