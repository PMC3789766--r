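# Small internal helpers shared across modules.

# round-half-up at `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# numeric parser tolerating the unicode minus sign used in typeset tables
parse_numeric <- function(x) {
  x <- gsub("−", "-", as.character(x))
  suppressWarnings(as.numeric(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
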