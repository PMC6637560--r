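# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() wrapper that never appends the call, keeping CLI errors readable
qstop <- function(...) stop(..., call. = FALSE)

qwarn <- function(...) warning(..., call. = FALSE)

# match.arg with a clearer error naming the offending field
match_enum <- function(value, choices, field, context = NULL) {
  if (length(value) != 1L || is.na(value) || !value %in% choices) {
    where <- if (is.null(context)) "" else paste0(" (", context, ")")
    qstop(sprintf("invalid %s%s: '%s' (must be one of: %s)",
                  field, where, paste(value, collapse = ","),
                  paste(choices, collapse = ", ")))
  }
  value
}

# sample mode of a discrete vector; ties between 0 and 1 resolve to 1,
# mirroring the >= 0.5 re-binarization convention
sample_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  tab <- table(x)
  winners <- as.numeric(names(tab)[tab == max(tab)])
  max(winners)
}

is_binary_values <- function(x) all(is.na(x) | x %in% c(0, 1))

# round for human-readable reports; machine outputs keep full precision
round2 <- function(x) round(x, 2)
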