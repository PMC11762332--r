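# internal helpers shared across modules

# Deterministic child seed from a master seed and string tags.
# Polynomial string hash folded into [0, 2^31 - 2]; stable across platforms.
child_seed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tags)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# population variance of a flattened matrix (sklearn's X.var())
pop_var <- function(x) {
  x <- as.numeric(x)
  mean((x - mean(x))^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
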