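# Small numeric helpers shared across modules.

#' Numerically stable log(1 + exp(x))
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @keywords internal
#' @noRd
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  mid <- x > 18 & x <= 33
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

# trapezoidal integral of y over x (sorted x)
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_wp <- function(..., class) {
  stop(structure(class = c(class, "wp_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
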