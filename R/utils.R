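# Internal error/condition helpers. All user-facing failures carry a
# condition class under "ipddta_error" so callers (and the CLI) can react
# to the *kind* of failure rather than matching message text.

ipd_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "ipddta_error")))
}

# A caution is a message with a dedicated class: analyses that are legal but
# statistically hazardous (e.g. per-study optimal thresholds) signal it so
# logs and tests can detect the warning banner without aborting.
ipd_caution <- function(message, class = "ipddta_caution") {
  cond <- structure(
    class = c(class, "ipddta_caution", "message", "condition"),
    list(message = paste0(message, "\n"), call = sys.call(-1))
  )
  message(cond)
}

ipd_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "ipddta_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw k rows from a bivariate normal with mean mu (length 2) and 2x2
# covariance Sigma, via the Cholesky factor.
rbvnorm <- function(k, mu, Sigma) {
  z <- matrix(rnorm(2 * k), k, 2)
  sweep(z %*% chol(Sigma), 2, mu, `+`)
}
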