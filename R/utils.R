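# Internal helpers shared across modules.

# Scalar numeric check with a readable error.
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed) || seed != trunc(seed)) {
    abort("`seed` is required and must be a single integer; generators never use global RNG state.")
  }
  as.integer(seed)
}

# Multiplicative Gaussian noise with coefficient of variation `cv`,
# evaluated under a local RNG scope so global state is untouched.
apply_cv_noise <- function(x, cv, seed) {
  if (cv == 0) return(x)
  withr::with_seed(seed, x * (1 + cv * rnorm(length(x))))
}

check_increasing <- function(x, name, strictly = TRUE) {
  d <- diff(x)
  bad <- if (strictly) any(d <= 0) else any(d < 0)
  if (length(x) && bad) {
    abort(sprintf("`%s` must be %sincreasing (duplicates or reversals found).",
                  name, if (strictly) "strictly " else ""))
  }
  invisible(x)
}

# Coefficient of determination without summary.lm's perfect-fit warning
# (noiseless synthetic data makes perfect fits a designed use here).
r_squared_lm <- function(fit) {
  r <- stats::residuals(fit)
  y <- r + stats::fitted(fit)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  max(0, min(1, 1 - sum(r^2) / tss))
}

new_fit <- function(fields, class) {
  structure(fields, class = c(class, "tauassay_fit"))
}

#' @export
print.tauassay_fit <- function(x, ...) {
  cat("<", class(x)[1L], ">\n", sep = "")
  print(glance(x), ...)
  invisible(x)
}
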