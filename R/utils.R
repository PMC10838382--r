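# internal validation helpers; error classes are stable API for callers

stop_domain <- function(msg, ...) {
  abort(msg, class = "effluxr_error_domain", ...)
}

stop_schema <- function(msg, ...) {
  abort(msg, class = "effluxr_error_schema", ...)
}

check_number <- function(x, name, positive = FALSE, non_negative = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x)) {
    stop_domain(sprintf("`%s` must be numeric.", name))
  }
  if (anyNA(x)) {
    stop_domain(sprintf("`%s` contains missing values.", name))
  }
  if (finite && any(!is.finite(x))) {
    stop_domain(sprintf("`%s` must be finite.", name))
  }
  if (positive && any(x <= 0)) {
    stop_domain(sprintf("`%s` must be strictly positive.", name))
  }
  if (non_negative && any(x < 0)) {
    stop_domain(sprintf("`%s` must be non-negative.", name))
  }
  invisible(x)
}

check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_schema(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# lognormal multiplicative noise with a given coefficient of variation
cv_noise <- function(n, cv) {
  if (cv <= 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = 0, sd = sdlog))
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
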