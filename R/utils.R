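#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_input("`%s` must be a single non-missing number", name)
  }
  if (finite && !is.finite(x)) stop_input("`%s` must be finite", name)
  invisible(x)
}

check_numeric_vector <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop_input("`%s` must be a non-empty numeric vector", name)
  }
  if (anyNA(x)) stop_input("`%s` contains missing values", name)
  if (finite && any(!is.finite(x))) stop_input("`%s` contains non-finite values", name)
  invisible(x)
}

# extdata lookup that works from the installed package
icusurv_extdata <- function(file) {
  path <- system.file("extdata", file, package = "icusurv")
  if (!nzchar(path)) stop_input("cannot locate extdata file '%s'", file)
  path
}

# Derive a reproducible child seed from a parent seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + as.double(offset)) %% 2147483629) + 1L
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
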