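#' @importFrom rlang %||% abort warn .data
#' @importFrom stats var sd median quantile rnorm runif rbinom rexp pnorm
#'   pchisq qnorm setNames complete.cases fft binomial coef predict
#' @importFrom utils head tail
NULL

# internal: stop with a message naming the offending argument/field
stop_field <- function(field, msg) {
  rlang::abort(paste0("invalid `", field, "`: ", msg), class = "perirad_validation_error")
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a single number in [0, 1]")
  x
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0)
    stop_field(field, "must be a single positive number")
  x
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stop_field(field, paste0("must be a single integer >= ", min))
  as.integer(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) stop_field(field, "must be TRUE or FALSE")
  x
}

# Binary labels arrive as 0/1, logical, or factor/character with the PD level
# named; everything funnels through here so "PD is the positive class" is
# decided in exactly one place.
as_binary_labels <- function(labels, positive = "PD") {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    u <- unique(labels[!is.na(labels)])
    if (!all(u %in% c(0, 1))) stop_field("labels", "numeric labels must be 0/1")
    return(as.integer(labels))
  }
  as.integer(as.character(labels) == positive)
}

# deterministic child seeds: keep everything under 2^31 - 1
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483647L)
}
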