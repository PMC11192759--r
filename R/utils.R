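#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# logistic and clamped logit used throughout the dynamics; the logit clamp keeps
# bias finite for nodes whose base activity sits on 0 or 1
sigmoid <- function(x) 1 / (1 + exp(-x))

clamped_logit <- function(p, eps = 1e-6) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# saturating transform of concentration: c / (1 + c), bounded in [0, 1)
conc_saturation <- function(conc) conc / (1 + conc)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg)
  invisible(TRUE)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
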