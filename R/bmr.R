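#' Benchmark response definitions
#'
#' A benchmark response (BMR) anchors the benchmark dose: the BMD is the dose
#' at which the fitted model produces this predefined change relative to
#' background. Conventions follow common regulatory practice:
#' `bmr_extra(0.10)` is 10% extra risk, `[P(d) - P(0)] / [1 - P(0)]`, the
#' default for quantal data; `bmr_added()` is added risk `P(d) - P(0)`;
#' `bmr_sd()` is a one-control-SD shift of a continuous mean; `bmr_rel(0.05)`
#' is a 5% change relative to the control mean (used for developmental
#' endpoints).
#'
#' @param level Response level: a fraction in (0, 1) for risk-based BMRs, a
#'   positive fraction for `bmr_rel()`, a positive number of SDs for `bmr_sd()`.
#' @return An object of class `bmr` with fields `kind` and `level`.
#' @examples
#' bmr_extra(0.10)
#' bmr_sd()
#' @export
bmr_extra <- function(level = 0.10) new_bmr("extra_risk", level)

#' @rdname bmr_extra
#' @export
bmr_added <- function(level = 0.10) new_bmr("added_risk", level)

#' @rdname bmr_extra
#' @export
bmr_sd <- function(level = 1) new_bmr("one_sd", level)

#' @rdname bmr_extra
#' @export
bmr_rel <- function(level = 0.05) new_bmr("relative_deviation", level)

new_bmr <- function(kind, level) {
  if (kind %in% c("extra_risk", "added_risk") && (level <= 0 || level >= 1)) {
    abort("risk-based BMR level must lie in (0, 1)")
  }
  if (kind %in% c("one_sd", "relative_deviation") && level <= 0) {
    abort("BMR level must be positive")
  }
  structure(list(kind = kind, level = level), class = "bmr")
}

#' @export
format.bmr <- function(x, ...) {
  switch(x$kind,
    extra_risk = sprintf("%g%% extra risk", 100 * x$level),
    added_risk = sprintf("%g%% added risk", 100 * x$level),
    one_sd = sprintf("%g control SD", x$level),
    relative_deviation = sprintf("%g%% relative deviation", 100 * x$level)
  )
}

#' @export
print.bmr <- function(x, ...) {
  cat("<bmr>", format(x), "\n")
  invisible(x)
}

as_bmr <- function(x) {
  if (inherits(x, "bmr")) return(x)
  abort("supply a benchmark response built with bmr_extra()/bmr_added()/bmr_sd()/bmr_rel()")
}
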