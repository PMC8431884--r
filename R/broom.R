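#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an accumulation curve
#'
#' @param x An [accumulation_curve()].
#' @param ... Unused.
#' @return The per-step tibble (`k`, `mean`, `sd`, `pct`) without the extra
#'   class/attributes.
#' @export
tidy.accumulation_curve <- function(x, ...) {
  tibble(k = x$k, mean = x$mean, sd = x$sd, pct = x$pct)
}

#' One-row summary of an accumulation curve
#'
#' @param x An [accumulation_curve()].
#' @param ... Unused.
#' @return Tibble with `unit_type`, `n_units`, `S_obs`, `S_hat`,
#'   `estimator`, `method`, `n_resamples`.
#' @export
glance.accumulation_curve <- function(x, ...) {
  tibble(unit_type = attr(x, "unit_type"), n_units = attr(x, "n_units"),
         S_obs = attr(x, "S_obs"), S_hat = attr(x, "S_hat"),
         estimator = attr(x, "estimator"), method = attr(x, "method"),
         n_resamples = attr(x, "n_resamples"))
}
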