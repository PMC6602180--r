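#' Tidy a personalisation fit
#'
#' @param x A `myelo_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter: `term`,
#'   `estimate`, `std.error` (natural scale) and `rse` (%).
#' @exportS3Method generics::tidy
tidy.myelo_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$covariance), 0))
  tibble(term = names(x$estimates), estimate = unname(x$estimates),
         std.error = unname(se), rse = unname(x$rse))
}

#' @rdname tidy.myelo_fit
#' @exportS3Method generics::glance
glance.myelo_fit <- function(x, ...) {
  tibble(model = x$problem$spec$id, n_cycles = length(x$problem$cycles),
         n_obs = x$n_obs, n_params = length(x$estimates),
         objective = x$objective, rmse = x$rmse, singular = x$singular)
}

#' Tidy a pooled PK fit
#'
#' @param x A `pk_fit`.
#' @param ... Unused.
#' @return A tibble with `term` (micro constants in 1/h, volumes in L,
#'   derived macro constants in L/h and L), `estimate` and `rse` (%).
#' @exportS3Method generics::tidy
tidy.pk_fit <- function(x, ...) {
  tibble(term = names(x$estimates), estimate = unname(x$estimates),
         rse = unname(x$rse[names(x$estimates)]))
}

#' @rdname tidy.pk_fit
#' @exportS3Method generics::glance
glance.pk_fit <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_params = 4, objective = x$objective,
         sigma = sqrt(x$objective / max(x$n_obs - 4, 1)),
         singular = x$singular)
}
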