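# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an endpoint comparison
#'
#' One row per endpoint: effect estimate with CI, test used, statistic,
#' degrees of freedom (Welch alongside the classical n1+n2-2 for unpaired
#' t-tests), two-sided p, and per-arm ns.
#'
#' @param x An `endpoint_result` from [compare_groups()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy endpoint_result
#' @export
tidy.endpoint_result <- function(x, ...) {
  tibble::tibble(
    endpoint = x$endpoint,
    test = x$test,
    estimate = x$estimate,
    conf_low = x$conf_low,
    conf_high = x$conf_high,
    statistic = x$statistic,
    df = x$df,
    df_classical = x$df_classical,
    p_value = x$p_value,
    n_x = x$summary_x$n,
    n_y = x$summary_y$n
  )
}

#' @rdname tidy.endpoint_result
#' @method glance endpoint_result
#' @export
glance.endpoint_result <- function(x, ...) {
  tibble::tibble(
    endpoint = x$endpoint, test = x$test, p_value = x$p_value,
    alpha_gate = x$alpha_gate, degenerate = x$degenerate,
    gate_checks = nrow(x$gate)
  )
}

#' Tidy the daily-activity mixed model
#'
#' @param x An `activity_model` from [fit_activity_model()].
#' @param ... Unused.
#' @return `tidy()`: one row per fixed effect (estimate, SE, Wald CI);
#'   `glance()`: one row with the interaction contrast, variance components
#'   and fit sizes.
#' @method tidy activity_model
#' @export
tidy.activity_model <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.activity_model
#' @method glance activity_model
#' @export
glance.activity_model <- function(x, ...) {
  ia <- x$coefficients[x$coefficients$term == x$interaction_term, ]
  tibble::tibble(
    interaction = ia$estimate,
    interaction_conf_low = ia$conf_low,
    interaction_conf_high = ia$conf_high,
    var_dog = x$var_dog,
    var_residual = x$var_residual,
    n_dogs = x$n_dogs,
    n_observations = x$n_observations,
    singular = x$singular
  )
}
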