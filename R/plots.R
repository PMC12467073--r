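#' Plot a loading trace
#'
#' Force-time or cumulative-work-time view of one or more traces. Pass a
#' named list of traces to overlay slow/fast (or small/large) loading
#' conditions on one panel.
#'
#' @param object A `kv_trace`, or a named list of them.
#' @param what `"force"` for F(t), `"work"` for cumulative W(t) with the
#'   elastic/viscous/total components as separate lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' p <- kv_params(k = 1000, eta = 50)
#' traces <- list(
#'   slow = sample_trace(linear_ramp(0.02, 2.0, n = 201), p),
#'   fast = sample_trace(linear_ramp(0.02, 0.5, n = 201), p))
#' autoplot(traces$slow)
#' plot_traces(traces, what = "work")
#' @export
plot_traces <- function(object, what = c("force", "work"), ...) {
  what <- match.arg(what)
  if (inherits(object, "kv_trace")) object <- list(trace = object)
  stopifnot(is.list(object), length(object) > 0)
  if (is.null(names(object))) names(object) <- paste0("trace", seq_along(object))
  df <- purrr::imap(object, function(tr, nm) {
    tibble::tibble(condition = nm, t = tr$t, F = tr$F,
                   elastic = tr$w_el, viscous = tr$w_visc,
                   total = tr$w_total)
  }) |> purrr::list_rbind()

  if (what == "force") {
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$F,
                                       colour = .data$condition)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "time (s)", y = "force (N)",
                      colour = NULL,
                      title = "Kelvin–Voigt force under ramp loading") +
        ggplot2::theme_minimal())
  }
  long <- tidyr::pivot_longer(df, c("elastic", "viscous", "total"),
                              names_to = "component", values_to = "w")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$w,
                                     colour = .data$condition,
                                     linetype = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "cumulative work (J)",
                  colour = NULL, linetype = NULL,
                  title = "Cumulative work partition under ramp loading") +
    ggplot2::theme_minimal()
}

#' @rdname plot_traces
#' @method autoplot kv_trace
#' @export
autoplot.kv_trace <- function(object, what = c("force", "work"), ...) {
  plot_traces(object, what = what)
}

#' Bar chart of an energy-budget table
#'
#' Elastic vs viscous energy per scenario, on a log scale when the
#' energies span orders of magnitude (as nanoparticle scenarios do).
#'
#' @param data A tibble with columns `label`, `w_el`, `w_visc`, e.g. from
#'   [np_scenarios()] or [worked_example_np()].
#' @param log_scale Use a log10 energy axis (default `TRUE`).
#' @return A ggplot object.
#' @examples
#' plot_budgets(np_scenarios(n = 101))
#' @export
plot_budgets <- function(data, log_scale = TRUE) {
  stopifnot(all(c("label", "w_el", "w_visc") %in% names(data)))
  long <- tidyr::pivot_longer(data[c("label", "w_el", "w_visc")],
                              c("w_el", "w_visc"),
                              names_to = "component", values_to = "w")
  long$component <- c(w_el = "elastic", w_visc = "viscous")[long$component]
  g <- ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$w,
                                          fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "energy (J)", fill = NULL,
                  title = "Elastic storage vs viscous dissipation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
  if (log_scale) g <- g + ggplot2::scale_y_log10()
  g
}

#' @method autoplot ramp_protocol
#' @export
#' @rdname plot_traces
autoplot.ramp_protocol <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$x)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "displacement (m)",
                  title = "Linear displacement ramp") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
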