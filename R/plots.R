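#' Plot an MC run's observable time series
#'
#' Order parameters P (loop formation) and S (symmetry breaking) plus the
#' per-species largest-aggregate fractions against MC sweeps.
#'
#' @param object An `mc_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mc_run <- function(object, ...) {
  d <- object$series |>
    select("sweep", "P", "S", "cluster_A", "cluster_B") |>
    tidyr::pivot_longer(-"sweep", names_to = "observable")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sweep, y = .data$value,
                                  colour = .data$observable)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "MC sweep", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phase scan
#'
#' Order-parameter means with replicate standard errors along the scanned
#' axis (the first axis when several were crossed), on a log axis when the
#' values span more than a decade.  For conformation scans the response is
#' `P_mean`; for symmetry-breaking scans `S_abs_mean`.
#'
#' @param object A `phase_scan`.
#' @param response Response column (default chosen from the scan's init).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_scan <- function(object, response = NULL, ...) {
  axis <- attr(object, "axes")[1]
  response <- response %||%
    if (identical(attr(object, "init"), "looped")) "S_abs_mean" else "P_mean"
  se_col <- sub("_mean$", "_se", response)
  d <- as_tibble(object)
  has_se <- se_col %in% names(d)
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[axis]],
                                       y = .data[[response]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point()
  if (has_se) {
    g <- g + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data[[response]] - .data[[se_col]],
                   ymax = .data[[response]] + .data[[se_col]]),
      width = 0
    )
  }
  xv <- d[[axis]]
  if (min(xv) > 0 && max(xv) / min(xv) > 10) {
    g <- g + ggplot2::scale_x_log10()
  }
  g + ggplot2::labs(x = axis, y = response) + ggplot2::theme_minimal()
}
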