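#' Plot cumulative incidence curves
#'
#' Cumulative incidence Q(age) for one or more curves (typically the four
#' genes of one endpoint), the characteristic S-shaped penetrance display.
#' Cosmetic helper; requires ggplot2.
#'
#' @param curves a `cuminc_curve` or list of them.
#' @return A ggplot object.
#' @export
plot_cumulative_incidence <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_cumulative_incidence requires ggplot2", call. = FALSE)
  }
  if (inherits(curves, "cuminc_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(gene = cv$gene, endpoint = cv$endpoint,
               age = cv$age, q = cv$q, stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$q,
                                   colour = .data$gene,
                                   linetype = .data$endpoint)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Age (years)", y = "Cumulative incidence Q(age)") +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan-Meier crude survival curve
#'
#' @param curve a `km_curve`.
#' @return A ggplot object.
#' @export
plot_survival <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_survival requires ggplot2", call. = FALSE)
  }
  df <- data.frame(time = c(0, curve$time), surv = c(1, curve$surv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years since diagnosis", y = "Crude survival") +
    ggplot2::theme_minimal()
}
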