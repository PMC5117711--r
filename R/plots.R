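#' Plot epistasis against inter-site distance
#'
#' Scatter of the epistasis statistic versus the distance between the
#' mutated sites in the initial reference fold, with the direct-contact
#' threshold `1.5 * l` marked.
#'
#' @param records An `epistasis_records` tibble with `R` values.
#' @param l Bond length in Angstroms (contact threshold `1.5 * l`).
#' @return A ggplot object.
#' @export
plot_epistasis_distance <- function(records, l = 3.8) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$R, y = .data$eps)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 1.5 * l, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "inter-site distance R (Å)",
                  y = expression(epsilon))
}

#' @rdname plot_epistasis_distance
#' @param object An `epistasis_records` tibble.
#' @param ... Unused.
#' @export
autoplot.epistasis_records <- function(object, l = 3.8, ...) {
  plot_epistasis_distance(object, l)
}

#' Plot an epistasis distribution with its Gaussian fit
#'
#' @param summary An [summarize_epistasis()] result.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_epsilon_distribution <- function(summary, bins = 20) {
  df <- tibble(eps = summary$eps)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eps)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey70", color = "grey30") +
    ggplot2::stat_function(
      fun = dnorm,
      args = list(mean = summary$mean, sd = max(summary$sigma_mle, 1e-12))) +
    ggplot2::labs(x = expression(epsilon), y = "density")
}

#' @rdname plot_epsilon_distribution
#' @param object An `epistasis_summary`.
#' @param ... Unused.
#' @export
autoplot.epistasis_summary <- function(object, bins = 20, ...) {
  plot_epsilon_distribution(object, bins)
}

#' Plot a fitness distribution
#'
#' Histogram of repeated fitness measurements with a Gaussian overlay at
#' the sample mean and width.
#'
#' @param P Numeric vector of fitness values.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_fitness_distribution <- function(P, bins = 20) {
  fe <- fitness_error(P)
  ggplot2::ggplot(tibble(P = P), ggplot2::aes(x = .data$P)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey70", color = "grey30") +
    ggplot2::stat_function(fun = dnorm,
                           args = list(mean = fe$mean,
                                       sd = max(fe$sigma, 1e-12))) +
    ggplot2::labs(x = "fitness P", y = "density")
}

#' Plot the per-monomer order profile of a reference fold
#'
#' @param object A `reference_fold`.
#' @param ... Unused.
#' @return A ggplot object with the Lindemann threshold marked.
#' @export
autoplot.reference_fold <- function(object, ...) {
  df <- tibble(monomer = seq_along(object$rmsf), rmsf = object$rmsf,
               ordered = object$ordered_mask)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$monomer, y = .data$rmsf,
                                   fill = .data$ordered)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$lindemann_c * object$l,
                        linetype = "dashed") +
    ggplot2::labs(x = "monomer", y = "RMSF (Å)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
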