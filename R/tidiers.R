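#' Turn a skim fit into a tidy per-multiplicity tibble
#'
#' One row per spectrum entry `j` with the estimated `r_j`.
#'
#' @param x A `skim_fit` from [estimate_genome()].
#' @param ... Unused.
#' @return A tibble with columns `j` and `r`.
#' @export
tidy.skim_fit <- function(x, ...) {
  tibble(j = seq_along(x$r), r = x$r)
}

#' One-row summary of a skim fit
#'
#' @param x A `skim_fit` from [estimate_genome()].
#' @param ... Unused.
#' @return A one-row tibble: `length`, `coverage`, `eps`, `lambda`,
#'   `uniqueness`, `objective`, `iterations`, `accept_rate`.
#' @export
glance.skim_fit <- function(x, ...) {
  tibble(
    length = x$length,
    coverage = x$coverage,
    eps = x$eps,
    lambda = x$lambda,
    uniqueness = x$uniqueness,
    objective = x$objective,
    iterations = nrow(x$trace),
    accept_rate = if (nrow(x$trace) > 0) mean(x$trace$accepted) else
      NA_real_)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot an annealing trace
#'
#' Proposed-objective values per iteration, accepted moves highlighted.
#'
#' @param object A `skim_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.skim_fit <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$t, y = .data$objective)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$accepted),
                        alpha = 0.6, size = 0.8, na.rm = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "objective (L1, h >= 2)",
                  colour = "accepted") +
    ggplot2::theme_minimal()
}

#' Plot a k-mer count histogram
#'
#' @param object A [kmer_histogram()].
#' @param max_h Truncate the x axis at this multiplicity (default 60).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kmer_histogram <- function(object, max_h = 60, ...) {
  df <- dplyr::filter(as_tibble(object), .data$h <= max_h)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$count)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = "multiplicity h", y = "distinct k-mers") +
    ggplot2::theme_minimal()
}

#' Plot a repeat spectrum
#'
#' @param object A [repeat_spectrum()] or `skim_fit`.
#' @param ... Unused.
#' @return A ggplot object with `r_j` on a log scale.
#' @export
autoplot.repeat_spectrum <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::filter(df, .data$r > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "copy number j", y = expression(r[j])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
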