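#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a hit profile
#'
#' Plots either the run-hitting probabilities themselves or (default) their
#' deficit from the sparsity upper bound `min(x/s, 1)`, the way sampling
#' schemes are usually compared.
#'
#' @param object a `hit_profile`.
#' @param type `"deficit"` or `"h"`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.hit_profile <- function(object, type = c("deficit", "h"), ...) {
  type <- match.arg(type)
  y <- rlang::sym(type)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = !!y)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "run size x",
      y = if (type == "deficit") "upper bound − H(x)" else "H(x)",
      title = attr(object, "scheme")
    ) +
    ggplot2::theme_minimal()
}

#' Compare several hit profiles in one plot
#'
#' @param profiles a named list of `hit_profile` tibbles (names become the
#'   legend; unnamed entries use their scheme attribute).
#' @param type `"deficit"` or `"h"`.
#' @return a ggplot.
#' @examples
#' plot_profiles(list(
#'   ry = run_hit_profile(word_set("ry"), 10),
#'   rr = run_hit_profile(word_set("rr"), 10)
#' ))
#' @export
plot_profiles <- function(profiles, type = c("deficit", "h")) {
  type <- match.arg(type)
  nm <- names(profiles)
  if (is.null(nm)) nm <- rep("", length(profiles))
  lab <- purrr::map2_chr(profiles, nm, function(p, n) {
    if (nzchar(n)) n else attr(p, "scheme")
  })
  df <- purrr::map2_dfr(profiles, lab, function(p, l) {
    dplyr::mutate(tibble::as_tibble(p), scheme = l)
  })
  y <- rlang::sym(type)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = !!y,
                                   colour = .data$scheme)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "run size x",
      y = if (type == "deficit") "upper bound − H(x)" else "H(x)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sampled-distance distribution
#'
#' @param object a `distance_distribution`.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.distance_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$d, y = .data$prob)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(
      x = "distance between consecutive sampled positions",
      y = "probability",
      subtitle = sprintf("mean %.3g, variance %.3g, tail mass %.2g",
                         attr(object, "mean"), attr(object, "variance"),
                         attr(object, "tail_mass"))
    ) +
    ggplot2::theme_minimal()
}
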