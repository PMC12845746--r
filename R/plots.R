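#' @describeIn nmf_fit autoplot method: weight bars and activation profiles
#'   per synergy.
#' @param object a `kick_synergy`.
#' @export
autoplot.kick_synergy <- function(object, ...) {
  w <- tidy(object, "weights")
  h <- tidy(object, "activations")
  w$panel <- sprintf("synergy %d weights", w$synergy)
  h$panel <- sprintf("synergy %d activation", h$synergy)
  p_w <- ggplot2::ggplot(w, ggplot2::aes(x = .data$muscle, y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~panel, ncol = 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "weight (unit-norm)")
  p_h <- ggplot2::ggplot(h, ggplot2::aes(x = .data$t, y = .data$activation)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "normalised cycle (points)", y = "activation")
  list(weights = p_w, activations = p_h)
}

#' Plot the Gap-statistic curve of a reference clustering
#'
#' @param refs a [reference_synergies()] object.
#' @return a ggplot: Gap(k) with one-standard-deviation bars; the selected
#'   cluster count is marked.
#' @export
plot_gap_curve <- function(refs) {
  stopifnot(inherits(refs, "kick_refs"))
  gc <- refs$gap_curve
  if (is.null(gc) || nrow(gc) == 0) {
    abort("No Gap curve available: the cluster count was fixed, not selected.",
          class = "kicksyn_invalid_parameter")
  }
  ggplot2::ggplot(gc, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$gap - .data$sd,
                                          ymax = .data$gap + .data$sd)) +
    ggplot2::geom_vline(xintercept = refs$n_clusters, linetype = 2) +
    ggplot2::scale_x_continuous(breaks = gc$k) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "number of clusters k", y = "Gap(k)",
                  title = sprintf("Gap statistic (selected k = %d)",
                                  refs$n_clusters))
}

#' Plot reference synergy centroids as weight profiles
#'
#' @param refs a [reference_synergies()] object.
#' @return a ggplot of centroid muscle weights, one facet per reference.
#' @export
plot_reference_synergies <- function(refs) {
  stopifnot(inherits(refs, "kick_refs"))
  df <- tibble(ref = rep(seq_len(refs$n_clusters), each = length(refs$muscles)),
               muscle = rep(refs$muscles, refs$n_clusters),
               weight = as.vector(t(refs$centroids)))
  df$muscle <- factor(df$muscle, levels = refs$muscles)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$muscle, y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ref, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "centroid weight")
}
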