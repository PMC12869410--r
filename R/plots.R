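#' Plot the training loss trace
#'
#' @param object A `ptgmm_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ptgmm_model <- function(object, ...) {
  tr <- object$loss_trace
  tr$step <- seq_len(nrow(tr))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_smooth(se = FALSE, method = "loess", formula = y ~ x,
                         colour = "firebrick") +
    ggplot2::labs(x = "training step", y = "FRC loss") +
    ggplot2::theme_minimal()
}

#' Plot the Gaussian embedding coloured by region
#'
#' @param object A `region_set` from [segment_gmm()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.region_set <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$region <- factor(df$region)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$emb1, y = .data$emb2,
                                   colour = .data$region)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "embedding 1", y = "embedding 2",
                  colour = "region") +
    ggplot2::theme_minimal()
}

#' Plot a region-focused particle embedding coloured by class
#'
#' @param object A `particle_embedding` from [focus_embed_particles()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.particle_embedding <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$class <- factor(df$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$emb1, y = .data$emb2,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = "embedding 1", y = "embedding 2", colour = "class") +
    ggplot2::theme_minimal()
}

#' Histogram of decoded amplitudes split by true presence
#'
#' The two overlaid distributions show decoded amplitude gates of
#' Gaussians whose atoms were present versus absent in each particle; a
#' well-trained model separates them around the classification
#' threshold.
#'
#' @param object An `amplitude_accuracy` result.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.amplitude_accuracy <- function(object, bins = 40, ...) {
  df <- object$histogram
  df$truth <- ifelse(df$true_present, "present", "absent")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$amplitude,
                                   fill = .data$truth)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::geom_vline(xintercept = object$threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "decoded amplitude gate", y = "count",
                  fill = "ground truth") +
    ggplot2::theme_minimal()
}
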