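#' Plot an ensemble
#'
#' * `type = "fates"`: bar chart of the four fate counts.
#' * `type = "elimination"`: histogram of elimination generations.
#' * `type = "trajectories"`: allele-frequency trajectories on a log10 axis
#'   (requires `keep_trajectories = TRUE` in [run_ensemble()]).
#'
#' @param object A `lineage_ensemble`.
#' @param type Which view to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lineage_ensemble <- function(object,
                                      type = c("fates", "elimination",
                                               "trajectories"),
                                      ...) {
  type <- match.arg(type)
  if (type == "fates") {
    df <- dplyr::count(object$outcomes, .data$status)
    df$status <- factor(df$status,
                        levels = c("eliminated", "fixed_then_extinct",
                                   "fixed_held", "persisting"))
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$n)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = NULL, y = "Lineages",
                      title = sprintf("Fates of %d %s lineages",
                                      object$n, object$config$name))
    )
  }
  if (type == "elimination") {
    df <- dplyr::filter(object$outcomes, .data$status == "eliminated")
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$terminal_generation)) +
        ggplot2::geom_histogram(binwidth = 1) +
        ggplot2::labs(x = "Generation of elimination", y = "Lineages")
    )
  }
  if (is.null(object$trajectories)) {
    stop("no trajectories retained; rerun with keep_trajectories = TRUE",
         call. = FALSE)
  }
  df <- dplyr::filter(object$trajectories, .data$frequency > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$frequency,
                                   group = .data$lineage_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Generation", y = "Allele frequency")
}

#' Plot repeat-length trajectories
#'
#' Spaghetti plot of repeat length per generation with the pathogenic
#' threshold marked, showing transitions between the expanded and normal
#' ranges.
#'
#' @param ens A `lineage_ensemble` with trajectories retained.
#' @param lineages Optional vector of lineage ids to show.
#' @return A ggplot.
#' @export
plot_repeat_trajectories <- function(ens, lineages = NULL) {
  if (is.null(ens$trajectories)) {
    stop("no trajectories retained; rerun with keep_trajectories = TRUE",
         call. = FALSE)
  }
  df <- ens$trajectories
  if (!is.null(lineages)) {
    df <- dplyr::filter(df, .data$lineage_id %in% lineages)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation,
                                   y = .data$repeat_length,
                                   group = .data$lineage_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_hline(yintercept = ens$config$pathogenic_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "Generation", y = "CAG repeat length")
}
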