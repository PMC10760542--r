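#' Per-animal swarm plot with mean and SEM
#'
#' Mirrors the standard presentation of per-animal puncta metrics:
#' jittered per-animal points by genotype with a mean +/- SEM overlay.
#'
#' @param animals Per-animal tibble (see [analyze_study()]).
#' @param metric Per-animal metric column to plot.
#' @param normalize_to Optional genotype label; values are divided by
#'   that group's mean (the convention for intensity graphs).
#' @return A ggplot object.
#' @export
plot_group_metric <- function(animals, metric = "mean_peak_to_bead",
                              normalize_to = NULL) {
  df <- as.data.frame(animals)[, c("genotype", metric)]
  names(df) <- c("genotype", "value")
  df <- df[is.finite(df$value), ]
  if (!is.null(normalize_to))
    df$value <- normalize_to_wt(df$value,
                                df$value[df$genotype == normalize_to])
  summ <- do.call(rbind, lapply(split(df, df$genotype), function(d)
    data.frame(genotype = d$genotype[1L], mean = mean(d$value),
               sem = stats::sd(d$value) / sqrt(nrow(d)))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::geom_errorbar(
      data = summ,
      ggplot2::aes(y = .data$mean, ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.3, linewidth = 0.8) +
    ggplot2::geom_point(data = summ, ggplot2::aes(y = .data$mean),
                        shape = 18, size = 3) +
    ggplot2::labs(y = metric, x = NULL) +
    ggplot2::theme_classic()
}

#' Plot a profile with detected puncta
#'
#' @param profile Raw [intensity_profile()].
#' @param result Result of [measure_puncta()] on that profile.
#' @return A ggplot object.
#' @export
plot_profile_detection <- function(profile, result) {
  df <- as.data.frame(profile)
  sm <- as.data.frame(result$smoothed)
  p <- result$puncta
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position_um,
                                        y = .data$intensity)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_line(data = sm, color = "steelblue") +
    ggplot2::labs(x = "position (um)", y = "intensity (a.u.)") +
    ggplot2::theme_classic()
  if (nrow(p))
    g <- g + ggplot2::geom_point(
      data = data.frame(position_um = p$peak_pos_um,
                        intensity = p$peak_intensity),
      color = "firebrick", size = 2)
  g
}
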