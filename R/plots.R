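#' Plot the identity-to-consensus distribution
#'
#' Stacked per-species histogram of percent identity to the family
#' consensus; a bimodal shape with a high-identity cross-species peak and
#' a divergent within-species tail is the visual signature of a recent
#' horizontally spread family over an old resident one.
#'
#' @param identities tibble from [identity_to_consensus()].
#' @param bin_width histogram bin width in identity percent.
#' @param group1_floor,divergent_ceiling reference lines for the group
#'   division; `NULL` to omit.
#' @return A ggplot object.
#' @export
plot_identity_histogram <- function(identities, bin_width = 0.5,
                                    group1_floor = 92.5,
                                    divergent_ceiling = 90) {
  p <- ggplot2::ggplot(identities,
                       ggplot2::aes(x = .data$identity,
                                    fill = .data$species)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0,
                            closed = "right", color = "grey30",
                            linewidth = 0.1) +
    ggplot2::labs(x = "identity to consensus (%)", y = "sequences",
                  fill = "species") +
    ggplot2::theme_minimal()
  if (!is.null(group1_floor)) {
    p <- p + ggplot2::geom_vline(xintercept = group1_floor,
                                 linetype = "dashed")
  }
  if (!is.null(divergent_ceiling)) {
    p <- p + ggplot2::geom_vline(xintercept = divergent_ceiling,
                                 linetype = "dotted")
  }
  p
}

#' Plot pairwise Ka/Ks estimates
#'
#' Scatter of dN against dS with the neutral `omega = 1` diagonal; points
#' hugging the diagonal indicate the absence of selective constraint
#' typical of dead transposon copies.
#'
#' @param kaks tibble of [nei_gojobori()] rows (e.g. from
#'   [kaks_group_pairs()]).
#' @return A ggplot object.
#' @export
plot_kaks <- function(kaks) {
  ggplot2::ggplot(kaks, ggplot2::aes(x = .data$dS, y = .data$dN)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = expression(K[s]), y = expression(K[a])) +
    ggplot2::theme_minimal()
}
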