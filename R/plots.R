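#' Plot item characteristic curves
#'
#' Category response probabilities ("trace lines") against the latent
#' trait, one panel per item.
#'
#' @param bank A [grm_bank()] (or a single [grm_item()]).
#' @param grid A [theta_grid()] (default: dense standard-normal grid).
#' @return A ggplot object.
#' @export
plot_icc <- function(bank, grid = normal_grid(121)) {
  if (inherits(bank, "grm_item")) bank <- grm_bank(list(bank))
  stopifnot(inherits(bank, "grm_bank"))
  df <- do.call(rbind, lapply(names(bank$items), function(id) {
    it <- bank$items[[id]]
    P <- icc_curve(it, grid)
    data.frame(item = id,
               theta = rep(grid$points, ncol(P)),
               category = factor(rep(0:(ncol(P) - 1L), each = length(grid$points))),
               prob = as.vector(P), stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$prob,
                                   colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~item) +
    ggplot2::labs(x = expression(theta), y = "P(response)",
                  colour = "category") +
    ggplot2::theme_minimal()
}

#' Plot test information curves
#'
#' Overlays the test information function of one or more banks/forms, with
#' the information-10 reference line (reliability 0.90).
#'
#' @param banks Named list of [grm_bank()] objects.
#' @param grid A [theta_grid()].
#' @return A ggplot object.
#' @export
plot_information <- function(banks, grid = normal_grid(121)) {
  if (inherits(banks, "grm_bank")) banks <- list(bank = banks)
  df <- do.call(rbind, lapply(names(banks), function(nm) {
    ti <- test_information(banks[[nm]], grid$points)
    data.frame(form = nm, theta = ti$theta, information = ti$information,
               stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$information,
                                   colour = .data$form)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 10, linetype = "dashed") +
    ggplot2::labs(x = expression(theta), y = "information") +
    ggplot2::theme_minimal()
}

#' Plot a two-group ICC overlay for a DIF item
#'
#' @param overlay Output of [group_icc_overlay()].
#' @return A ggplot object.
#' @export
plot_dif_overlay <- function(overlay) {
  ggplot2::ggplot(overlay, ggplot2::aes(x = .data$theta, y = .data$prob,
                                        colour = factor(.data$category),
                                        linetype = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(theta), y = "P(response)",
                  colour = "category", linetype = "group") +
    ggplot2::theme_minimal()
}
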