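# broom-style accessors and ggplot2 autoplot methods for the scan results.

#' @export
tidy.ewas_scan <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.ewas_scan <- function(x, alpha = 0.05, ...) {
  thr <- bonferroni_threshold(alpha, attr(x, "m_tests"))
  tibble::tibble(m_tests = attr(x, "m_tests"),
                 bonferroni_threshold = thr,
                 n_significant = sum(x$p < thr),
                 prop_hypo = mean(x$delta_beta[x$p < thr] < 0))
}

#' @export
tidy.vmp_scan <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.vmp_scan <- function(x, alpha = 0.05, ...) {
  thr <- bonferroni_threshold(alpha, attr(x, "m_tests"))
  tibble::tibble(m_tests = attr(x, "m_tests"),
                 bonferroni_threshold = thr,
                 n_significant = sum(x$p < thr))
}

#' @export
tidy.de_scan <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.de_scan <- function(x, alpha = 0.05, ...) {
  thr <- bonferroni_threshold(alpha, attr(x, "m_tests"))
  tibble::tibble(m_tests = attr(x, "m_tests"),
                 bonferroni_threshold = thr,
                 n_significant = sum(x$p < thr, na.rm = TRUE),
                 prop_up = mean(x$log2fc[!is.na(x$p) & x$p < thr] > 0))
}

#' @export
tidy.dmr_scan <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  out$leading_edge_size <- lengths(out$leading_edge)
  out
}

#' @export
glance.dmr_scan <- function(x, fdr = 0.05, ...) {
  tibble::tibble(n_regions = nrow(x),
                 n_perm = attr(x, "n_perm"),
                 n_significant = sum(x$p_fdr < fdr, na.rm = TRUE))
}

#' Volcano plot of a differential methylation or expression scan
#'
#' @param object An `ewas_scan` or `de_scan`.
#' @param alpha Family-wise error rate for the threshold line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ewas_scan <- function(object, alpha = 0.05, ...) {
  thr <- bonferroni_threshold(alpha, attr(object, "m_tests"))
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$delta_beta, y = -log10(.data$p),
                               colour = .data$p < thr)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = expression(Delta * beta~"(case - control)"),
                  y = expression(-log[10]~italic(p)))
}

#' @rdname autoplot.ewas_scan
#' @export
autoplot.de_scan <- function(object, alpha = 0.05, ...) {
  thr <- bonferroni_threshold(alpha, attr(object, "m_tests"))
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                               colour = !is.na(.data$p) & .data$p < thr)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = expression(log[2]~"fold change"),
                  y = expression(-log[10]~italic(p)))
}

#' Enrichment-score overview of a region scan
#'
#' @param object A `dmr_scan`.
#' @param fdr FDR call level.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dmr_scan <- function(object, fdr = 0.05, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$nes, y = -log10(.data$p_perm),
                               colour = .data$p_fdr < fdr)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~.data$region_kind) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "normalised enrichment score",
                  y = expression(-log[10]~italic(p)[perm]))
}
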