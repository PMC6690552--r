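# Diagnostic plots: log2 M/F distributions by element (the visual used to
# read off sex linkage), the gene-level ratio distribution, and the cutoff
# sweep.

#' Scaffold log2 M/F coverage by Muller element
#'
#' Histogram of per-scaffold log2 M/F coverage ratios faceted by assigned
#' element, with the autosomal (0) and X (-1) expectations marked. The
#' X-linked elements — including any neo-X — stand one doubling below the
#' autosomal mass; Y contigs fall far right (or off scale, at infinite
#' ratio).
#'
#' @param scaffolds Output of [classify_linkage()].
#' @return A ggplot object.
#' @export
plot_scaffold_mf <- function(scaffolds) {
  dat <- filter(scaffolds, is.finite(.data$log2_mf))
  dat$assigned_element[is.na(dat$assigned_element)] <- "unassigned"
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2_mf,
                                    fill = .data$linkage_class)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = c(-1, 0), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$assigned_element)) +
    ggplot2::labs(x = "log2 male/female coverage ratio",
                  y = "scaffolds", fill = "linkage") +
    ggplot2::theme_minimal()
}

#' Gene-level M/F ratio distribution
#'
#' Histogram of finite per-gene normalized M/F coverage ratios with the
#' Y-amplification cutoff marked.
#'
#' @param calls Output of [call_y_amplified()].
#' @return A ggplot object.
#' @export
plot_mf_ratios <- function(calls) {
  dat <- filter(calls, is.finite(.data$mf_ratio))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mf_ratio,
                                    fill = .data$y_amplified)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = dat$cutoff_used[1],
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "normalized M/F coverage ratio", y = "genes",
                  fill = "Y-amplified") +
    ggplot2::theme_minimal()
}

#' Cutoff sweep curve
#'
#' Number of Y-amplification calls as a function of the M/F ratio cutoff.
#'
#' @param sweep Output of [cutoff_sweep()].
#' @return A ggplot object.
#' @export
plot_cutoff_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$cutoff,
                                      y = .data$n_called)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "M/F ratio cutoff", y = "genes called") +
    ggplot2::theme_minimal()
}

#' Plot a pipeline run
#'
#' @param object A `coamp_run`.
#' @param type One of `"mf"` (gene ratio distribution), `"scaffolds"`
#'   (scaffold log2 M/F by element) or `"sweep"` (cutoff sweep).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot coamp_run
#' @export
autoplot.coamp_run <- function(object, type = c("mf", "scaffolds", "sweep"),
                               ...) {
  type <- rlang::arg_match(type)
  switch(type,
         mf = plot_mf_ratios(object$amp),
         scaffolds = plot_scaffold_mf(object$scaffolds),
         sweep = plot_cutoff_sweep(object$sweep))
}
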