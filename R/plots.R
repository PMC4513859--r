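# ggplot2 views of the main result types.

#' Plot a read stack on its hairpin
#'
#' Horizontal segments for every distinct read (y = read rank, alpha by
#' count) over shaded mature/star intervals, with the dot-bracket pairing
#' state as a rug along the x axis.
#'
#' @param stack read-stack tibble.
#' @param fold the precursor `hairpin_fold`.
#' @param duplex optional duplex tibble from [call_products()].
#' @return a ggplot object.
#' @export
plot_read_stack <- function(stack, fold, duplex = NULL) {
  stack <- arrange(stack, .data$start) |>
    mutate(rank = dplyr::row_number())
  paired <- tidy(fold)
  p <- ggplot2::ggplot(stack) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$rank,
                   yend = .data$rank, linewidth = log10(.data$count + 1))) +
    ggplot2::geom_rug(data = filter(paired, .data$paired),
                      ggplot2::aes(x = .data$position), sides = "b",
                      length = ggplot2::unit(0.02, "npc")) +
    ggplot2::scale_linewidth_continuous(range = c(0.3, 2),
                                        name = "log10 reads") +
    ggplot2::labs(x = "precursor position (nt)", y = "read",
                  title = unique(stack$locus_id)[1]) +
    ggplot2::theme_minimal()
  if (!is.null(duplex) && !is.na(duplex$mirna_start)) {
    shade <- tibble(xmin = duplex$mirna_start, xmax = duplex$mirna_end,
                    product = "miRNA")
    if (!is.na(duplex$star_start)) {
      shade <- bind_rows(shade, tibble(xmin = duplex$star_start,
                                       xmax = duplex$star_end,
                                       product = "miRNA*"))
    }
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf,
                   ymax = Inf, fill = .data$product),
      alpha = 0.15, inherit.aes = FALSE) +
      ggplot2::scale_fill_manual(values = c("miRNA" = "red",
                                            "miRNA*" = "blue"))
  }
  p
}

#' Verdict composition of a pipeline run
#' @param object a `mircert_run`.
#' @param ... unused.
#' @return a ggplot object (bar chart of verdicts with reason codes).
#' @export
autoplot.mircert_run <- function(object, ...) {
  dat <- mutate(object$summary,
                label = ifelse(.data$reason_codes == "", .data$verdict,
                               paste0(.data$verdict, ":",
                                      .data$reason_codes)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$verdict,
                                    fill = .data$label)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "loci", fill = "classification") +
    ggplot2::theme_minimal()
}

#' Mature/star length distributions of miRNA sets
#'
#' @param object a `mirna_structural_summary`.
#' @param ... further summaries to overlay (cross-lineage comparison view).
#' @return a ggplot object.
#' @export
autoplot.mirna_structural_summary <- function(object, ...) {
  summaries <- c(list(object), purrr::keep(list(...), function(x) {
    inherits(x, "mirna_structural_summary")
  }))
  long <- purrr::map_dfr(summaries, tidy)
  lens <- filter(long, .data$metric %in% c("mature_length", "star_length"))
  ggplot2::ggplot(lens,
                  ggplot2::aes(x = factor(.data$length), y = .data$n,
                               fill = .data$set_label)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "length (nt)", y = "loci", fill = NULL) +
    ggplot2::theme_minimal()
}

#' First-nucleotide composition of miRNA sets
#'
#' U/A/C/G fractions at position one of matures and stars, the 5'-U bias
#' view.
#'
#' @param ... one or more `mirna_structural_summary` objects.
#' @return a ggplot object.
#' @export
plot_first_nt_composition <- function(...) {
  summaries <- purrr::keep(list(...), function(x) {
    inherits(x, "mirna_structural_summary")
  })
  comps <- purrr::map_dfr(summaries, tidy) |>
    filter(stringr::str_detect(.data$metric, "_first_")) |>
    tidyr::separate_wider_delim("metric", "_first_",
                                names = c("product", "nt"))
  ggplot2::ggplot(comps,
                  ggplot2::aes(x = .data$nt, y = .data$value,
                               fill = .data$set_label)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~product) +
    ggplot2::labs(x = "first nucleotide", y = "fraction", fill = NULL) +
    ggplot2::theme_minimal()
}
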