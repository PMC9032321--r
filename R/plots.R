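# ggplot2 views of the profile components, mirroring the figure panels the
# field conventionally reports: size distribution by strand, 5'-start
# density along the genome as a mirror plot, and 5'-terminal composition.

#' Size distribution plot
#'
#' Stacked bars of total-weighted read counts per length, split by strand.
#'
#' @param profile A [vsirna_profile()].
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(profile) {
  tidy(profile, "size_strand") |>
    ggplot2::ggplot(ggplot2::aes(
      x = factor(.data$length), y = .data$total_count, fill = .data$strand
    )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "read length (nt)", y = "total reads", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Positional mirror plot
#'
#' Sense 5'-start counts above the axis, antisense below, with hotspot
#' intervals shaded.
#'
#' @param profile A [vsirna_profile()].
#' @return A ggplot object.
#' @export
plot_positional_profile <- function(profile) {
  pos <- tidy(profile, "positional")
  hs <- tidy(profile, "hotspots")
  p <- ggplot2::ggplot(pos, ggplot2::aes(x = .data$offset)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$sense), fill = "#2166ac", width = 1) +
    ggplot2::geom_col(ggplot2::aes(y = -.data$antisense), fill = "#b2182b", width = 1) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "genome position (nt)", y = "5'-start count (sense up / antisense down)") +
    ggplot2::theme_minimal()
  if (nrow(hs)) {
    hs <- mutate(hs, ymin = ifelse(.data$strand == "sense", 0, -Inf),
                 ymax = ifelse(.data$strand == "sense", Inf, 0))
    p <- p + ggplot2::geom_rect(
      data = hs,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = .data$ymin, ymax = .data$ymax),
      inherit.aes = FALSE, alpha = 0.15, fill = "orange"
    )
  }
  p
}

#' 5'-terminal composition plot
#'
#' Per-base fractions at the analysis length, unique and total weightings
#' side by side.
#'
#' @param profile A [vsirna_profile()].
#' @return A ggplot object.
#' @export
plot_five_prime <- function(profile) {
  tidy(profile, "five_prime") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$base, y = .data$fraction,
                                 fill = .data$base)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~weighting) +
    ggplot2::labs(
      x = sprintf("5'-terminal base of %d-nt reads", profile$analysis_length),
      y = "fraction"
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot a vsiRNA profile
#'
#' @param object A [vsirna_profile()].
#' @param type One of `"size"`, `"positional"`, `"five_prime"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vsirna_profile
#' @export
autoplot.vsirna_profile <- function(object,
                                    type = c("size", "positional", "five_prime"),
                                    ...) {
  switch(match.arg(type),
    size = plot_size_distribution(object),
    positional = plot_positional_profile(object),
    five_prime = plot_five_prime(object)
  )
}

#' Autoplot a genome annotation
#'
#' Linear genome map: UTRs as thin segments, ORFs as arrows stacked by
#' overlap.
#'
#' @param object A [segment_genome()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot genome_annotation
#' @export
autoplot.genome_annotation <- function(object, ...) {
  feats <- tidy(object) |>
    filter(.data$length > 0) |>
    mutate(row = cumsum(.data$feature == "CDS") * (.data$feature == "CDS"))
  ggplot2::ggplot(feats) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = ifelse(.data$feature == "CDS", .data$row - 0.35, -0.05),
      ymax = ifelse(.data$feature == "CDS", .data$row + 0.35, 0.05),
      fill = .data$feature
    )) +
    ggplot2::labs(x = "genome position (nt)", y = NULL, fill = NULL,
                  title = object$genome_id) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
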