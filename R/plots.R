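#' Pangenome partition spectrum
#'
#' Frequency spectrum of the pangenome: for each number of genomes a
#' family occurs in, how many families fall there, coloured by
#' partition.  A healthy bacterial pangenome shows the characteristic
#' U-shape — a persistent peak at full occupancy, a cloud peak at one
#' or two genomes and a shell in between.
#'
#' @param object A `pangenome_partition` from [partition_em()].
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.pangenome_partition <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n_genomes_present,
                                    fill = .data$partition)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = c(persistent = "#E08A00",
                                          shell = "#1B9E77",
                                          cloud = "#4477AA")) +
    ggplot2::labs(x = "genomes containing the family",
                  y = "gene families", fill = "partition") +
    ggplot2::theme_minimal()
}

#' Map of detected RGPs along genomes
#'
#' One horizontal track per genome/contig with RGP intervals drawn as
#' segments, shaded by region score.
#'
#' @param rgps RGP tibble from [detect_rgps()].
#' @return A `ggplot` object.
#' @export
plot_rgp_map <- function(rgps) {
  dat <- rgps %>%
    mutate(track = paste(.data$genome_id, .data$contig_id, sep = " / "),
           xend = ifelse(.data$end > .data$start, .data$end,
                         .data$start + .data$span))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$start, xend = .data$xend,
                                    y = .data$track, yend = .data$track,
                                    colour = .data$score)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::labs(x = "position (bp)", y = NULL, colour = "score") +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise Mash distances
#'
#' @param dist Symmetric distance matrix with genome ids as dimnames.
#' @param max_dist Distance drawn as the upper end of the fill scale;
#'   the default matches the 0.06 species cutoff so same-species blocks
#'   are visible.
#' @return A `ggplot` object.
#' @export
plot_distance_heatmap <- function(dist, max_dist = 0.06) {
  dat <- as_tibble(dist, rownames = "a") %>%
    tidyr::pivot_longer(-"a", names_to = "b", values_to = "distance")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$a, y = .data$b,
                                    fill = pmin(.data$distance, max_dist))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1,
                                  limits = c(0, max_dist),
                                  name = "Mash d") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
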