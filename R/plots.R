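#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_segment
#'   geom_col geom_hline geom_vline labs theme_minimal scale_colour_manual
#' @export
ggplot2::autoplot

#' Volcano plot of a differential table
#'
#' log2 ratio (good vs poor) against -log10 Welch p, colored by direction of
#' the passing candidates, with the fold and alpha thresholds drawn.
#'
#' @param object a `differential_tbl`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.differential_tbl <- function(object, ...) {
  th <- attr(object, "thresholds")
  d <- filter(as_tibble(object), !is.na(.data$t_p))
  ggplot(d, aes(x = .data$log2_ratio, y = -log10(.data$t_p),
                colour = .data$direction)) +
    geom_point(alpha = 0.6, size = 0.8) +
    geom_vline(xintercept = c(-1, 1) * log2(th$fold_threshold),
               linetype = "dashed", colour = "grey40") +
    geom_hline(yintercept = -log10(th$alpha),
               linetype = "dashed", colour = "grey40") +
    scale_colour_manual(values = c(up_in_good = "#2166ac",
                                   up_in_poor = "#b2182b",
                                   none = "grey70")) +
    labs(x = "log2 ratio (good - poor)", y = "-log10 Welch p",
         colour = NULL) +
    theme_minimal()
}

#' Bar plot of the top enriched gene sets
#'
#' @param object an `enrichment_tbl`.
#' @param n_top number of sets shown (default 15).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.enrichment_tbl <- function(object, n_top = 15, ...) {
  d <- utils::head(as_tibble(object), n_top)
  d$set_name <- factor(d$set_name, levels = rev(d$set_name))
  ggplot(d, aes(x = -log10(.data$p_raw), y = .data$set_name)) +
    geom_col(fill = "#2166ac") +
    geom_vline(xintercept = -log10(0.05), linetype = "dashed",
               colour = "grey40") +
    labs(x = "-log10 raw hypergeometric p", y = NULL) +
    theme_minimal()
}

#' Intensity-dependent correction curve of an IRON fit
#'
#' Anchor offsets (sample - reference, log2) against mean log2 intensity.
#'
#' @param object an `iron_curve` from [iron_normalize()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.iron_curve <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$intensity, y = .data$offset)) +
    geom_hline(yintercept = 0, colour = "grey60") +
    geom_line(colour = "#b2182b") +
    labs(x = "mean log2 intensity", y = "correction offset (log2)") +
    theme_minimal()
}

#' Layout plot of a subnetwork
#'
#' Fruchterman-Reingold layout (seeded for reproducibility) with nodes
#' colored by origin tag.
#'
#' @param object a `subnetwork`.
#' @param layout_seed seed for the layout (default 1).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.subnetwork <- function(object, layout_seed = 1, ...) {
  members <- object$members
  if (nrow(members) == 0) {
    return(ggplot() + theme_minimal() + labs(title = "empty subnetwork"))
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(object$edges[, c("from", "to")]),
    directed = FALSE, vertices = members$node
  )
  set.seed(layout_seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(node = members$node, origin = members$origin,
                  x = xy[, 1], y = xy[, 2])
  edges <- dplyr::left_join(
    dplyr::left_join(as_tibble(object$edges), nodes[, c("node", "x", "y")],
                     by = c(from = "node")),
    setNames(nodes[, c("node", "x", "y")], c("node", "xend", "yend")),
    by = c(to = "node")
  )
  ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend),
                 colour = "grey70") +
    geom_point(data = nodes, aes(x = .data$x, y = .data$y,
                                 colour = .data$origin), size = 3) +
    labs(colour = NULL, x = NULL, y = NULL) +
    theme_minimal()
}
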