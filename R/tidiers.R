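#' Tidy a validated interaction table
#'
#' Returns one row per TAP-ICP pair with the score and validation
#' statistics, in broom's tidy-format convention.
#'
#' @param x A `coactmap_validated` object.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.coactmap_validated <- function(x, ...) {
  as_tibble(x)[c("tap", "icp", "iap", "config", "S", "sign", "M_target",
                 "M_E", "R", "p_significance", "Q_significance",
                 "p_specificity", "Q_specificity", "passed", "stage")]
}

#' One-row summary of a validation run
#'
#' @param x A `coactmap_validated` object.
#' @param ... Unused.
#' @return One-row tibble with pair counts surviving each stage and the
#'   parameters used.
#' @export
glance.coactmap_validated <- function(x, ...) {
  p <- attr(x, "params")
  tibble(n_pairs = nrow(x),
         n_scored = sum(!is.na(x$S) & abs(x$S) > 0),
         n_robust = sum(x$robust),
         n_significant = sum(x$stage %in% c("specificity", "passed")),
         n_passed = sum(x$passed),
         model = p$model, q_threshold = p$q_threshold,
         n_boot = p$n_boot, n_random = p$n_random)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Validation-stage plot of scored interactions
#'
#' Scatter of the combined-action score against robustness (`-log(R)`),
#' colored by the last validation stage reached; the `-log(R) = 0`
#' robustness threshold is drawn as a horizontal line.
#'
#' @param object A `coactmap_validated` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coactmap_validated <- function(object, ...) {
  d <- as_tibble(object)
  d <- d[!is.na(d$S), ]
  d$neg_log_R <- -log(d$R)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$S, y = .data$neg_log_R,
                                  color = .data$stage)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", color = "red") +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "combined action score S", y = expression(-log(R)),
                  color = "stage reached") +
    ggplot2::theme_minimal()
}

#' Network plot of validated interactions
#'
#' Draws the interaction network with gene-state vertices (high state dark,
#' low state light) and edges colored by the direction of IAP change;
#' ligand-receptor edges are dashed.
#'
#' @param object A `coactmap_network` object.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coactmap_network <- function(object, seed = 1, ...) {
  nodes <- object$nodes
  edges <- object$edges
  if (nrow(nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::ggtitle(paste0("empty network (", object$iap, ")")))
  }
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  pos <- tibble(node = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  nodes <- left_join(nodes, pos, by = "node")
  edges <- edges |>
    left_join(rename(pos, xa = "x", ya = "y"), by = c(node_a = "node")) |>
    left_join(rename(pos, xb = "x", yb = "y"), by = c(node_b = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, color = .data$direction,
                   linetype = .data$is_ligand_receptor)) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$state,
                   shape = .data$class), size = 6) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$gene),
      vjust = -1.4, size = 3) +
    ggplot2::scale_shape_manual(values = c(TAP = 21, ICP = 22)) +
    ggplot2::scale_color_manual(values = c(up = "firebrick", down = "steelblue")) +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid", `TRUE` = "dashed")) +
    ggplot2::labs(title = paste0("interaction network: ", object$iap)) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
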