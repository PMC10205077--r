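#' Render an integrated flow diagram
#'
#' Schematic of directed flows between recording sites/regions: nodes on a
#' circle, arrows whose width and color scale monotonically with flow weight.
#' For clarity, the smallest `trim_fraction` of nonzero edges are not shown
#' (floor rounding; default 15%).
#'
#' @param graph a `flow_graph` from [integrate_flows()]
#' @param trim_fraction fraction of smallest nonzero edges hidden, in [0, 1)
#' @param file optional PNG path; NULL draws on the active device only if
#'   one is open, otherwise skips drawing
#' @return the rendered (kept) edge list, invisibly
#' @export
render_flow_diagram <- function(graph, trim_fraction = 0.15, file = NULL) {
  assert_that(is.numeric(trim_fraction) && trim_fraction >= 0 && trim_fraction < 1,
              "trim_fraction must be in [0, 1)")
  assert_that(all(graph$weight >= 0), "flow weights must be >= 0")
  nz <- graph[graph$weight > 0, , drop = FALSE]
  n_drop <- floor(trim_fraction * nrow(nz))
  if (n_drop > 0) {
    keep <- order(nz$weight, decreasing = TRUE)[seq_len(nrow(nz) - n_drop)]
    nz <- nz[sort(keep), , drop = FALSE]
  }
  do_draw <- !is.null(file) || grDevices::dev.cur() > 1
  if (do_draw) {
    if (!is.null(file)) grDevices::png(file, width = 800, height = 800)
    nodes <- unique(c(graph$source, graph$target))
    th <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
    xy <- cbind(cos(th), sin(th))
    rownames(xy) <- nodes
    graphics::plot(xy, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
                   axes = FALSE, xlab = "", ylab = "", pch = 19, cex = 2)
    graphics::text(xy * 1.18, labels = nodes)
    if (nrow(nz) > 0) {
      wmax <- max(nz$weight)
      pal <- grDevices::colorRampPalette(c("grey70", "red"))(100)
      for (i in seq_len(nrow(nz))) {
        p0 <- xy[nz$source[i], ]; p1 <- xy[nz$target[i], ]
        shrink <- 0.08 / max(sqrt(sum((p1 - p0)^2)), 1e-9)
        a <- p0 + (p1 - p0) * shrink; b <- p1 - (p1 - p0) * shrink
        wrel <- nz$weight[i] / wmax
        graphics::arrows(a[1], a[2], b[1], b[2], length = 0.12,
                         lwd = 0.5 + 6 * wrel,
                         col = pal[max(1, ceiling(100 * wrel))])
      }
    }
    graphics::title(sprintf("integrated flow, %d of %d nonzero edges shown",
                            nrow(nz), sum(graph$weight > 0)))
    if (!is.null(file)) grDevices::dev.off()
  }
  invisible(nz)
}

#' Render group ERC time courses
#'
#' One panel per directed region-pair class: mean flow change with a
#' confidence band, asterisks marking time points of significant increase
#' over baseline, and shaded C1/V/C2 articulation epochs from the pooled
#' behavioural means (defaults 97/207/177 ms). Time zero is speech onset.
#'
#' @param group an `erc_group`
#' @param phoneme_epochs named durations (s) of `c1`, `v`, `c2`
#' @param classes which classes to draw (default all)
#' @param file optional PNG path
#' @return invisibly, the class names drawn
#' @export
render_timecourse <- function(group,
                              phoneme_epochs = c(c1 = 0.097, v = 0.207, c2 = 0.177),
                              classes = NULL, file = NULL) {
  classes <- classes %||% names(group$classes)
  do_draw <- !is.null(file) || grDevices::dev.cur() > 1
  if (do_draw) {
    if (!is.null(file)) grDevices::png(file, width = 900, height = 250 * length(classes))
    old <- graphics::par(mfrow = c(length(classes), 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old), add = TRUE)
    tt <- group$times
    edges <- cumsum(c(0, phoneme_epochs))
    shades <- grDevices::adjustcolor(c("orange", "skyblue", "orange"), 0.25)
    for (cls in classes) {
      cc <- group$classes[[cls]]
      ylim <- range(cc$mean + cc$ci, cc$mean - cc$ci, 0)
      graphics::plot(tt, cc$mean, type = "n", ylim = ylim,
                     xlab = "time re speech onset (s)", ylab = "flow change", main = cls)
      for (i in 1:3) graphics::rect(edges[i], ylim[1], edges[i + 1], ylim[2],
                                    col = shades[i], border = NA)
      graphics::polygon(c(tt, rev(tt)), c(cc$mean + cc$ci, rev(cc$mean - cc$ci)),
                        col = grDevices::adjustcolor("purple", 0.2), border = NA)
      graphics::lines(tt, cc$mean, col = "purple", lwd = 2)
      graphics::abline(h = 0, v = 0, lty = 3)
      if (any(cc$mask)) {
        graphics::points(tt[cc$mask], rep(ylim[2], sum(cc$mask)),
                         pch = 8, col = "purple", cex = 0.6)
      }
    }
    if (!is.null(file)) grDevices::dev.off()
  }
  invisible(classes)
}

#' Write a flow graph as a CSV edge list
#'
#' @param graph a `flow_graph`
#' @param file output CSV path
#' @return `file`, invisibly
#' @export
write_flow_graph <- function(graph, file) {
  utils::write.csv(as.data.frame(graph), file, row.names = FALSE)
  invisible(file)
}
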