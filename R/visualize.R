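#' @import ggplot2
NULL

# palettes mirroring the reference figures; all overridable per call
hapflow_palettes <- list(
  nucleotide = c(A = "rosybrown", C = "sienna1", G = "lightgoldenrod1",
                 T = "lightskyblue", `-` = "grey70", N = "grey45"),
  support = c(strong = "black", moderate = "red", weak = "pink1",
              poor = "white"),
  group = c(greenhouse = "blue", firm = "red", nature = "green")
)

default_palette <- function(categories, type = NULL) {
  categories <- as.character(unique(categories))
  if (!is.null(type) && type %in% names(hapflow_palettes) &&
      all(categories %in% names(hapflow_palettes[[type]]))) {
    return(hapflow_palettes[[type]][categories])
  }
  stats::setNames(grDevices::rainbow(length(categories)), categories)
}

#' Save a hapflow figure to PNG or SVG
#'
#' @param p A ggplot object from one of the `plot_*()` functions.
#' @param path Output file; format chosen by extension (`.png` or `.svg`).
#' @param width,height Size in inches.
#' @param dpi Resolution for raster output.
#' @return `path`, invisibly.
#' @export
save_plot <- function(p, path, width = 8, height = 7, dpi = 150) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else if (ext == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = dpi, type = "cairo")
  } else {
    stop("unsupported figure format: .", ext, " (use .png or .svg)",
         call. = FALSE)
  }
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

# ---- tree layout -----------------------------------------------------------

# Node coordinates for a phylo: x = depth by branch length from the basal
# node, tips at y = 1..n (ladderized by clade size), internal y = mean of
# children. Returns nodes and the rectangular "elbow" segments.
tree_layout <- function(t, ladderize = TRUE) {
  n <- length(t$tip.label)
  root <- n + 1L
  kids_e <- split(seq_len(nrow(t$edge)), t$edge[, 1L])
  elen <- if (is.null(t$edge.length)) rep(1, nrow(t$edge)) else t$edge.length
  clade_n <- function(node) {
    if (node <= n) return(1L)
    sum(vapply(kids_e[[as.character(node)]],
               function(e) clade_n(t$edge[e, 2L]), integer(1)))
  }
  x <- y <- numeric(n + t$Nnode)
  tip_counter <- 0L
  assign_xy <- function(node, depth) {
    x[node] <<- depth
    if (node <= n) {
      tip_counter <<- tip_counter + 1L
      y[node] <<- tip_counter
      return(invisible())
    }
    ee <- kids_e[[as.character(node)]]
    if (ladderize) {
      ee <- ee[order(vapply(ee, function(e) clade_n(t$edge[e, 2L]),
                            integer(1)))]
    }
    for (e in ee) assign_xy(t$edge[e, 2L], depth + elen[e])
    y[node] <<- mean(y[t$edge[ee, 2L]])
  }
  assign_xy(root, 0)
  nodes <- tibble::tibble(
    node = seq_len(n + t$Nnode), x = x, y = y,
    is_tip = seq_len(n + t$Nnode) <= n,
    label = c(t$tip.label, rep(NA_character_, t$Nnode))
  )
  px <- x[t$edge[, 1L]]; cx <- x[t$edge[, 2L]]
  py <- y[t$edge[, 1L]]; cy <- y[t$edge[, 2L]]
  horiz <- tibble::tibble(
    parent = t$edge[, 1L], child = t$edge[, 2L],
    x = px, xend = cx, y = cy, yend = cy, length = elen
  )
  vert <- tibble::tibble(
    parent = t$edge[, 1L], child = t$edge[, 2L],
    x = px, xend = px, y = py, yend = cy, length = elen
  )
  list(nodes = nodes, horizontal = horiz, vertical = vert)
}

# map a rectangular layout into the plane for circular display
polarize <- function(df, xcols, ycols, n_tips, r0 = 0) {
  ang <- function(yv) 2 * pi * (yv - 1) / n_tips
  out <- df
  for (i in seq_along(xcols)) {
    r <- df[[xcols[i]]] + r0
    a <- ang(df[[ycols[i]]])
    out[[xcols[i]]] <- r * cos(a)
    out[[ycols[i]]] <- r * sin(a)
  }
  out
}

arc_points <- function(r, y1, y2, n_tips, steps = 24L) {
  yy <- seq(y1, y2, length.out = steps)
  a <- 2 * pi * (yy - 1) / n_tips
  tibble::tibble(x = r * cos(a), y = r * sin(a))
}

scalebar_data <- function(xmax, y = 0) {
  len <- signif(xmax / 5, 1)
  tibble::tibble(x = 0, xend = len, y = y, yend = y,
                 label = format(len, trim = TRUE))
}

#' Plot a phylogenetic tree (rectangular or circular)
#'
#' Renders an NJ tree with one of three coloring modes mirroring the
#' reference figures: `"population"` colors tip points by population,
#' `"branchlength"` colors edges on a continuous two-color gradient by
#' branch length (a DNA-distance view), and `"support"` draws internal
#' node points filled by bootstrap confidence bin (black / red / pink1 /
#' white for strong / moderate / weak / poor).
#'
#' @param t A `phylo`; for `mode = "support"` it must carry supports in
#'   `node.label` (see [bootstrap_support()]).
#' @param mode `"plain"`, `"population"`, `"branchlength"` or `"support"`.
#' @param layout `"rectangular"` or `"circular"`.
#' @param pm Population map (for `mode = "population"`); defaults to
#'   parsing the tip labels.
#' @param palette Optional named color vector overriding the defaults.
#' @param show_tip_labels Draw tip labels (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_tree <- function(t, mode = c("plain", "population", "branchlength",
                                  "support"),
                      layout = c("rectangular", "circular"),
                      pm = NULL, palette = NULL, show_tip_labels = TRUE) {
  mode <- match.arg(mode)
  layout <- match.arg(layout)
  n <- length(t$tip.label)
  if (mode == "support" && is.null(t$node.label)) {
    stop("mode = \"support\" needs bootstrap supports in node.label",
         call. = FALSE)
  }
  lay <- tree_layout(t)
  circ <- layout == "circular"
  horiz <- lay$horizontal
  xmax <- max(lay$nodes$x)

  if (circ) {
    hseg <- polarize(horiz, c("x", "xend"), c("y", "yend"), n)
    varc <- dplyr::bind_rows(lapply(seq_len(nrow(lay$vertical)), function(i) {
      v <- lay$vertical[i, ]
      pts <- arc_points(v$x, v$y, v$yend, n)
      pts$grp <- i
      pts$length <- v$length
      pts
    }))
  } else {
    hseg <- horiz
    vseg <- lay$vertical
  }

  p <- ggplot()
  if (mode == "branchlength") {
    p <- p + geom_segment(data = hseg,
                          aes(x = .data$x, y = .data$y, xend = .data$xend,
                              yend = .data$yend, color = .data$length))
    p <- if (circ) {
      p + geom_path(data = varc, aes(x = .data$x, y = .data$y,
                                     group = .data$grp, color = .data$length))
    } else {
      p + geom_segment(data = vseg,
                       aes(x = .data$x, y = .data$y, xend = .data$xend,
                           yend = .data$yend, color = .data$length))
    }
    p <- p + scale_color_gradient(name = "branch length",
                                  low = "darkred", high = "steelblue")
  } else {
    p <- p + geom_segment(data = hseg,
                          aes(x = .data$x, y = .data$y, xend = .data$xend,
                              yend = .data$yend), linewidth = 0.4)
    p <- if (circ) {
      p + geom_path(data = varc, aes(x = .data$x, y = .data$y,
                                     group = .data$grp), linewidth = 0.4)
    } else {
      p + geom_segment(data = vseg,
                       aes(x = .data$x, y = .data$y, xend = .data$xend,
                           yend = .data$yend), linewidth = 0.4)
    }
  }

  tips <- lay$nodes[lay$nodes$is_tip, ]
  if (mode == "population") {
    pops <- if (is.null(pm)) parse_population(tips$label) else {
      key <- stats::setNames(pm$population, pm$label)
      unname(key[tips$label])
    }
    tips$population <- pops
    pal <- if (is.null(palette)) default_palette(pops) else palette
    tp <- if (circ) polarize(tips, "x", "y", n) else tips
    p <- p + geom_point(data = tp,
                        aes(x = .data$x, y = .data$y,
                            color = .data$population), size = 2) +
      scale_color_manual(name = "population", values = pal)
  }
  if (mode == "support") {
    sp <- support_table(t)
    nd <- dplyr::inner_join(lay$nodes, sp, by = "node")
    if (circ) nd <- polarize(nd, "x", "y", n)
    pal <- if (is.null(palette)) hapflow_palettes$support else palette
    if (nrow(nd) > 0L) {
      p <- p + geom_point(data = nd,
                          aes(x = .data$x, y = .data$y, fill = .data$bin),
                          shape = 21, size = 3, color = "black") +
        scale_fill_manual(name = "bootstrap", values = pal, drop = FALSE)
    }
  }
  if (show_tip_labels && !circ) {
    p <- p + geom_text(data = tips,
                       aes(x = .data$x, y = .data$y, label = .data$label),
                       hjust = -0.05, size = 2.6) +
      expand_limits(x = xmax * 1.25)
  }
  if (!circ) {
    sb <- scalebar_data(xmax, y = 0)
    p <- p + geom_segment(data = sb, aes(x = .data$x, xend = .data$xend,
                                         y = .data$y, yend = .data$yend)) +
      geom_text(data = sb, aes(x = (.data$x + .data$xend) / 2,
                               y = .data$y - 0.4, label = .data$label),
                size = 2.6)
  }
  p + theme_void() + theme(legend.position = "right")
}

#' Alignment panel beside the tree
#'
#' One row of colored cells per tip (four nucleotide colors; gaps in a
#' reserved fifth color), row order equal to the tip order of the plotted
#' (ladderized) tree, with the tree and a scale bar on the left.
#'
#' @param t A `phylo` whose tips are alignment labels.
#' @param al Alignment tibble containing at least all tree tips.
#' @param palette Optional nucleotide palette (named by character).
#' @return A ggplot object.
#' @export
plot_msa_tree <- function(t, al, palette = NULL) {
  al <- validate_alignment(al)
  missing <- setdiff(t$tip.label, al$label)
  if (length(missing) > 0L) {
    stop("tip(s) missing from the alignment: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  lay <- tree_layout(t)
  tips <- lay$nodes[lay$nodes$is_tip, ]
  m <- alignment_matrix(al)[tips$label, , drop = FALSE]
  L <- ncol(m)
  xmax <- max(lay$nodes$x)
  x0 <- xmax * 1.35
  w <- (xmax * 1.6) / L
  cells <- tibble::tibble(
    y = rep(tips$y, times = L),
    site = rep(seq_len(L), each = nrow(m)),
    state = as.vector(m)
  )
  cells$x <- x0 + (cells$site - 0.5) * w
  pal <- if (is.null(palette)) hapflow_palettes$nucleotide else palette
  present <- unique(cells$state)
  pal <- pal[intersect(names(pal), present)]
  extra <- setdiff(present, names(pal))
  if (length(extra) > 0L) {
    pal <- c(pal, stats::setNames(grDevices::grey.colors(length(extra)),
                                  extra))
  }
  sb <- scalebar_data(xmax, y = 0)
  ggplot() +
    geom_segment(data = lay$horizontal,
                 aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend), linewidth = 0.4) +
    geom_segment(data = lay$vertical,
                 aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend), linewidth = 0.4) +
    geom_tile(data = cells,
              aes(x = .data$x, y = .data$y, fill = .data$state),
              width = w, height = 0.9) +
    geom_text(data = tips, aes(x = xmax * 1.02, y = .data$y,
                               label = .data$label),
              hjust = 0, size = 2.2) +
    geom_segment(data = sb, aes(x = .data$x, xend = .data$xend,
                                y = .data$y, yend = .data$yend)) +
    geom_text(data = sb, aes(x = (.data$x + .data$xend) / 2, y = -0.6,
                             label = .data$label), size = 2.4) +
    scale_fill_manual(name = "base", values = pal) +
    theme_void()
}

# ---- heatmap ---------------------------------------------------------------

# dendrogram "elbow" segments for an hclust, x in leaf-order units
hclust_segments <- function(hc) {
  k <- length(hc$order)
  leaf_x <- match(seq_len(k), hc$order)
  pos <- matrix(0, nrow(hc$merge), 2L)  # x, height of each merge node
  segs <- list()
  node_xy <- function(id) {
    if (id < 0) c(leaf_x[-id], 0) else pos[id, ]
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- node_xy(hc$merge[i, 1L])
    b <- node_xy(hc$merge[i, 2L])
    h <- hc$height[i]
    pos[i, ] <- c(mean(c(a[1L], b[1L])), h)
    segs[[i]] <- tibble::tibble(
      x = c(a[1L], a[1L], b[1L]),
      y = c(a[2L], h, h),
      xend = c(a[1L], b[1L], b[1L]),
      yend = c(h, h, b[2L])
    )
  }
  dplyr::bind_rows(segs)
}

#' Clustered distance heatmap with marginal dendrograms
#'
#' Symmetric color field of the distance matrix with rows and columns
#' ordered by hierarchical clustering (complete linkage on the given
#' distances) and dendrograms drawn on both margins. Small distances are
#' dark red, large distances white, so tight haplotype clusters show as
#' dark blocks; the image is invariant to permutations of the input.
#'
#' @param d Symmetric distance matrix with dimnames.
#' @param low,high Colors for distance 0 and the maximum.
#' @return A ggplot object.
#' @export
plot_heatmap <- function(d, low = "darkred", high = "white") {
  stopifnot(is.matrix(d))
  if (max(abs(d - t(d))) > 1e-9) {
    stop("heatmap input must be a symmetric distance matrix", call. = FALSE)
  }
  k <- nrow(d)
  if (!is.null(rownames(d))) {
    # canonical label order first: with tied distances the hclust merge
    # sequence depends on input order, and this keeps the image invariant
    # to permutations of the input matrix
    d <- d[order(rownames(d)), order(rownames(d)), drop = FALSE]
  }
  if (k > 1L) {
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    # canonical leaf orientation (by mean row distance) so the image does
    # not depend on the input permutation
    dend <- stats::reorder(stats::as.dendrogram(hc), rowSums(d),
                           agglo.FUN = mean)
    ord <- stats::order.dendrogram(dend)
    hc$order <- ord
  } else {
    ord <- 1L
  }
  labs <- rownames(d)[ord]
  cells <- tibble::tibble(
    row = rep(seq_len(k), times = k),
    col = rep(seq_len(k), each = k),
    value = as.vector(d[ord, ord, drop = FALSE])
  )
  p <- ggplot() +
    geom_tile(data = cells, aes(x = .data$col, y = .data$row,
                                fill = .data$value)) +
    scale_fill_gradient(name = "distance", low = low, high = high) +
    scale_x_continuous(breaks = seq_len(k), labels = labs,
                       expand = c(0, 0)) +
    scale_y_continuous(breaks = seq_len(k), labels = labs,
                       expand = c(0, 0)) +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5),
          panel.grid = element_blank())
  if (k > 1L) {
    seg <- hclust_segments(hc)
    hmax <- max(hc$height)
    margin <- 0.25 * k
    top <- seg
    top$y <- k + 0.5 + seg$y / hmax * margin
    top$yend <- k + 0.5 + seg$yend / hmax * margin
    left <- tibble::tibble(
      x = 0.5 - seg$y / hmax * margin,
      xend = 0.5 - seg$yend / hmax * margin,
      y = seg$x, yend = seg$xend
    )
    p <- p +
      geom_segment(data = top, aes(x = .data$x, y = .data$y,
                                   xend = .data$xend, yend = .data$yend),
                   linewidth = 0.3) +
      geom_segment(data = left, aes(x = .data$x, y = .data$y,
                                    xend = .data$xend, yend = .data$yend),
                   linewidth = 0.3)
  }
  p
}

# ---- network ---------------------------------------------------------------

circle_slice <- function(cx, cy, r, a0, a1, id, category, steps = 32L) {
  a <- seq(a0, a1, length.out = steps)
  tibble::tibble(
    x = c(cx, cx + r * cos(a)), y = c(cy, cy + r * sin(a)),
    slice = id, category = category
  )
}

#' Plot a haplotype network
#'
#' Haplotype nodes as pies (slices proportional to the composition at the
#' network's level), connected by MST links (solid) and alternative links
#' (dashed), with one tick mark per mutational step on each link. Node
#' size encodes haplotype frequency: with `size_mode = "area"` (default)
#' the disc area is proportional to `hf`, avoiding visual exaggeration of
#' the dominant haplotype; `"radius"` makes the radius proportional.
#' Layout is force-directed with a fixed seed.
#'
#' @param net A `haplo_network` from [build_network()].
#' @param palette Optional named colors for the composition categories.
#' @param size_mode `"area"` or `"radius"`.
#' @param seed Layout seed.
#' @param label_nodes Draw haplotype ids at node centers.
#' @return A ggplot object.
#' @export
plot_network <- function(net, palette = NULL, size_mode = c("area", "radius"),
                         seed = 42L, label_nodes = TRUE) {
  stopifnot(inherits(net, "haplo_network"))
  size_mode <- match.arg(size_mode)
  g <- igraph::graph_from_data_frame(
    net$links[, c("from", "to", "weight")],
    directed = FALSE, vertices = net$nodes$haplotype
  )
  xy <- with_seed(seed, igraph::layout_with_fr(g, weights = 1 /
                                                 (igraph::E(g)$weight + 1)))
  nodes <- net$nodes
  nodes$x <- xy[, 1L]
  nodes$y <- xy[, 2L]
  span <- max(diff(range(nodes$x)), diff(range(nodes$y)), 1e-6)
  rel <- if (size_mode == "area") sqrt(nodes$size) else nodes$size
  nodes$r <- 0.08 * span * rel / max(rel)

  links <- dplyr::left_join(
    net$links,
    stats::setNames(nodes[, c("haplotype", "x", "y")],
                    c("from", "x0", "y0")), by = "from")
  links <- dplyr::left_join(
    links,
    stats::setNames(nodes[, c("haplotype", "x", "y")],
                    c("to", "x1", "y1")), by = "to")

  # tick marks: `weight` short perpendicular dashes per link
  ticks <- dplyr::bind_rows(lapply(seq_len(nrow(links)), function(i) {
    l <- links[i, ]
    w <- l$weight
    if (w < 1L) return(NULL)
    f <- seq_len(w) / (w + 1)
    dx <- l$x1 - l$x0; dy <- l$y1 - l$y0
    len <- sqrt(dx^2 + dy^2)
    if (len < 1e-9) return(NULL)
    px <- -dy / len; py <- dx / len
    h <- 0.012 * span
    tibble::tibble(
      x = l$x0 + f * dx - px * h, y = l$y0 + f * dy - py * h,
      xend = l$x0 + f * dx + px * h, yend = l$y0 + f * dy + py * h
    )
  }))

  comp <- net$composition
  pal <- if (is.null(palette)) {
    default_palette(comp$category,
                    type = if (net$level == "group") "group" else NULL)
  } else palette
  miss <- setdiff(unique(comp$category), names(pal))
  if (length(miss) > 0L) {
    stop("composition categories without colors: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  slices <- dplyr::bind_rows(lapply(seq_len(nrow(nodes)), function(i) {
    nd <- nodes[i, ]
    cc <- comp[comp$haplotype == nd$haplotype, ]
    a <- 2 * pi * c(0, cumsum(cc$count) / sum(cc$count))
    dplyr::bind_rows(lapply(seq_len(nrow(cc)), function(s) {
      circle_slice(nd$x, nd$y, nd$r, a[s], a[s + 1L],
                   id = paste(nd$haplotype, s), category = cc$category[s])
    }))
  }))

  p <- ggplot() +
    geom_segment(data = links[links$kind == "mst", ],
                 aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                     yend = .data$y1), linewidth = 0.5)
  if (any(links$kind == "alternative")) {
    p <- p + geom_segment(data = links[links$kind == "alternative", ],
                          aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                              yend = .data$y1),
                          linetype = "dashed", linewidth = 0.35,
                          color = "grey40")
  }
  if (!is.null(ticks) && nrow(ticks) > 0L) {
    p <- p + geom_segment(data = ticks,
                          aes(x = .data$x, y = .data$y, xend = .data$xend,
                              yend = .data$yend), linewidth = 0.3)
  }
  p <- p + geom_polygon(data = slices,
                        aes(x = .data$x, y = .data$y, group = .data$slice,
                            fill = .data$category),
                        color = "grey20", linewidth = 0.2) +
    scale_fill_manual(name = net$level, values = pal) +
    coord_equal() + theme_void()
  if (label_nodes) {
    p <- p + geom_text(data = nodes,
                       aes(x = .data$x, y = .data$y + .data$r,
                           label = .data$haplotype),
                       vjust = -0.4, size = 2.8)
  }
  p
}

#' @describeIn plot_network autoplot method for haplotype networks.
#' @param object A `haplo_network`.
#' @param ... Passed to [plot_network()].
#' @method autoplot haplo_network
#' @export
autoplot.haplo_network <- function(object, ...) plot_network(object, ...)

#' @describeIn collapse_haplotypes autoplot method: haplotype frequency
#'   barplot.
#' @param object A `hapset`.
#' @method autoplot hapset
#' @export
autoplot.hapset <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$haplotype <- factor(df$haplotype, levels = df$haplotype)
  ggplot(df, aes(x = .data$haplotype, y = .data$hf)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "haplotype frequency (hf)") +
    theme_minimal()
}
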