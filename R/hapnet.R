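#' Minimum-spanning haplotype network
#'
#' Builds a haplotype network from an integer (Hamming) distance matrix:
#' the backbone is a minimum spanning tree computed by Kruskal's algorithm
#' with deterministic tie-breaking (weight, then lexicographically smaller
#' endpoint pair), so the result does not depend on input label order.
#' Equal-cost *alternative* links are the non-tree pairs `(i, j)` whose
#' distance equals the weight of the edge that first connected `i`'s and
#' `j`'s components during the Kruskal merge sequence (equivalently, the
#' maximum-weight link on the tree path between them). `alt_threshold`
#' additionally admits every non-tree pair with weight `<= alt_threshold`
#' as an alternative link, for exploring denser networks.
#'
#' Link weights are mutational steps (one tick per nucleotide difference in
#' the plots); no median or inferred intermediate nodes are ever created.
#'
#' @param d Integer-valued symmetric distance matrix over the haplotypes
#'   (from [hamming_matrix()]).
#' @param hs `hapset` from [collapse_haplotypes()]; node sizes are its `hf`.
#' @param pm Optional population map from [build_population_map()]
#'   (required for `level = "population"` or `"group"`).
#' @param level Composition level for the node pies: `"individual"`,
#'   `"population"` or `"group"`.
#' @param alt_threshold Optional nonnegative integer; see above.
#' @return A `haplo_network`: list with `nodes` (tibble `haplotype`,
#'   `size`), `links` (tibble `from`, `to`, `weight`, `kind`),
#'   `composition` (long tibble `haplotype`, `category`, `count`) and
#'   `level`.
#' @export
build_network <- function(d, hs, pm = NULL,
                          level = c("population", "individual", "group"),
                          alt_threshold = NULL) {
  level <- match.arg(level)
  stopifnot(is.matrix(d), !is.null(rownames(d)))
  if (max(abs(d - round(d))) > 1e-9) {
    stop("network distances must be integer-valued (mutational steps)",
         call. = FALSE)
  }
  if (!setequal(rownames(d), hs$haplotype)) {
    stop("distance matrix labels do not match the haplotype set",
         call. = FALSE)
  }
  d <- d[hs$haplotype, hs$haplotype, drop = FALSE]
  k <- nrow(d)

  links <- kruskal_links(d)
  if (!is.null(alt_threshold)) {
    stopifnot(alt_threshold >= 0)
    extra <- links$kind == "none" & links$weight <= alt_threshold
    links$kind[extra] <- "alternative"
  }
  links <- links[links$kind != "none", , drop = FALSE]

  composition <- switch(level,
    individual = tibble::tibble(
      haplotype = rep(hs$haplotype, lengths(hs$members)),
      category = unlist(hs$members, use.names = FALSE),
      count = 1L
    ),
    {
      if (is.null(pm)) {
        stop("a population map is required for level = \"", level, "\"",
             call. = FALSE)
      }
      pmx <- population_matrix(hs, pm, level = level)
      long <- tidyr::pivot_longer(pmx, -"haplotype",
                                  names_to = "category", values_to = "count")
      long[long$count > 0L, ]
    }
  )

  structure(list(
    nodes = tibble::tibble(haplotype = hs$haplotype, size = hs$hf),
    links = tibble::as_tibble(links),
    composition = composition,
    level = level
  ), class = "haplo_network")
}

#' Total weight of the minimum spanning tree backbone
#'
#' @param net A `haplo_network` from [build_network()].
#' @return Integer: sum of the `mst` link weights, minimal over all
#'   spanning trees of the haplotype graph.
#' @export
mst_total_weight <- function(net) {
  stopifnot(inherits(net, "haplo_network"))
  as.integer(sum(net$links$weight[net$links$kind == "mst"]))
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("Haplotype network: ", nrow(x$nodes), " haplotypes, ",
      sum(x$links$kind == "mst"), " MST links (total weight ",
      mst_total_weight(x), "), ",
      sum(x$links$kind == "alternative"), " alternative links; ",
      "composition by ", x$level, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.haplo_network <- function(x, ...) x$links

#' @export
glance.haplo_network <- function(x, ...) {
  tibble::tibble(
    n_haplotypes = nrow(x$nodes),
    n_samples = sum(x$nodes$size),
    n_mst_links = sum(x$links$kind == "mst"),
    n_alternative_links = sum(x$links$kind == "alternative"),
    mst_total_weight = mst_total_weight(x)
  )
}

#' Write a haplotype network to TSV / JSON
#'
#' Writes the link list (`from`, `to`, `weight`, `kind`), the node table
#' with composition counts spread into columns, and a JSON dump of the
#' whole network for plotting pipelines.
#'
#' @param net A `haplo_network`.
#' @param edge_path,node_path,json_path Output paths; `NULL` skips a file.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, edge_path = NULL, node_path = NULL,
                          json_path = NULL) {
  if (!is.null(edge_path)) {
    utils::write.table(net$links, edge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(node_path)) {
    wide <- tidyr::pivot_wider(net$composition, names_from = "category",
                               values_from = "count", values_fill = 0L)
    tab <- dplyr::left_join(net$nodes, wide, by = "haplotype")
    tab[is.na(tab)] <- 0L
    utils::write.table(tab, node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(level = net$level, nodes = net$nodes, links = net$links,
           composition = net$composition),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(c(edge_path, node_path, json_path))
}

# Kruskal MST over a labelled integer matrix. Returns every unordered pair
# as a row with kind "mst", "alternative" (equal to the merge weight of the
# pair's components) or "none".
kruskal_links <- function(d) {
  labs <- rownames(d)
  k <- length(labs)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  pairs <- data.frame(
    i = idx[, 1L], j = idx[, 2L],
    from = labs[idx[, 1L]], to = labs[idx[, 2L]],
    weight = as.integer(round(d[idx])),
    stringsAsFactors = FALSE
  )
  swap <- pairs$from > pairs$to
  tmp <- pairs$from[swap]; pairs$from[swap] <- pairs$to[swap]
  pairs$to[swap] <- tmp
  ord <- order(pairs$weight, pairs$from, pairs$to, method = "radix")
  pairs <- pairs[ord, ]

  comp <- seq_len(k)
  connect_w <- matrix(NA_integer_, k, k)
  kind <- rep("none", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    ci <- comp[pairs$i[r]]; cj <- comp[pairs$j[r]]
    if (ci != cj) {
      kind[r] <- "mst"
      a <- which(comp == ci); b <- which(comp == cj)
      connect_w[a, b] <- connect_w[b, a] <- pairs$weight[r]
      comp[b] <- ci
    }
  }
  eq <- kind == "none" &
    pairs$weight == connect_w[cbind(pairs$i, pairs$j)]
  kind[eq] <- "alternative"
  pairs$kind <- kind
  pairs[, c("from", "to", "weight", "kind")]
}
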