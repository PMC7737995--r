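#' Neighbor-joining tree estimation
#'
#' Standard NJ agglomeration (Saitou & Nei): at each step join the pair
#' `(i, j)` minimizing the rate-corrected criterion
#' `Q(i,j) = (r - 2) d(i,j) - R_i - R_j` where `R_i = sum_m d(i,m)` and `r`
#' is the number of active nodes; branch lengths
#' `v_i = d(i,j)/2 + (R_i - R_j)/(2(r - 2))`, `v_j = d(i,j) - v_i`;
#' reduction `d(u,m) = (d(i,m) + d(j,m) - d(i,j))/2`. Ties in `Q` are broken
#' by the lowest `(i, j)` index pair in the current node ordering, making
#' the result deterministic across platforms. Negative branch lengths are
#' retained by default (they keep the additivity identity exact); set
#' `clamp_negative = TRUE` to floor them at zero.
#'
#' On an additive (tree-realizable) matrix, path lengths on the returned
#' tree reproduce the input distances exactly.
#'
#' @param d Symmetric distance matrix with dimnames (e.g. from
#'   [hamming_matrix()] or [k80_matrix()]), or a [stats::dist] object.
#' @param clamp_negative Floor negative branch lengths at zero.
#' @return An unrooted [ape] `phylo` object. For `k >= 3` taxa every
#'   internal node has degree 3 (the basal node is the trifurcation).
#' @examples
#' d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' nj_tree(d)
#' @export
nj_tree <- function(d, clamp_negative = FALSE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > 1e-12) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  labels <- rownames(d)

  if (n == 2L) {
    tr <- structure(list(
      edge = matrix(c(3L, 3L, 1L, 2L), 2L),
      edge.length = rep(d[1L, 2L] / 2, 2L),
      tip.label = labels, Nnode = 1L
    ), class = "phylo", order = "cladewise")
    return(tr)
  }

  # active node ids: tips are 1..n; internal nodes get n+1, n+2, ...
  act <- seq_len(n)
  D <- d
  next_id <- n + 1L
  parent <- child <- integer(0)
  elen <- numeric(0)

  while (length(act) > 3L) {
    r <- length(act)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    ut <- upper.tri(Q)
    qmin <- min(Q[ut])
    cand <- which(ut & Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    parent <- c(parent, next_id, next_id)
    child <- c(child, act[i], act[j])
    elen <- c(elen, vi, vj)
    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D <- rbind(cbind(D, dn), c(dn, 0))[-c(i, j), -c(i, j), drop = FALSE]
    # new node joins at the end of the active list
    act <- c(act[-c(i, j)], next_id)
    next_id <- next_id + 1L
  }

  # terminal trifurcation over the last three nodes
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  parent <- c(parent, rep(next_id, 3L))
  child <- c(child, act)
  elen <- c(elen, va, vb, vc)

  if (clamp_negative) elen <- pmax(elen, 0)
  as_phylo_from_edges(parent, child, elen, labels, root = next_id)
}

#' Nonparametric bootstrap support for tree edges
#'
#' Builds `B` pseudo-alignments by sampling alignment columns with
#' replacement (seeded), applies the distance + NJ tree builder to each,
#' and scores every internal edge of the reference tree by the percentage
#' of replicate trees containing the same unrooted bipartition of tip
#' labels (branch lengths ignored; support rounded to the nearest integer).
#' A replicate whose distance matrix is undefined (K80 saturation) is
#' redrawn, up to 10 attempts, and the redraw count is recorded in the
#' `"redraws"` attribute.
#'
#' @param al Alignment tibble (`label`, `sequence`).
#' @param B Number of bootstrap replicates (>= 1; the workflow default
#'   used for the reference figures is 100).
#' @param seed Integer seed; the support vector is reproducible for a
#'   fixed seed.
#' @param model Distance used by the tree builder: `"hamming"` or `"k80"`.
#' @param ... Further arguments to [k80_matrix()] (e.g. `site_policy`).
#' @return The reference NJ tree (`phylo`) with integer support
#'   percentages in `node.label` (NA on the basal trifurcation, which is
#'   not an edge) and attributes `bootstrap_B` and `redraws`.
#' @export
bootstrap_support <- function(al, B = 100L, seed = 1L,
                              model = c("hamming", "k80"), ...) {
  model <- match.arg(model)
  al <- validate_alignment(al)
  stopifnot(B >= 1L)
  dist_fun <- switch(model,
    hamming = function(a) hamming_matrix(stats::setNames(a$sequence, a$label)),
    k80 = function(a) k80_matrix(a, ...)
  )
  ref <- nj_tree(dist_fun(al))
  ref_splits <- tree_splits(ref)
  counts <- stats::setNames(integer(length(ref_splits$key)), ref_splits$key)

  m <- alignment_matrix(al)
  L <- ncol(m)
  set.seed(seed)
  redraws <- 0L
  for (b in seq_len(B)) {
    rep_tree <- NULL
    for (attempt in seq_len(10L)) {
      cols <- sample.int(L, L, replace = TRUE)
      ps <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
      boot_al <- tibble::tibble(label = al$label, sequence = unname(ps))
      rep_tree <- tryCatch(nj_tree(dist_fun(boot_al)), error = function(e) NULL)
      if (!is.null(rep_tree)) break
      redraws <- redraws + 1L
    }
    if (is.null(rep_tree)) {
      stop("bootstrap replicate ", b, " failed after 10 redraws ",
           "(undefined distances)", call. = FALSE)
    }
    hit <- ref_splits$key %in% tree_splits(rep_tree)$key
    counts[hit] <- counts[hit] + 1L
  }

  support <- as.integer(round(100 * counts / B))
  node.label <- rep(NA_integer_, ref$Nnode)
  node.label[ref_splits$node - length(ref$tip.label)] <- support
  ref$node.label <- node.label
  attr(ref, "bootstrap_B") <- B
  attr(ref, "redraws") <- redraws
  ref
}

#' Bin a bootstrap support percentage into confidence categories
#'
#' Default intervals are left-open right-closed, as produced by
#' `cut(support, c(0, 50, 70, 85, 100))`: `(0,50]` poor, `(50,70]` weak,
#' `(70,85]` moderate, `(85,100]` strong (support 0 is poor). With
#' `closed_left = TRUE` the boundaries move down one class at the left
#' edge: `>= 85` strong, `[70,85)` moderate, `[50,70)` weak, `< 50` poor.
#'
#' @param s Numeric vector of supports in `[0, 100]`.
#' @param closed_left Use the "85 and above is strong" convention.
#' @return An ordered factor with levels `poor < weak < moderate < strong`.
#' @examples
#' bin_support(c(90, 85, 50))
#' bin_support(85, closed_left = TRUE)
#' @export
bin_support <- function(s, closed_left = FALSE) {
  if (any(is.na(s)) || any(s < 0 | s > 100)) {
    stop("support values must lie in [0, 100]", call. = FALSE)
  }
  lev <- c("poor", "weak", "moderate", "strong")
  idx <- if (closed_left) {
    findInterval(s, c(50, 70, 85)) + 1L
  } else {
    4L - findInterval(-s, -c(85, 70, 50))
  }
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Serialize a tree to Newick text
#'
#' Writes standard Newick with branch lengths at the given precision;
#' internal-node supports (in `node.label`) are emitted as internal node
#' labels. Labels containing Newick metacharacters or whitespace are
#' single-quoted, so `ape::read.tree(text = write_newick(t))` round-trips
#' topology, branch lengths and labels exactly.
#'
#' @param t A `phylo` object.
#' @param precision Significant digits for branch lengths (default 10).
#' @param path Optional file to write the string to.
#' @return The Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(t, precision = 10L, path = NULL) {
  stopifnot(inherits(t, "phylo"))
  n <- length(t$tip.label)
  root <- n + 1L
  kids <- split(seq_len(nrow(t$edge)), t$edge[, 1L])
  fmt_len <- function(e) {
    if (is.null(t$edge.length)) "" else
      paste0(":", format(t$edge.length[e], digits = precision,
                         trim = TRUE, scientific = FALSE))
  }
  quote_label <- function(x) {
    x <- as.character(x)
    needs <- grepl("[][(),:;'\\s]", x, perl = TRUE)
    x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
    x
  }
  node_label <- function(node) {
    if (is.null(t$node.label)) return("")
    lab <- t$node.label[node - n]
    if (is.na(lab) || !nzchar(as.character(lab))) "" else
      quote_label(as.character(lab))
  }
  render <- function(node) {
    if (node <= n) return(quote_label(t$tip.label[node]))
    inner <- vapply(kids[[as.character(node)]], function(e) {
      paste0(render(t$edge[e, 2L]), fmt_len(e))
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")", node_label(node))
  }
  out <- paste0(render(root), ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Parse a Newick string or file into a tree
#'
#' Thin wrapper over [ape::read.tree()], the inverse of [write_newick()]:
#' `read_newick(write_newick(t))` is topology- and length-identical to `t`.
#'
#' @param text Newick string (or `NULL` when reading from `path`).
#' @param path Optional file to read instead of `text`.
#' @return A `phylo` object.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text) == is.null(path)) {
    stop("supply exactly one of `text` or `path`", call. = FALSE)
  }
  t <- if (!is.null(path)) ape::read.tree(file = path) else
    ape::read.tree(text = text)
  unquote <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
    x
  }
  t$tip.label <- unquote(t$tip.label)
  if (!is.null(t$node.label)) t$node.label <- unquote(t$node.label)
  t
}

#' Nontrivial unrooted bipartitions of a tree
#'
#' For every internal edge, the set of tip labels on the child side is
#' canonicalized (the side not containing the alphabetically first tip,
#' sorted and concatenated) so that bipartitions can be compared across
#' trees regardless of rooting or label order.
#'
#' @param t A `phylo` object.
#' @return A tibble with columns `node` (child node number of the edge),
#'   `key` (canonical bipartition key) and `tips` (list column of the tip
#'   labels on the child side).
#' @export
tree_splits <- function(t) {
  stopifnot(inherits(t, "phylo"))
  n <- length(t$tip.label)
  root <- n + 1L
  anchor <- sort(t$tip.label)[1L]
  internal <- setdiff(unique(t$edge[, 1L]), root)
  # also internal children of root beyond the basal node itself
  internal <- sort(unique(c(internal, t$edge[t$edge[, 2L] > n, 2L])))
  kids <- split(t$edge[, 2L], t$edge[, 1L])
  clade_tips <- function(node) {
    if (node <= n) return(t$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], clade_tips), use.names = FALSE)
  }
  rows <- lapply(internal, function(node) {
    tips <- clade_tips(node)
    if (length(tips) <= 1L || length(tips) >= n - 1L) return(NULL)
    side <- if (anchor %in% tips) setdiff(t$tip.label, tips) else tips
    tibble::tibble(node = node, key = paste(sort(side), collapse = "\r"),
                   tips = list(tips))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(node = integer(0), key = character(0),
                          tips = list())
  }
  out
}

#' Support table for a bootstrapped tree
#'
#' @param t A `phylo` with supports in `node.label` (see
#'   [bootstrap_support()]).
#' @return Tibble with columns `node`, `support`, `bin` and `tips` (the
#'   smaller side of the bipartition).
#' @export
support_table <- function(t) {
  sp <- tree_splits(t)
  n <- length(t$tip.label)
  sp$support <- as.integer(t$node.label[sp$node - n])
  sp$bin <- bin_support(sp$support)
  sp[, c("node", "support", "bin", "tips")]
}

# Build a valid ape phylo from parent/child edge vectors whose internal ids
# are arbitrary: renumber internal nodes in preorder from `root` so tips
# stay 1..n and internals are n+1 .. 2n-2.
as_phylo_from_edges <- function(parent, child, elen, tip_labels, root) {
  n <- length(tip_labels)
  kids <- split(seq_along(parent), parent)
  new_id <- integer(max(c(parent, child)))
  new_id[seq_len(n)] <- seq_len(n)
  counter <- n
  edge <- matrix(0L, length(parent), 2L)
  elen_out <- numeric(length(parent))
  k <- 0L
  descend <- function(node) {
    for (e in kids[[as.character(node)]]) {
      ch <- child[e]
      if (ch > n) {
        counter <<- counter + 1L
        new_id[ch] <<- counter
      }
      k <<- k + 1L
      edge[k, ] <<- c(new_id[node], new_id[ch])
      elen_out[k] <<- elen[e]
      if (ch > n) descend(ch)
    }
  }
  counter <- counter + 1L
  new_id[root] <- counter
  descend(root)
  structure(list(
    edge = edge,
    edge.length = elen_out,
    tip.label = tip_labels,
    Nnode = counter - n
  ), class = "phylo", order = "cladewise")
}
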