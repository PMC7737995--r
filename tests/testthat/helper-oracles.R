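# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately avoid the package's own algorithms.

toy_alignment <- function(seqs, labels = NULL) {
  if (is.null(labels)) labels <- paste0("S", seq_along(seqs))
  tibble::tibble(label = labels, sequence = seqs)
}

# brute-force polymorphic column scan
bf_variable_positions <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  which(apply(m, 2L, function(col) length(unique(col)) >= 2L))
}

# brute-force Hamming
bf_hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

# exhaustive minimum spanning tree weight: enumerate all (k-1)-edge subsets
# of the complete graph and keep the connected ones
bf_mst_weight <- function(d) {
  k <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  best <- Inf
  for (sel in utils::combn(nrow(pairs), k - 1L, simplify = FALSE)) {
    comp <- seq_len(k)
    for (r in sel) {
      ci <- comp[pairs[r, 1L]]; cj <- comp[pairs[r, 2L]]
      comp[comp == cj] <- ci
    }
    if (length(unique(comp)) == 1L) {
      best <- min(best, sum(d[pairs[sel, , drop = FALSE]]))
    }
  }
  best
}

# maximum link weight on the MST path between two nodes (BFS over mst links)
mst_path_max <- function(links, from, to) {
  mst <- links[links$kind == "mst", ]
  adj <- split(
    data.frame(nb = c(mst$to, mst$from), w = c(mst$weight, mst$weight)),
    c(mst$from, mst$to)
  )
  seen <- stats::setNames(list(NULL), from)
  queue <- list(list(node = from, mx = 0))
  while (length(queue) > 0L) {
    cur <- queue[[1L]]; queue <- queue[-1L]
    if (cur$node == to) return(cur$mx)
    for (r in seq_len(NROW(adj[[cur$node]]))) {
      nb <- adj[[cur$node]]$nb[r]
      if (!nb %in% names(seen)) {
        seen[[nb]] <- TRUE
        queue <- c(queue, list(list(node = nb,
                                    mx = max(cur$mx, adj[[cur$node]]$w[r]))))
      }
    }
  }
  stop("nodes not connected in MST")
}

# a hapset-shaped table for network tests over an arbitrary distance matrix
fake_hapset <- function(ids) {
  hs <- tibble::tibble(
    haplotype = ids,
    sequence = paste0("seq", seq_along(ids)),
    hf = 1L,
    pct = round(100 / length(ids), 2),
    members = as.list(paste0(ids, "_m"))
  )
  attr(hs, "n_samples") <- length(ids)
  class(hs) <- c("hapset", class(hs))
  hs
}

random_integer_distance <- function(k, max_w = 9L) {
  d <- matrix(0L, k, k)
  d[upper.tri(d)] <- sample.int(max_w, k * (k - 1L) / 2L, replace = TRUE)
  d <- d + t(d)
  dimnames(d) <- list(paste0("N", seq_len(k)), paste0("N", seq_len(k)))
  d
}

reference_groups <- c(
  Aksu = "greenhouse", Demre = "greenhouse", Kumluca = "greenhouse",
  Firm = "firm",
  Bayatbadem = "nature", Phaselis = "nature", Geyikbayir = "nature",
  Termessos = "nature"
)
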