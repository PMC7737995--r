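#' Pairwise Hamming distance matrix
#'
#' The Hamming distance between two equal-length strings is the number of
#' positions at which they differ; all characters (including gaps, `N` and
#' ambiguity codes) are compared literally. Invariant columns contribute
#' zero, so Hamming on variable-site strings equals Hamming on the full
#' sequences for the same pair.
#'
#' @param x Either a data frame with an id column (`haplotype` or `label`)
#'   and a string column (`sites` or `sequence`), or a named character
#'   vector of equal-length strings.
#' @return A symmetric integer matrix with zero diagonal, dimnames set to
#'   the ids, and attribute `metric = "hamming"`.
#' @examples
#' hamming_matrix(c(a = "ACGT", b = "ACGA", c = "TCGA"))
#' @export
hamming_matrix <- function(x) {
  s <- as_id_strings(x)
  if (length(s) < 2L) {
    stop("need at least 2 sequences", call. = FALSE)
  }
  if (length(unique(nchar(s))) != 1L) {
    stop("sequences have unequal lengths", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(s, "", fixed = TRUE))
  k <- nrow(m)
  d <- matrix(0L, k, k, dimnames = list(names(s), names(s)))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  attr(d, "metric") <- "hamming"
  d
}

#' Kimura two-parameter (K80) distance from substitution proportions
#'
#' Under the K80 model, with `p` the proportion of sites showing a
#' transition difference (A<->G or C<->T) and `q` the proportion showing a
#' transversion difference, the evolutionary distance is
#' `d = -(1/2) log(1 - 2p - q) - (1/4) log(1 - 2q)`.
#' The distance is undefined when `1 - 2p - q <= 0` or `1 - 2q <= 0`
#' (saturation); this is reported as an error, never a silent `NaN`.
#'
#' @param p Proportion of transition differences (`>= 0`).
#' @param q Proportion of transversion differences (`>= 0`, `p + q <= 1`).
#' @return The K80 distance, a nonnegative real. `p = q = 0` gives 0.
#' @examples
#' k80_distance(0.1, 0.05)
#' @export
k80_distance <- function(p, q) {
  stopifnot(p >= 0, q >= 0, p + q <= 1)
  a <- 1 - 2 * p - q
  b <- 1 - 2 * q
  if (a <= 0 || b <= 0) {
    stop("K80 distance undefined: substitution proportions too large ",
         "(p = ", p, ", q = ", q, ")", call. = FALSE)
  }
  -0.5 * log(a) - 0.25 * log(b)
}

#' K80 distance matrix over an alignment
#'
#' Per pair of sequences, counts transition and transversion proportions
#' over the usable sites and applies [k80_distance()]. Only definite bases
#' A/C/G/T are usable: under `"global-deletion"` (the default) every column
#' containing any non-ACGT character in any sequence is dropped before all
#' comparisons; under `"pairwise-deletion"` each pair uses the columns where
#' both of its sequences have definite bases.
#'
#' @param al Alignment tibble (`label`, `sequence`), or a `hapset` (its
#'   `haplotype`/`sequence` columns are used).
#' @param site_policy `"global-deletion"` or `"pairwise-deletion"`.
#' @return A symmetric numeric matrix with attribute `metric = "K80"`.
#' @export
k80_matrix <- function(al, site_policy = c("global-deletion",
                                           "pairwise-deletion")) {
  site_policy <- match.arg(site_policy)
  s <- as_id_strings(al)
  if (length(s) < 2L) {
    stop("need at least 2 sequences", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(s, "", fixed = TRUE))
  ok <- m == "A" | m == "C" | m == "G" | m == "T"
  if (site_policy == "global-deletion") {
    keep <- apply(ok, 2L, all)
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  purine <- m == "A" | m == "G"
  k <- nrow(m)
  d <- matrix(0, k, k, dimnames = list(names(s), names(s)))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      use <- ok[i, ] & ok[j, ]
      n_use <- sum(use)
      if (n_use == 0L) {
        stop("no usable sites for pair ", names(s)[i], " / ", names(s)[j],
             call. = FALSE)
      }
      diff <- use & (m[i, ] != m[j, ])
      ts <- sum(diff & (purine[i, ] == purine[j, ]))  # A<->G or C<->T
      tv <- sum(diff) - ts
      d[i, j] <- d[j, i] <- k80_distance(ts / n_use, tv / n_use)
    }
  }
  attr(d, "metric") <- "K80"
  d
}

#' Long-format view of a distance matrix
#'
#' @param d Symmetric distance matrix with dimnames.
#' @param upper Include the upper triangle (default `FALSE`: each unordered
#'   pair once).
#' @return Tibble with columns `from`, `to`, `distance`.
#' @export
dist_tibble <- function(d, upper = FALSE) {
  stopifnot(is.matrix(d), !is.null(rownames(d)))
  idx <- which(if (upper) row(d) != col(d) else lower.tri(d), arr.ind = TRUE)
  tibble::tibble(
    from = rownames(d)[idx[, 2L]],
    to = rownames(d)[idx[, 1L]],
    distance = d[idx]
  )
}

#' Write a distance matrix as TSV
#'
#' @param d Symmetric distance matrix with dimnames.
#' @param path Output path.
#' @param format `"lower"` for a lower-triangular layout (first row is the
#'   column header over labels 1..k-1, each subsequent row one label and its
#'   distances to the preceding labels) or `"square"` for the full matrix.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(d, path, format = c("lower", "square")) {
  format <- match.arg(format)
  labs <- rownames(d)
  k <- length(labs)
  if (format == "square") {
    utils::write.table(cbind(data.frame(id = labs), as.data.frame(d)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- c(paste(c("", labs[-k]), collapse = "\t"),
               vapply(seq(2L, k), function(i) {
                 paste(c(labs[i], format(d[i, seq_len(i - 1L)],
                                         trim = TRUE, scientific = FALSE)),
                       collapse = "\t")
               }, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}

# Accepts a hapset/alignment-like data frame or a named character vector and
# returns a named character vector of sequences.
as_id_strings <- function(x) {
  if (is.data.frame(x)) {
    id_col <- intersect(c("haplotype", "label"), names(x))[1L]
    str_col <- intersect(c("sites", "sequence"), names(x))[1L]
    if (is.na(id_col) || is.na(str_col)) {
      stop("data frame must have an id column (haplotype/label) and a ",
           "string column (sites/sequence)", call. = FALSE)
    }
    stats::setNames(x[[str_col]], x[[id_col]])
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("S", seq_along(x))
    x
  } else {
    stop("cannot interpret input as labelled sequences", call. = FALSE)
  }
}
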