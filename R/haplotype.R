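#' Collapse identical sequences into haplotypes
#'
#' Exact string equality (after the read-time normalization of
#' [read_fasta()]) defines haplotype membership: gaps and `N` are literal
#' states, never wildcards, so the partition is well defined. Haplotypes are
#' numbered `H1..Hk` in order of first appearance in the alignment.
#'
#' @param al Alignment tibble (`label`, `sequence`).
#' @return A `hapset` tibble with one row per haplotype and columns
#'   `haplotype` (id), `sequence` (full sequence), `hf` (count), `pct`
#'   (percentage of samples, round-half-up to 2 decimals) and `members`
#'   (list column of sample labels). Attribute `n_samples` holds the sample
#'   total N.
#' @examples
#' al <- tibble::tibble(label = c("P_1", "P_2", "Q_1"),
#'                      sequence = c("ACGT", "ACGT", "ACGA"))
#' collapse_haplotypes(al)
#' @export
collapse_haplotypes <- function(al) {
  al <- validate_alignment(al)
  first <- !duplicated(al$sequence)
  uniq <- al$sequence[first]
  idx <- match(al$sequence, uniq)
  hf <- tabulate(idx, nbins = length(uniq))
  n <- nrow(al)
  hs <- tibble::tibble(
    haplotype = paste0("H", seq_along(uniq)),
    sequence = uniq,
    hf = hf,
    pct = round_half_up(100 * hf / n, 2L),
    members = unname(split(al$label, factor(idx, levels = seq_along(uniq))))
  )
  attr(hs, "n_samples") <- n
  class(hs) <- c("hapset", class(hs))
  hs
}

#' Extract the variable (polymorphic) sites of a haplotype set
#'
#' Returns exactly the alignment columns with at least two distinct states
#' across the haplotype sequences, in ascending position order. By default a
#' gap/`N` difference makes a site variable (all characters are compared
#' literally); `acgt_only = TRUE` restricts variability to differences among
#' `A`, `C`, `G`, `T`.
#'
#' @param hs A `hapset` from [collapse_haplotypes()], or any data frame with
#'   `haplotype` and `sequence` columns.
#' @param acgt_only If `TRUE`, only A/C/G/T differences count as variation.
#' @return A tibble with columns `haplotype` and `sites` (the concatenated
#'   states at the variable positions). Attribute `positions` holds the
#'   1-based site indices (strictly increasing). With a single haplotype the
#'   table has zero positions and empty `sites` strings.
#' @export
variable_sites <- function(hs, acgt_only = FALSE) {
  stopifnot(is.data.frame(hs), all(c("haplotype", "sequence") %in% names(hs)),
            nrow(hs) >= 1L)
  m <- do.call(rbind, strsplit(hs$sequence, "", fixed = TRUE))
  poly <- apply(m, 2L, function(col) {
    states <- unique(col)
    if (acgt_only) states <- intersect(states, c("A", "C", "G", "T"))
    length(states) >= 2L
  })
  pos <- which(poly)
  out <- tibble::tibble(
    haplotype = hs$haplotype,
    sites = apply(m[, pos, drop = FALSE], 1L, paste, collapse = "")
  )
  attr(out, "positions") <- as.integer(pos)
  out
}

#' Render a variable-site table in dot notation
#'
#' The reference row is written verbatim; in every other row, a position
#' equal to the reference is printed as `.` and a differing state is printed
#' literally. The rendering is invertible given the reference row (see
#' [dot_expand()]).
#'
#' @param vst Variable-site table from [variable_sites()] (columns
#'   `haplotype`, `sites`), or any tibble of equal-length strings in a
#'   `sites` column.
#' @param reference_row Index of the reference haplotype (default 1).
#' @return A tibble with columns `haplotype` and `pattern`.
#' @export
dot_notation <- function(vst, reference_row = 1L) {
  stopifnot(is.data.frame(vst), all(c("haplotype", "sites") %in% names(vst)))
  k <- nrow(vst)
  if (reference_row < 1L || reference_row > k) {
    stop("reference_row must be between 1 and ", k, call. = FALSE)
  }
  ref <- strsplit(vst$sites[reference_row], "", fixed = TRUE)[[1L]]
  pattern <- vapply(vst$sites, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    paste(ifelse(ch == ref, ".", ch), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  pattern[reference_row] <- vst$sites[reference_row]
  tibble::tibble(haplotype = vst$haplotype, pattern = pattern)
}

#' Expand dot-notation patterns against a reference string
#'
#' Inverse of [dot_notation()]: each `.` takes the reference state, any
#' other character stands for itself.
#'
#' @param pattern Character vector of dot-notation strings.
#' @param reference Reference string (printed verbatim in the table).
#' @return Character vector of full state strings.
#' @export
dot_expand <- function(pattern, reference) {
  ref <- strsplit(reference, "", fixed = TRUE)[[1L]]
  vapply(pattern, function(p) {
    ch <- strsplit(p, "", fixed = TRUE)[[1L]]
    if (length(ch) != length(ref)) {
      stop("pattern length ", length(ch), " does not match reference length ",
           length(ref), call. = FALSE)
    }
    paste(ifelse(ch == ".", ref, ch), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Haplotype frequency matrix by population or group
#'
#' Tabulates, for each haplotype, how many of its member samples belong to
#' each population (or group). Row sums equal the haplotype frequencies
#' `hf`; column sums equal the population (group) sizes; the grand total is
#' the sample count N.
#'
#' @param hs A `hapset` from [collapse_haplotypes()].
#' @param pm Population map from [build_population_map()].
#' @param level `"population"` (default) or `"group"`.
#' @return A tibble with a `haplotype` column followed by one integer count
#'   column per population/group (columns in alphabetical order).
#' @export
population_matrix <- function(hs, pm, level = c("population", "group")) {
  level <- match.arg(level)
  stopifnot(is.data.frame(hs), "members" %in% names(hs))
  if (level == "group" && !"group" %in% names(pm)) {
    stop("population map has no group column; supply `groups` to ",
         "build_population_map()", call. = FALSE)
  }
  key <- stats::setNames(pm[[level]], pm$label)
  all_members <- unlist(hs$members, use.names = FALSE)
  unmapped <- setdiff(all_members, names(key))
  if (length(unmapped) > 0L) {
    stop("sample label(s) missing from the population map: ",
         paste(utils::head(unmapped, 5L), collapse = ", "), call. = FALSE)
  }
  cats <- sort(unique(unname(key)))
  counts <- matrix(
    vapply(hs$members, function(mem) {
      as.integer(table(factor(unname(key[mem]), levels = cats)))
    }, integer(length(cats))),
    nrow = length(cats)
  )
  out <- tibble::as_tibble(t(counts), .name_repair = "minimal")
  names(out) <- cats
  out <- dplyr::bind_cols(tibble::tibble(haplotype = hs$haplotype), out)
  attr(out, "level") <- level
  out
}

#' @describeIn collapse_haplotypes Tidy summary: one row per haplotype,
#'   without the list column.
#' @param x A `hapset`.
#' @param ... Unused.
#' @export
tidy.hapset <- function(x, ...) {
  tibble::as_tibble(x)[, c("haplotype", "hf", "pct", "sequence")]
}

#' @describeIn collapse_haplotypes One-row summary: number of haplotypes,
#'   sample count, modal haplotype and its frequency.
#' @export
glance.hapset <- function(x, ...) {
  mode_i <- which.max(x$hf)
  tibble::tibble(
    n_haplotypes = nrow(x),
    n_samples = attr(x, "n_samples"),
    modal_haplotype = x$haplotype[mode_i],
    modal_hf = x$hf[mode_i],
    modal_pct = x$pct[mode_i]
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

# round-half-up to `digits` decimals; base round() is round-half-even and
# would print 45.82 for 55/120
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}
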