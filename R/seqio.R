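#' Read an aligned multi-sequence FASTA file
#'
#' Reads a DNA FASTA file into an alignment tibble. Sequences are uppercased
#' and `U` is mapped to `T` so the rest of the pipeline sees a single DNA
#' alphabet. Record order is preserved. By default the full header line
#' (minus the leading `>`) is the label, because sample labels in this
#' workflow may contain spaces (e.g. `"Bayatbadem 24"`); set
#' `label_from = "first-token"` to truncate labels at the first whitespace.
#'
#' @param path Path to a FASTA file with at least one record. Both
#'   line-wrapped and single-line sequence layouts are accepted.
#' @param label_from Either `"header"` (default, full header line) or
#'   `"first-token"`.
#' @return A tibble with columns `label` and `sequence`, one row per record.
#'   All sequences have equal length; labels are unique.
#' @examples
#' fas <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), fas)
#' read_fasta(fas)
#' @export
read_fasta <- function(path, label_from = c("header", "first-token")) {
  label_from <- match.arg(label_from)
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) {
    stop("not a FASTA file (first non-blank line is not a header): ", path,
         call. = FALSE)
  }
  labels <- sub("^>", "", lines[hdr])
  labels <- sub("\\s+$", "", labels)
  if (label_from == "first-token") {
    labels <- sub("\\s.*$", "", labels)
  }
  seqs <- split(lines[!hdr], cumsum(hdr)[!hdr])
  if (length(seqs) != length(labels)) {
    stop("FASTA record without sequence lines in ", path, call. = FALSE)
  }
  seqs <- vapply(seqs, paste0, character(1), collapse = "")
  new_alignment(labels, normalize_dna(unname(seqs)))
}

#' Write an alignment to FASTA
#'
#' Round-trip contract: `read_fasta(write_fasta(al, f))` reproduces `al`
#' exactly, including record order.
#'
#' @param al Alignment tibble (`label`, `sequence`).
#' @param path Output file path.
#' @param width Line width for sequence wrapping; `Inf` writes one line per
#'   sequence (the default, keeping labels with spaces round-trip safe).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(al, path, width = Inf) {
  al <- validate_alignment(al)
  seqs <- al$sequence
  if (is.finite(width)) {
    seqs <- vapply(seqs, function(s) {
      paste(substring(s, seq(1L, nchar(s), width),
                      pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s))),
            collapse = "\n")
    }, character(1))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0(">", al$label, "\n", seqs), con)
  invisible(path)
}

#' Parse a population name out of a sample label
#'
#' Sample labels encode population membership as `<Population><sep><number>`
#' with separator underscore or space, e.g. `"Kumluca_6"` or
#' `"Bayatbadem 24"`. The rule strips the final maximal run of digits plus
#' the single underscore/space immediately before it, so multi-part names
#' like `"Geyik_bayir_3"` keep their interior separators. A label with no
#' trailing digits is returned unchanged. Idempotent.
#'
#' @param label Character vector of sample labels.
#' @return Character vector of population names.
#' @examples
#' parse_population(c("Kumluca_6", "Bayatbadem 24", "Firm"))
#' @export
parse_population <- function(label) {
  if (any(!nzchar(label))) {
    stop("empty sample label", call. = FALSE)
  }
  pop <- sub("[ _]?[0-9]+$", "", label)
  bad <- !nzchar(pop)
  if (any(bad)) {
    stop("label(s) reduce to an empty population name: ",
         paste(unique(label[bad]), collapse = ", "), call. = FALSE)
  }
  pop
}

#' Build the sample-to-population (and optional group) map
#'
#' Populations are inferred from the alignment labels via
#' [parse_population()]. An optional population-to-group mapping is attached
#' verbatim; it must cover every population present.
#'
#' @param al Alignment tibble.
#' @param groups Optional named character vector or two-column data frame
#'   (`population`, `group`) mapping each population to a group.
#' @return A tibble with columns `label`, `population` and (when `groups` is
#'   given) `group`.
#' @export
build_population_map <- function(al, groups = NULL) {
  al <- validate_alignment(al)
  pm <- tibble::tibble(
    label = al$label,
    population = parse_population(al$label)
  )
  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      grp <- stats::setNames(as.character(groups[[2L]]),
                             as.character(groups[[1L]]))
    } else {
      grp <- groups
    }
    missing <- setdiff(unique(pm$population), names(grp))
    if (length(missing) > 0L) {
      stop("group mapping is missing population(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    pm$group <- unname(grp[pm$population])
  }
  pm
}

#' Read a population-to-group mapping from a two-column TSV
#'
#' Expected columns: `population<TAB>group`, with or without a header line.
#'
#' @param path TSV file path.
#' @return Named character vector, `population -> group`.
#' @export
read_group_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) {
    stop("group mapping TSV must have two columns (population, group)",
         call. = FALSE)
  }
  if (identical(tolower(df[1L, 1L]), "population")) {
    df <- df[-1L, , drop = FALSE]
  }
  stats::setNames(df[[2L]], df[[1L]])
}

#' Trim gap-rich alignment ends
#'
#' Removes leading and trailing columns whose fraction of missing characters
#' (`-`, `N`, `?`) exceeds `max_missing_fraction`. Interior columns are never
#' touched and surviving characters are never altered. The number of columns
#' removed from the left is recorded in the `"trim_offset"` attribute so that
#' 1-based positions reported downstream can be related back to the input
#' coordinates.
#'
#' @param al Alignment tibble.
#' @param max_missing_fraction Real in `[0, 1]`; a flank column is dropped
#'   when its missing fraction is strictly greater than this.
#' @return The trimmed alignment tibble with attribute `trim_offset`.
#' @export
trim_ends <- function(al, max_missing_fraction = 0.5) {
  al <- validate_alignment(al)
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  m <- alignment_matrix(al)
  miss <- colMeans(m == "-" | m == "N" | m == "?")
  bad <- miss > max_missing_fraction
  keep_from <- match(FALSE, bad)
  keep_to <- length(bad) + 1L - match(FALSE, rev(bad))
  if (is.na(keep_from)) {
    stop("trimming at max_missing_fraction = ", max_missing_fraction,
         " would remove every column", call. = FALSE)
  }
  out <- new_alignment(
    al$label,
    unname(apply(m[, keep_from:keep_to, drop = FALSE], 1L, paste,
                 collapse = ""))
  )
  attr(out, "trim_offset") <- keep_from - 1L
  out
}

# --- internal helpers -------------------------------------------------------

normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

new_alignment <- function(labels, sequences) {
  validate_alignment(tibble::tibble(label = labels, sequence = sequences))
}

validate_alignment <- function(al) {
  if (!is.data.frame(al) || !all(c("label", "sequence") %in% names(al))) {
    stop("an alignment must be a data frame with columns 'label' and 'sequence'",
         call. = FALSE)
  }
  al <- tibble::as_tibble(al[, c("label", "sequence",
                                 setdiff(names(al), c("label", "sequence")))])
  if (nrow(al) == 0L) {
    stop("alignment has no records", call. = FALSE)
  }
  if (anyNA(al$label) || any(!nzchar(al$label))) {
    stop("alignment labels must be non-empty", call. = FALSE)
  }
  dup <- unique(al$label[duplicated(al$label)])
  if (length(dup) > 0L) {
    stop("duplicate record label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  len <- nchar(al$sequence)
  if (length(unique(len)) != 1L) {
    tab <- split(al$label, len)
    msg <- paste(vapply(names(tab), function(l) {
      paste0("length ", l, ": ", paste(utils::head(tab[[l]], 3L), collapse = ", "))
    }, character(1)), collapse = "; ")
    stop("sequences have unequal lengths (", msg, ")", call. = FALSE)
  }
  if (len[1L] == 0L) {
    stop("alignment has zero columns", call. = FALSE)
  }
  al
}

alignment_length <- function(al) nchar(al$sequence[1L])

# character matrix view, rows = records, columns = 1-based sites
alignment_matrix <- function(al) {
  m <- do.call(rbind, strsplit(al$sequence, "", fixed = TRUE))
  rownames(m) <- al$label
  m
}
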