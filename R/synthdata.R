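#' Generate a synthetic haplotype alignment with known truth
#'
#' Emulates the structure of the workflow's input data: a random ancestral
#' sequence, `k` planted haplotypes each carrying a distinct random set of
#' substitutions (no indels, matching gapless mtDNA data; the first
#' haplotype is the unmutated ancestor itself), and individuals
#' named `<Pop>_<i>` assigned to populations by a seeded scheme. Every
#' planted haplotype is guaranteed to appear in at least one individual, so
#' [collapse_haplotypes()] recovers exactly the planted partition and
#' counts.
#'
#' The `mixing` parameter controls how strongly haplotypes are tied to
#' populations: at `mixing = 1` every population draws haplotypes from the
#' same pool; at `mixing = 0` each population (beyond the guaranteed
#' coverage draws) uses only its own "private" haplotype plus the shared
#' dominant haplotype `H1` — emulating the typical mtDNA pattern of private
#' haplotypes around one dominant shared haplotype.
#'
#' @param k Number of planted haplotypes (`k >= 1`).
#' @param L Alignment length in sites (default 373, a cytochrome-b
#'   fragment length typical of this kind of survey).
#' @param pops Named integer vector of population sizes
#'   (default: 8 populations of 15, the reference design). `sum(pops)`
#'   must be `>= k`.
#' @param divergence Integer range `c(min, max)`: number of substitutions
#'   separating each planted haplotype from the ancestor.
#' @param mixing Real in `[0, 1]`, see above.
#' @param seed Integer seed; output is byte-identical across runs for a
#'   fixed seed. The caller's RNG state is left untouched.
#' @return A list with `alignment` (tibble `label`, `sequence`) and
#'   `truth`: planted `haplotypes` (strings), `assignment` (k x n_pops
#'   integer count matrix), `ancestor`, `mutation_positions` (list), and
#'   `seed`.
#' @export
generate_dataset <- function(k, L = 373L,
                             pops = stats::setNames(rep(15L, 8L),
                                                    paste0("Pop", 1:8)),
                             divergence = c(1L, 10L),
                             mixing = 0.5, seed = 1L) {
  stopifnot(k >= 1L, L >= 1L, all(pops >= 0L), sum(pops) >= k,
            length(divergence) == 2L, divergence[1L] <= divergence[2L],
            divergence[2L] <= L, mixing >= 0, mixing <= 1,
            k == 1L || divergence[1L] >= 1L)
  if (is.null(names(pops))) names(pops) <- paste0("Pop", seq_along(pops))
  n <- sum(pops)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    ancestor <- sample(bases, L, replace = TRUE)
    haps <- character(0)
    mut_pos <- vector("list", k)
    # haplotype 1 is the unmutated ancestor (the dominant shared variant);
    # this also guarantees that the MST over haplotype distances never
    # exceeds the planted mutation total
    for (h in seq_len(k)) {
      repeat {
        n_mut <- if (h == 1L) 0L else
          sample(seq(divergence[1L], divergence[2L]), 1L)
        pos <- sort(sample.int(L, n_mut))
        s <- ancestor
        for (p in pos) s[p] <- sample(setdiff(bases, ancestor[p]), 1L)
        s <- paste(s, collapse = "")
        if (!s %in% haps) break
      }
      haps <- c(haps, s)
      mut_pos[[h]] <- pos
    }

    # haplotype weights per population: shared dominant H1 + one private
    # haplotype per population, diluted towards uniform by `mixing`
    n_pop <- length(pops)
    private <- if (k >= 2L) 1L + (seq_len(n_pop) - 1L) %% (k - 1L) + 1L else
      rep(1L, n_pop)
    weights <- lapply(seq_len(n_pop), function(p) {
      w0 <- numeric(k)
      w0[1L] <- 2
      w0[private[p]] <- w0[private[p]] + 1
      mixing * rep(1 / k, k) + (1 - mixing) * w0 / sum(w0)
    })

    # draw haplotype indices per individual; first k draws cover all
    # haplotypes so the planted partition is recoverable
    pop_of <- rep(names(pops), pops)
    hap_of <- integer(n)
    cover <- sample.int(n, k)
    hap_of[cover] <- sample.int(k, k)
    for (i in setdiff(seq_len(n), cover)) {
      hap_of[i] <- sample.int(k, 1L,
                              prob = weights[[match(pop_of[i], names(pops))]])
    }

    labels <- unlist(lapply(names(pops), function(p) {
      paste0(p, "_", seq_len(pops[[p]]))
    }), use.names = FALSE)
    al <- new_alignment(labels, haps[hap_of])
    assignment <- matrix(
      vapply(seq_len(k), function(h) {
        as.integer(table(factor(pop_of[hap_of == h], levels = names(pops))))
      }, integer(n_pop)),
      nrow = n_pop
    )
    assignment <- t(assignment)
    dimnames(assignment) <- list(paste0("H", seq_len(k)), names(pops))
    list(
      alignment = al,
      truth = list(haplotypes = haps, assignment = assignment,
                   ancestor = paste(ancestor, collapse = ""),
                   mutation_positions = mut_pos, seed = seed)
    )
  })
}

#' Reference haplotype table fixture (20 cyt b haplotypes, 41 variable sites)
#'
#' The package ships, as plain TSV, the printed reference table of 20
#' cytochrome-b haplotypes from 120 buff-tailed bumblebee samples: the
#' dot-notation strings over the 41 variable sites, the haplotype
#' frequencies `hf` (summing to 120) and percentages `pct`. This function
#' loads it and expands the dot notation against the H1 reference row.
#'
#' @return A tibble with columns `haplotype`, `pattern` (dot notation),
#'   `sequence` (expanded 41-site string), `sites` (alias of `sequence`,
#'   so the result feeds [hamming_matrix()] and [dot_notation()] directly),
#'   `hf` and `pct`; attribute `n_samples = 120`.
#' @export
load_table1_fixture <- function() {
  df <- utils::read.delim(extdata_path("table1_haplotypes.tsv"),
                          stringsAsFactors = FALSE, colClasses = c(
                            haplotype = "character", pattern = "character",
                            hf = "integer", pct = "numeric"))
  out <- tibble::as_tibble(df)
  out$sequence <- dot_expand(out$pattern, out$pattern[1L])
  out$sites <- out$sequence
  attr(out, "n_samples") <- sum(out$hf)
  out[, c("haplotype", "pattern", "sequence", "sites", "hf", "pct")]
}

#' Reference haplotype-by-population count fixture
#'
#' Counts of each of the 20 reference haplotypes in each of the 8
#' populations (15 samples each; greenhouse populations Aksu, Demre,
#' Kumluca; nature populations Bayatbadem, Phaselis, Geyikbayir,
#' Termessos; plus a commercial Firm population). The shipped table is the
#' arithmetically consistent version: as printed, two Geyikbayir entries
#' sat on the wrong rows (H8/H10 instead of H9/H11), breaking the row-sum
#' identity with the haplotype frequencies; the shipped fixture restores
#' them so that row sums equal `hf` and every column sums to 15.
#'
#' @return A tibble `haplotype` + 8 integer population columns.
#' @export
load_table2_fixture <- function() {
  tibble::as_tibble(utils::read.delim(
    extdata_path("table2_population_counts.tsv"),
    stringsAsFactors = FALSE, check.names = FALSE))
}

#' Reference Hamming distance matrix fixture
#'
#' The printed 20 x 20 haplotype Hamming distance matrix (lower triangle),
#' as a full symmetric integer matrix.
#'
#' @return Symmetric integer matrix with H1..H20 dimnames.
#' @export
load_table3_fixture <- function() {
  lines <- readLines(extdata_path("table3_hamming_lower.tsv"))
  labs <- c(strsplit(lines[1L], "\t")[[1L]][-1L], "H20")
  d <- matrix(0L, 20L, 20L, dimnames = list(labs, labs))
  for (ln in lines[-1L]) {
    f <- strsplit(ln, "\t")[[1L]]
    i <- match(f[1L], labs)
    vals <- as.integer(f[-1L])
    d[i, seq_along(vals)] <- d[seq_along(vals), i] <- vals
  }
  attr(d, "metric") <- "hamming"
  d
}

#' Synthetic stand-in for the reference 120-sequence alignment
#'
#' The full 120 x 373 bp reference alignment is not redistributable with
#' the package, but its haplotype census is fully determined by the shipped
#' reference tables. This constructor builds a synthetic alignment that
#' reproduces that census exactly: a fixed monomorphic 373-bp backbone with
#' the 41 reference variable-site columns planted at deterministic,
#' evenly-spread positions, and one record per individual assigned to
#' populations according to the reference haplotype-by-population counts
#' (labels `<Population>_<i>`, `i` = 1..15). Collapsing it yields 20
#' haplotypes with the printed frequencies, 41 polymorphic sites, and the
#' printed Hamming distance matrix. It is synthetic: the backbone bases and
#' the variable-site coordinates are arbitrary, so only haplotype-level
#' quantities (not site coordinates) are meaningful.
#'
#' @param L Total alignment length (default 373).
#' @return A tibble alignment of 120 records of length `L`, plus attribute
#'   `variable_positions` (where the 41 sites were planted).
#' @export
synthetic_reference_alignment <- function(L = 373L) {
  t1 <- load_table1_fixture()
  t2 <- load_table2_fixture()
  m <- nchar(t1$sequence[1L])
  stopifnot(L >= m)
  positions <- round(seq(from = 5L, to = L - 4L, length.out = m))
  backbone <- rep(c("A", "C", "G", "T"), length.out = L)
  full <- vapply(t1$sequence, function(s) {
    x <- backbone
    x[positions] <- strsplit(s, "", fixed = TRUE)[[1L]]
    paste(x, collapse = "")
  }, character(1), USE.NAMES = FALSE)

  pops <- setdiff(names(t2), "haplotype")
  counter <- stats::setNames(integer(length(pops)), pops)
  labels <- character(0)
  seqs <- character(0)
  # haplotype-major order so that first-appearance numbering in
  # collapse_haplotypes() reproduces the reference ids H1..H20
  for (h in seq_len(nrow(t2))) {
    for (p in pops) {
      cnt <- t2[[p]][h]
      if (cnt > 0L) {
        idx <- counter[[p]] + seq_len(cnt)
        counter[[p]] <- counter[[p]] + cnt
        labels <- c(labels, paste0(p, "_", idx))
        seqs <- c(seqs, rep(full[h], cnt))
      }
    }
  }
  al <- new_alignment(labels, seqs)
  attr(al, "variable_positions") <- positions
  al
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "hapflow")
  if (!nzchar(p)) {
    # during in-source loading (pkgload) system.file already handles inst/;
    # this fallback covers direct sourcing in development
    p <- file.path("inst", "extdata", file)
  }
  p
}
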