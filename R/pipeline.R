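#' Run the full haplotype workflow from one aligned FASTA
#'
#' The single-input pipeline: reads an aligned FASTA whose labels encode
#' populations, optionally trims gap-rich ends, collapses haplotypes,
#' writes the haplotype/dot-notation/frequency tables, the Hamming
#' (haplotype-level) and K80 (sequence-level) distance matrices, plain and
#' bootstrapped NJ trees in Newick, the haplotype network link and node
#' lists, all figures, and a JSON manifest recording the configuration,
#' package version and input checksum.
#'
#' @param input Path to the aligned multi-FASTA input.
#' @param output_dir Directory for outputs (created if needed).
#' @param groups Optional population-to-group mapping: named character
#'   vector, two-column data frame, or path to a `population<TAB>group`
#'   TSV.
#' @param bootstrap Number of bootstrap replicates for the haplotype tree
#'   (default 100).
#' @param seed Seed for the bootstrap and network layout.
#' @param trim Optional `max_missing_fraction` for [trim_ends()]; `NULL`
#'   skips trimming.
#' @param level Composition level for the haplotype network.
#' @param alt_threshold Optional alternative-link threshold for
#'   [build_network()].
#' @param figures Write figure files (default `TRUE`).
#' @param figure_format `"png"` or `"svg"`.
#' @return Invisibly, a named list of all output paths.
#' @export
run_all <- function(input, output_dir, groups = NULL, bootstrap = 100L,
                    seed = 1L, trim = NULL,
                    level = c("population", "individual", "group"),
                    alt_threshold = NULL, figures = TRUE,
                    figure_format = c("png", "svg")) {
  level <- match.arg(level)
  figure_format <- match.arg(figure_format)
  t0 <- Sys.time()
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  out <- function(f) file.path(output_dir, f)
  paths <- list()
  stage <- "read"
  withCallingHandlers({
    al <- read_fasta(input)
    if (!is.null(trim)) al <- trim_ends(al, trim)
    if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
      groups <- read_group_tsv(groups)
    }
    pm <- build_population_map(al, groups = groups)

    stage <- "haplotypes"
    hs <- collapse_haplotypes(al)
    vst <- variable_sites(hs)
    dots <- dot_notation(vst)
    hap_tab <- tibble::tibble(
      haplotype = hs$haplotype, hf = hs$hf, pct = hs$pct,
      sites = vst$sites,
      members = vapply(hs$members, paste, character(1), collapse = ",")
    )
    utils::write.table(hap_tab, paths$haplotypes <- out("haplotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dot_tab <- dplyr::left_join(dots, hap_tab[, c("haplotype", "hf", "pct")],
                                by = "haplotype")
    utils::write.table(dot_tab, paths$dot <- out("haplotypes_dot.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pmx <- population_matrix(hs, pm, level = "population")
    utils::write.table(pmx, paths$pop_matrix <- out("haplotype_by_population.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if ("group" %in% names(pm)) {
      gmx <- population_matrix(hs, pm, level = "group")
      utils::write.table(gmx, paths$group_matrix <- out("haplotype_by_group.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "distances"
    dh <- hamming_matrix(vst)
    write_distance_tsv(dh, paths$hamming <- out("hamming_lower.tsv"),
                       format = "lower")
    dk <- k80_matrix(al)
    write_distance_tsv(dk, paths$k80 <- out("k80_square.tsv"),
                       format = "square")

    stage <- "trees"
    seq_tree <- nj_tree(dk)
    write_newick(seq_tree, path = paths$seq_tree <- out("nj_sequences_k80.nwk"))
    hap_boot <- bootstrap_support(
      tibble::tibble(label = vst$haplotype, sequence = vst$sites),
      B = bootstrap, seed = seed, model = "hamming")
    write_newick(hap_boot,
                 path = paths$hap_tree <- out("nj_haplotypes_bootstrap.nwk"))
    st <- support_table(hap_boot)
    st$tips <- vapply(st$tips, paste, character(1), collapse = ",")
    utils::write.table(st, paths$supports <- out("bootstrap_supports.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "network"
    net <- build_network(dh, hs, pm, level = level,
                         alt_threshold = alt_threshold)
    write_network(net, edge_path = paths$net_edges <- out("network_links.tsv"),
                  node_path = paths$net_nodes <- out("network_nodes.tsv"),
                  json_path = paths$net_json <- out("network.json"))

    if (figures) {
      stage <- "figures"
      fig <- function(name) out(paste0(name, ".", figure_format))
      paths$fig_msa <- save_plot(plot_msa_tree(seq_tree, al), fig("fig_msa_tree"),
                                 width = 10, height = 10)
      paths$fig_heatmap <- save_plot(plot_heatmap(dh), fig("fig_heatmap"))
      paths$fig_network <- save_plot(plot_network(net, seed = seed),
                                     fig("fig_network"))
      paths$fig_tree_pop <- save_plot(
        plot_tree(seq_tree, mode = "population", layout = "circular", pm = pm),
        fig("fig_tree_population"))
      paths$fig_tree_bl <- save_plot(
        plot_tree(seq_tree, mode = "branchlength", layout = "circular"),
        fig("fig_tree_branchlength"))
      paths$fig_tree_boot <- save_plot(
        plot_tree(hap_boot, mode = "support"), fig("fig_tree_bootstrap"))
    }

    stage <- "manifest"
    manifest <- list(
      package = "hapflow",
      version = as.character(utils::packageVersion("hapflow")),
      created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      input = normalizePath(input),
      input_md5 = unname(tools::md5sum(input)),
      config = list(bootstrap = bootstrap, seed = seed, trim = trim,
                    level = level, alt_threshold = alt_threshold,
                    figures = figures, figure_format = figure_format),
      n_sequences = nrow(al), alignment_length = alignment_length(al),
      n_haplotypes = nrow(hs),
      outputs = lapply(paths, basename)
    )
    jsonlite::write_json(manifest, paths$manifest <- out("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }, error = function(e) {
    message("pipeline failed during stage '", stage, "': ",
            conditionMessage(e))
  })
  invisible(paths)
}
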