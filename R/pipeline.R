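#' Run the full downstream analysis and write its outputs
#'
#' One call covering the whole workflow on a single community: lineage
#' exclusion, rarefaction to even depth, alpha diversity, six-way abundance
#' classification with its contribution summary, prevalence-filtered Spearman
#' co-occurrence network with modules, Zi-Pi roles and keystones, and -- when
#' metadata is supplied -- TSI plus the diversity/taxa/keystone environmental
#' screens and indicator calls. All randomness (rarefaction, module
#' detection) derives from `seed`, so a fixed seed yields byte-identical
#' output files.
#'
#' Files written to `out_dir`: `rarefied.tsv`, `alpha.tsv`, `categories.tsv`,
#' `partition_summary.tsv`, `network/` (see [export_network()]),
#' `network_summary.json`, and with metadata `tsi.tsv`, `screen_*.tsv`,
#' `indicators.tsv`.
#'
#' @param table an [asv_table()] of raw counts.
#' @param tax taxonomy `data.frame`.
#' @param meta optional metadata `data.frame`.
#' @param out_dir output directory (created).
#' @param seed integer seed.
#' @param depth rarefaction depth or `"auto"` (minimum sample total).
#' @param exclude lineage keywords for [exclude_lineages()].
#' @param prevalence,r_thresh,p_thresh network thresholds.
#' @param rank rank for the taxa-environment screen.
#' @param tsi_method passed to [trophic_state_index()].
#' @return invisibly, a list with all intermediate objects (`rarefied`,
#'   `alpha`, `assignment`, `partition`, `net`, `summary`, `keystones`,
#'   `keystone_groups`, and the screen tables when metadata is given).
#' @export
run_pipeline <- function(table, tax, meta = NULL, out_dir, seed,
                         depth = "auto",
                         exclude = c("chloroplast", "mitochondria", "unknown"),
                         prevalence = 0.5, r_thresh = 0.6, p_thresh = 0.05,
                         rank = "genus", tsi_method = "tli_composite") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  filtered <- exclude_lineages(table, tax, exclude)
  if (!nrow(filtered)) abort("no ASVs left after lineage exclusion")
  rarefied <- rarefy_table(filtered, depth = depth, seed = seed)
  write_asv_table(rarefied, file.path(out_dir, "rarefied.tsv"))

  alpha <- alpha_diversity(rarefied)
  tsv(alpha, "alpha.tsv")

  props <- relative_abundance(rarefied)
  assignment <- classify_asvs(props)
  tsv(as.data.frame(assignment), "categories.tsv")
  partition <- summarize_partition(assignment, props)
  tsv(partition, "partition_summary.tsv")

  net_table <- prevalence_filter(rarefied, prevalence)
  res <- list(rarefied = rarefied, alpha = alpha, assignment = assignment,
              partition = partition)
  if (nrow(net_table) >= 2L) {
    corr <- spearman_all_pairs(relative_abundance(net_table))
    net <- build_network(corr, r_thresh, p_thresh)
    if (nrow(net$edges)) {
      net <- annotate_network(net, seed = seed)
      export_network(net, file.path(out_dir, "network"), tax = tax,
                     assignment = assignment)
      summ <- network_summary(net, tax)
      jsonlite::write_json(summ, file.path(out_dir, "network_summary.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      keystones <- keystone_set(net$nodes)
      res$net <- net
      res$summary <- summ
      res$keystones <- keystones
      res$keystone_groups <- category_of_keystones(assignment, keystones)
    }
  }

  if (!is.null(meta)) {
    common <- match_samples(rarefied, meta)
    meta <- meta[match(common, meta$sample_id), , drop = FALSE]
    tsi <- trophic_state_index(meta, tsi_method)
    tsv(tsi, "tsi.tsv")
    scr_div <- diversity_env_screen(alpha, meta)
    tsv(scr_div, "screen_diversity.tsv")
    rank_tab <- aggregate_rank(rarefied, tax, rank)
    scr_taxa <- taxa_env_screen(rank_tab, meta, tsi)
    tsv(scr_taxa, "screen_taxa.tsv")
    res$tsi <- tsi
    res$screen_diversity <- scr_div
    res$screen_taxa <- scr_taxa
    res$indicators <- indicator_call(scr_taxa)
    tsv(res$indicators, "indicators.tsv")
    if (!is.null(res$keystones) && length(res$keystones)) {
      scr_ks <- keystone_env_screen(props, res$keystones, meta, tsi)
      tsv(scr_ks, "screen_keystones.tsv")
      res$screen_keystones <- scr_ks
    }
  }
  invisible(res)
}
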