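#' Remove ASVs with unwanted lineages
#'
#' Drops ASVs whose lineage contains any of the given keywords
#' (case-insensitive substring match on any rank), plus -- when the keyword
#' `"unknown"` is supplied -- ASVs unassigned at the domain rank or absent from
#' the taxonomy altogether. This reproduces the standard amplicon cleanup of
#' discarding chloroplast, mitochondrial and domain-unassigned reads before
#' analysis.
#'
#' @param table an [asv_table()].
#' @param tax taxonomy `data.frame` (see [read_taxonomy()]).
#' @param terms character vector of lineage keywords; default
#'   `c("chloroplast", "mitochondria", "unknown")`.
#' @return the filtered [asv_table()], ASV order preserved.
#' @export
exclude_lineages <- function(table, tax,
                             terms = c("chloroplast", "mitochondria", "unknown")) {
  stopifnot(is_asv_table(table))
  if (!length(terms)) abort("`terms` must be non-empty")
  terms <- tolower(terms)
  drop_unknown <- "unknown" %in% terms
  kw <- setdiff(terms, "unknown")

  idx <- match(rownames(table), tax$asv_id)
  lin <- as.matrix(tax[tax_ranks()])
  drop <- logical(nrow(table))
  for (i in seq_len(nrow(table))) {
    j <- idx[i]
    if (is.na(j)) { drop[i] <- drop_unknown; next }
    ranks <- tolower(lin[j, ])
    hit <- length(kw) && any(vapply(kw, function(t)
      any(grepl(t, ranks, fixed = TRUE), na.rm = TRUE), logical(1)))
    if (drop_unknown && is.na(lin[j, 1L])) hit <- TRUE
    drop[i] <- isTRUE(hit)
  }
  asv_table(unclass(table)[!drop, , drop = FALSE])
}

#' Rarefy an ASV table to even depth
#'
#' Subsamples each sample's reads without replacement (a multivariate
#' hypergeometric draw per sample) so that every column sums exactly to
#' `depth`. Deterministic given `seed`; the depth and seed are recorded in the
#' result's `rarefaction` attribute.
#'
#' @param table an [asv_table()].
#' @param depth target depth, a positive integer no larger than the smallest
#'   sample total; `"auto"` uses the smallest sample total (the usual
#'   rarefy-to-minimum convention).
#' @param seed integer seed (required).
#' @return a rarefied [asv_table()] with all-zero ASVs retained.
#' @examples
#' m <- matrix(rpois(40, 20), 10, 4,
#'             dimnames = list(paste0("ASV", 1:10), paste0("S", 1:4)))
#' r <- rarefy_table(asv_table(m), depth = 30, seed = 1)
#' colSums(r)
#' @export
rarefy_table <- function(table, depth = "auto", seed) {
  stopifnot(is_asv_table(table))
  if (missing(seed)) abort("`seed` is required for rarefaction")
  totals <- colSums(table)
  if (identical(depth, "auto")) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth <= 0L) abort("`depth` must be positive")
  low <- which(totals < depth)
  if (length(low))
    abort("depth %d exceeds the total of sample '%s' (%d)",
          depth, colnames(table)[low[1L]], totals[low[1L]])
  out <- with_seed(seed, {
    apply(unclass(table), 2L, function(x) {
      if (sum(x) == depth) return(x)
      pool <- rep.int(seq_along(x), x)
      take <- pool[sample.int(length(pool), depth)]
      tabulate(take, nbins = length(x))
    })
  })
  rownames(out) <- rownames(table)
  res <- asv_table(out)
  attr(res, "rarefaction") <- list(depth = depth, seed = as.integer(seed))
  res
}

#' Per-sample relative abundances
#'
#' @param table an [asv_table()].
#' @return numeric matrix of proportions (same dimnames); every column sums
#'   to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(is_asv_table(table))
  totals <- colSums(table)
  zero <- which(totals == 0)
  if (length(zero))
    abort("sample '%s' has zero total reads", colnames(table)[zero[1L]])
  sweep(unclass(table), 2L, totals, "/")
}

#' Aggregate relative abundances at a taxonomic rank
#'
#' Sums the proportions of ASVs sharing the same label at the requested rank;
#' ASVs unassigned at that rank (or missing from the taxonomy) pool into an
#' `"unassigned"` row. Column sums are preserved.
#'
#' @param table an [asv_table()] (proportions are computed internally) or a
#'   proportion matrix with ASV rownames.
#' @param tax taxonomy `data.frame`.
#' @param rank one of [tax_ranks()].
#' @return taxon x sample proportion matrix, rows ordered by decreasing mean
#'   abundance with `"unassigned"` last.
#' @export
aggregate_rank <- function(table, tax, rank) {
  if (!rank %in% tax_ranks()) abort("unknown rank '%s'", rank)
  props <- if (is_asv_table(table)) relative_abundance(table) else as.matrix(table)
  labels <- tax[[rank]][match(rownames(props), tax$asv_id)]
  labels[is.na(labels)] <- "unassigned"
  out <- rowsum(props, group = labels)
  ord <- order(rowMeans(out), decreasing = TRUE)
  out <- out[ord, , drop = FALSE]
  if ("unassigned" %in% rownames(out)) {
    i <- which(rownames(out) == "unassigned")
    out <- out[c(setdiff(seq_len(nrow(out)), i), i), , drop = FALSE]
  }
  out
}

#' Split an ASV table into abundant/rare/moderate sub-communities
#'
#' Partitions the table by the coarse group of a [classify_asvs()] assignment.
#' The three outputs keep original counts and together contain every input
#' ASV; they are the sub-community tables consumed by downstream functional
#' prediction tools.
#'
#' @param table an [asv_table()].
#' @param assignment a `category_assignment` from [classify_asvs()].
#' @return named list of [asv_table()]s: `abundant`, `rare`, `moderate`
#'   (possibly zero-row).
#' @export
split_subcommunities <- function(table, assignment) {
  stopifnot(is_asv_table(table))
  grp <- assignment$group[match(rownames(table), assignment$asv_id)]
  if (anyNA(grp))
    abort("ASV '%s' missing from assignment",
          rownames(table)[which(is.na(grp))[1L]])
  pick <- function(g) {
    m <- unclass(table)[grp == g, , drop = FALSE]
    structure(m, class = c("asv_table", "matrix", "array"))
  }
  list(abundant = pick("abundant"), rare = pick("rare"),
       moderate = pick("moderate"))
}
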