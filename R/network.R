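#' Prevalence filter for network analysis
#'
#' Keeps ASVs detected (count > 0) in strictly more than `min_fraction` of the
#' samples. With the default 0.5, an ASV present in exactly half of the
#' samples is removed; this is the usual pre-filter that keeps co-occurrence
#' networks to taxa observed across most of the data set.
#'
#' @param table an [asv_table()].
#' @param min_fraction fraction of samples in `[0, 1)`, default 0.5.
#' @return the filtered [asv_table()].
#' @export
prevalence_filter <- function(table, min_fraction = 0.5) {
  stopifnot(is_asv_table(table))
  if (min_fraction < 0 || min_fraction >= 1)
    abort("`min_fraction` must be in [0, 1)")
  prev <- rowSums(unclass(table) > 0L)
  keep <- prev > min_fraction * ncol(table)
  asv_table(unclass(table)[keep, , drop = FALSE])
}

# Spearman rho/p for the columns of a samples x features matrix.
# Shared engine for the all-pairs correlation and the environmental screens:
# average-rank ties, t-approximation p-values, |rho| = 1 => p = 0, constant
# columns => NA. Returns list(rho, p) of square matrices.
spearman_engine <- function(X, Y = NULL) {
  n <- nrow(X)
  rank_cols <- function(M) apply(M, 2L, rank)  # average ranks on ties
  RX <- rank_cols(X)
  sx <- apply(RX, 2L, stats::sd)
  if (is.null(Y)) {
    rho <- suppressWarnings(stats::cor(RX))
    rho[sx == 0, ] <- NA_real_
    rho[, sx == 0] <- NA_real_
    diag(rho) <- ifelse(sx == 0, NA_real_, 1)
  } else {
    RY <- rank_cols(Y)
    sy <- apply(RY, 2L, stats::sd)
    rho <- suppressWarnings(stats::cor(RX, RY))
    rho[sx == 0, ] <- NA_real_
    rho[, sy == 0] <- NA_real_
  }
  rho <- pmin(pmax(rho, -1), 1)
  p <- spearman_pvalue(rho, n)
  list(rho = rho, p = p)
}

# two-sided p from the t approximation t = rho * sqrt((n-2)/(1-rho^2))
spearman_pvalue <- function(rho, n) {
  p <- array(NA_real_, dim = dim(rho), dimnames = dimnames(rho))
  ok <- !is.na(rho)
  r <- rho[ok]
  exact1 <- abs(r) >= 1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * stats::pt(-abs(tt), df = n - 2)
  pv[exact1] <- 0
  p[ok] <- pmin(pv, 1)
  p
}

#' All-pairs Spearman correlation with significance
#'
#' Computes the Spearman rank correlation and its two-sided p-value for every
#' pair of ASVs across samples. Ranks use average-rank tie handling; p-values
#' come from the t-distribution approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom, with
#' \eqn{|\rho| = 1} mapped to \eqn{p = 0}. ASVs constant across samples have
#' undefined correlations; their entries are `NA` (they can never form edges)
#' and their count is reported in a message.
#'
#' @param props proportion (or count) matrix, ASV x sample, with at least 4
#'   samples.
#' @return a `cooc_cor` object: list with symmetric matrices `rho` and `p`,
#'   sample size `n_samples`, and `ids`.
#' @export
spearman_all_pairs <- function(props) {
  props <- as.matrix(props)
  if (ncol(props) < 4L) abort("need at least 4 samples, got %d", ncol(props))
  res <- spearman_engine(t(props))
  n_const <- sum(is.na(diag(res$rho)))
  if (n_const > 0)
    message(sprintf("%d constant ASV(s): correlations undefined, recorded as no-edge", n_const))
  diag(res$p)[!is.na(diag(res$rho))] <- 0
  structure(list(rho = res$rho, p = res$p, n_samples = ncol(props),
                 ids = rownames(props)),
            class = "cooc_cor")
}

#' Build a signed co-occurrence network from thresholded correlations
#'
#' Draws an edge between ASVs i and j exactly when `|rho| > r_thresh` and
#' `p < p_thresh` (both strict, so `rho = 0.6` exactly is not an edge). Edge
#' sign follows the sign of rho. ASVs with no qualifying edge are dropped:
#' the network contains connected nodes only.
#'
#' @param corr a `cooc_cor` from [spearman_all_pairs()], or any list with
#'   symmetric `rho`/`p` matrices and `ids`.
#' @param r_thresh correlation magnitude threshold, default 0.6.
#' @param p_thresh significance threshold, default 0.05.
#' @return a `cooc_network`: list with `edges` (`from`, `to`, `rho`, `p`,
#'   `sign`) and `nodes` (`asv_id`, `degree`) data frames.
#' @export
build_network <- function(corr, r_thresh = 0.6, p_thresh = 0.05) {
  if (r_thresh <= 0 || r_thresh >= 1 || p_thresh <= 0 || p_thresh >= 1)
    abort("thresholds must lie in (0, 1)")
  rho <- as.matrix(corr$rho)
  p <- as.matrix(corr$p)
  ids <- if (!is.null(corr$ids)) corr$ids else rownames(rho)
  keep <- upper.tri(rho) & !is.na(rho) & abs(rho) > r_thresh & !is.na(p) & p < p_thresh
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
                      rho = rho[keep], p = p[keep],
                      sign = ifelse(rho[keep] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  cooc_network(edges)
}

#' Construct a co-occurrence network from an edge list
#'
#' Low-level constructor used by [build_network()] and by the synthetic graph
#' generators. Self-loops and duplicate unordered pairs are rejected; nodes
#' are the endpoints of the edges (isolated nodes cannot be represented).
#'
#' @param edges `data.frame` with character columns `from`, `to` and
#'   optionally `rho`, `p`, `sign`.
#' @return a `cooc_network` object.
#' @export
cooc_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(edges)))
    abort("`edges` needs `from` and `to` columns")
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) abort("self-loops are not allowed")
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) abort("duplicate edges")
  }
  if (is.null(edges$rho)) edges$rho <- rep(NA_real_, nrow(edges))
  if (is.null(edges$p)) edges$p <- rep(NA_real_, nrow(edges))
  if (is.null(edges$sign))
    edges$sign <- ifelse(is.na(edges$rho) | edges$rho > 0, "positive", "negative")
  ids <- sort(unique(c(edges$from, edges$to)))
  deg <- table(factor(c(edges$from, edges$to), levels = ids))
  nodes <- data.frame(asv_id = ids, degree = as.integer(deg),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  pos <- if (nrow(x$edges)) mean(x$edges$sign == "positive") * 100 else NA
  cat(sprintf("co-occurrence network: %d nodes, %d edges (%.1f%% positive)\n",
              nrow(x$nodes), nrow(x$edges), pos))
  invisible(x)
}

#' Convert a co-occurrence network to an igraph graph
#' @param net a `cooc_network`.
#' @return an undirected [igraph::igraph] object.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[c("from", "to", "rho", "p", "sign")],
                                directed = FALSE,
                                vertices = net$nodes["asv_id"])
}

#' Detect network modules by modularity maximization
#'
#' Runs Louvain greedy modularity maximization on the undirected, unweighted,
#' unsigned edge set. Deterministic given `seed`. Modules are relabelled
#' 1, 2, ... by decreasing size (ties broken by smallest member id) so module
#' labels are stable descriptors.
#'
#' @param net a `cooc_network` with at least one edge.
#' @param seed integer seed (required; the heuristic is order-sensitive).
#' @param resolution Louvain resolution parameter, default 1.
#' @return named integer vector mapping node id to module label.
#' @export
detect_modules <- function(net, seed, resolution = 1) {
  if (missing(seed)) abort("`seed` is required for module detection")
  if (!nrow(net$edges)) abort("cannot detect modules in an empty network")
  g <- as_igraph(net)
  memb <- with_seed(seed, igraph::membership(
    igraph::cluster_louvain(g, weights = NA, resolution = resolution)))
  m <- as.integer(memb)
  names(m) <- names(memb)
  relabel_by_size(m)
}

# relabel module ids 1..M by decreasing size; ties by smallest member name
relabel_by_size <- function(m) {
  sizes <- table(m)
  first <- vapply(names(sizes), function(lv) min(names(m)[m == as.integer(lv)]), character(1))
  ord <- order(-as.integer(sizes), first)
  new <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- new[as.character(m)]
  stats::setNames(as.integer(out), names(m))
}

#' Within- and among-module connectivity (Zi, Pi)
#'
#' For every node i with degree \eqn{k_i} and \eqn{k_{is}} links into module
#' s: Zi is the z-score of the node's within-own-module degree among the
#' members of its module, \eqn{Z_i = (k_{is} - \bar{k}_s)/\sigma_{k_s}}
#' (0 when the module is a singleton or has zero spread), and Pi is the
#' participation coefficient \eqn{P_i = 1 - \sum_s (k_{is}/k_i)^2}.
#'
#' @param net a `cooc_network`.
#' @param modules named integer vector from [detect_modules()] covering every
#'   node.
#' @return `data.frame` with columns `asv_id`, `module`, `degree`, `zi`, `pi`.
#' @export
zi_pi <- function(net, modules) {
  ids <- net$nodes$asv_id
  if (!all(ids %in% names(modules))) abort("every node needs a module")
  mod <- modules[ids]
  mods <- sort(unique(as.integer(mod)))
  k_is <- matrix(0L, nrow = length(ids), ncol = length(mods),
                 dimnames = list(ids, as.character(mods)))
  ei <- match(net$edges$from, ids)
  ej <- match(net$edges$to, ids)
  for (e in seq_len(nrow(net$edges))) {
    k_is[ei[e], as.character(mod[ej[e]])] <- k_is[ei[e], as.character(mod[ej[e]])] + 1L
    k_is[ej[e], as.character(mod[ei[e]])] <- k_is[ej[e], as.character(mod[ei[e]])] + 1L
  }
  k <- rowSums(k_is)
  own <- k_is[cbind(seq_along(ids), match(as.character(mod), colnames(k_is)))]
  zi <- numeric(length(ids))
  for (s in mods) {
    members <- which(as.integer(mod) == s)
    ks <- own[members]
    sdev <- if (length(ks) > 1L) stats::sd(ks) else 0
    zi[members] <- if (sdev > 0) (ks - mean(ks)) / sdev else 0
  }
  pi_ <- 1 - rowSums((k_is / k)^2)
  data.frame(asv_id = ids, module = as.integer(mod), degree = as.integer(k),
             zi = zi, pi = pi_, stringsAsFactors = FALSE, row.names = NULL)
}

#' Topological role classification from Zi and Pi
#'
#' Nodes split into the four classic roles: network hubs (`zi > zi_thresh`
#' and `pi > pi_thresh`), module hubs (`zi > zi_thresh`, `pi <= pi_thresh`),
#' connectors (`zi <= zi_thresh`, `pi > pi_thresh`) and peripherals
#' (everything else). Boundary values fall on the peripheral side.
#'
#' @param zipi `data.frame` from [zi_pi()].
#' @param zi_thresh within-module connectivity cutoff, default 2.5.
#' @param pi_thresh among-module connectivity cutoff, default 0.62.
#' @return the input with a `role` factor column added.
#' @export
classify_roles <- function(zipi, zi_thresh = 2.5, pi_thresh = 0.62) {
  if (zi_thresh <= 0 || pi_thresh <= 0) abort("thresholds must be positive")
  hi_z <- zipi$zi > zi_thresh
  hi_p <- zipi$pi > pi_thresh
  role <- ifelse(hi_z & hi_p, "network hub",
          ifelse(hi_z, "module hub",
          ifelse(hi_p, "connector", "peripheral")))
  zipi$role <- factor(role, levels = c("peripheral", "module hub",
                                       "connector", "network hub"))
  zipi
}

#' Keystone taxa of a network
#'
#' Keystones are all non-peripheral nodes: network hubs, module hubs and
#' connectors.
#'
#' @param roles `data.frame` from [classify_roles()].
#' @return character vector of keystone ASV ids (possibly empty).
#' @export
keystone_set <- function(roles) {
  roles$asv_id[roles$role != "peripheral"]
}

#' Annotate a network with modules, connectivity and roles
#'
#' Convenience wrapper running [detect_modules()], [zi_pi()] and
#' [classify_roles()] and merging the results into the node table.
#'
#' @param net a `cooc_network`.
#' @param seed integer seed for module detection.
#' @param resolution,zi_thresh,pi_thresh passed through.
#' @return the network with `module`, `zi`, `pi`, `role` columns on `$nodes`.
#' @export
annotate_network <- function(net, seed, resolution = 1,
                             zi_thresh = 2.5, pi_thresh = 0.62) {
  modules <- detect_modules(net, seed = seed, resolution = resolution)
  roles <- classify_roles(zi_pi(net, modules), zi_thresh, pi_thresh)
  net$nodes <- merge(net$nodes[c("asv_id", "degree")], roles,
                     by = c("asv_id", "degree"), sort = FALSE)
  net$nodes <- net$nodes[order(net$nodes$asv_id), , drop = FALSE]
  rownames(net$nodes) <- NULL
  net
}

#' Summary statistics of an annotated network
#'
#' @param net an [annotate_network()]-annotated `cooc_network`.
#' @param tax optional taxonomy `data.frame` for per-phylum node composition.
#' @return list with `n_nodes`, `n_edges`, `pct_positive`, `pct_negative`,
#'   `n_modules`, `module_fractions_pct` (named, by module label),
#'   `n_keystones`, `roles` (named counts) and, when `tax` is given,
#'   `phylum_pct`.
#' @export
network_summary <- function(net, tax = NULL) {
  if (is.null(net$nodes$module))
    abort("network must be annotated first (see annotate_network)")
  ne <- nrow(net$edges)
  pos <- if (ne) mean(net$edges$sign == "positive") * 100 else NA_real_
  modtab <- table(net$nodes$module)
  out <- list(
    n_nodes = nrow(net$nodes),
    n_edges = ne,
    pct_positive = pos,
    pct_negative = if (ne) 100 - pos else NA_real_,
    n_modules = length(modtab),
    module_fractions_pct = stats::setNames(
      as.numeric(modtab) / nrow(net$nodes) * 100, names(modtab)),
    n_keystones = sum(net$nodes$role != "peripheral"),
    roles = vapply(split(net$nodes$role, net$nodes$role), length, integer(1))
  )
  if (!is.null(tax)) {
    phy <- tax$phylum[match(net$nodes$asv_id, tax$asv_id)]
    phy[is.na(phy)] <- "unassigned"
    tab <- sort(table(phy), decreasing = TRUE)
    out$phylum_pct <- stats::setNames(as.numeric(tab) / nrow(net$nodes) * 100,
                                      names(tab))
  }
  out
}

#' Export network tables and GraphML
#'
#' Writes `edges.tsv` (source, target, rho, p, sign), `nodes.tsv` (id,
#' degree, module, zi, pi, role, plus taxonomy lineage and abundance group
#' when available) and `network.graphml` for import into Gephi or Cytoscape.
#'
#' @param net an annotated `cooc_network`.
#' @param dir output directory (created if needed).
#' @param tax optional taxonomy `data.frame`.
#' @param assignment optional `category_assignment` for the abundance group
#'   column.
#' @return `dir`, invisibly.
#' @export
export_network <- function(net, dir, tax = NULL, assignment = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges <- net$edges
  names(edges)[1:2] <- c("source", "target")
  utils::write.table(format(edges, digits = 15, trim = TRUE),
                     file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- net$nodes
  if (!is.null(tax)) {
    i <- match(nodes$asv_id, tax$asv_id)
    nodes$phylum <- tax$phylum[i]
    nodes$genus <- tax$genus[i]
  }
  if (!is.null(assignment))
    nodes$group <- assignment$group[match(nodes$asv_id, assignment$asv_id)]
  utils::write.table(format(nodes, digits = 15, trim = TRUE),
                     file.path(dir, "nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  g <- as_igraph(net)
  if (!is.null(net$nodes$module)) {
    igraph::V(g)$module <- net$nodes$module[match(igraph::V(g)$name, net$nodes$asv_id)]
    igraph::V(g)$role <- as.character(
      net$nodes$role[match(igraph::V(g)$name, net$nodes$asv_id)])
  }
  igraph::write_graph(g, file.path(dir, "network.graphml"), format = "graphml")
  invisible(dir)
}
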