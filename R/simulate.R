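#' Configuration for the synthetic community generator
#'
#' Bundles and validates the parameters of [simulate_community()],
#' [simulate_metadata()] and [planted_network()]. Defaults describe a
#' desk-scale littoral-sediment-like study: 34 samples, 5,000 taxa whose
#' log-baselines follow a heavy-tailed lognormal species abundance
#' distribution (sdlog = 2, giving many rare and few abundant taxa), 50,000
#' reads per sample, four correlation modules of 30 taxa driven by shared
#' latent sample factors, a handful of taxa with margins forcing each
#' abundance category, and nutrient variables on realistic mesotrophic ranges
#' (TN 0.526--0.677 mg/L, TP 0.024--0.037 mg/L) with planted monotone links
#' to module factors.
#'
#' @param n_samples number of samples.
#' @param n_taxa total number of taxa.
#' @param depth sequencing depth per sample (multinomial total).
#' @param sad_meanlog,sad_sdlog lognormal species-abundance parameters for
#'   the log baseline intensities.
#' @param n_modules,taxa_per_module correlation-module structure.
#' @param loading latent-factor loading of module taxa (log scale).
#' @param noise_sd sd of per-taxon log-normal noise.
#' @param forced named integer vector: how many taxa to plant per abundance
#'   category (names among AAT, CAT, CRAT, MT, CRT, ART) with generating
#'   margins that force the category at the configured depth.
#' @param env_links `data.frame` with columns `variable`, `module`, `sign`:
#'   environmental variables generated as monotone transforms of a module's
#'   latent factor.
#' @param env_noise_sd sd of the noise added to linked variables before the
#'   monotone rescaling.
#' @param overdispersion optional Dirichlet overdispersion parameter; `NULL`
#'   (default) draws plain multinomial counts, a positive value `a` draws
#'   sample proportions from Dirichlet(a * p) first.
#' @param seed integer seed (required; all generators are deterministic
#'   given it).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 34L,
                       n_taxa = 5000L,
                       depth = 50000L,
                       sad_meanlog = 0, sad_sdlog = 2,
                       n_modules = 4L, taxa_per_module = 30L,
                       loading = 1, noise_sd = 0.3,
                       forced = c(AAT = 2L, CAT = 3L, CRAT = 3L, MT = 2L,
                                  CRT = 5L, ART = 20L),
                       env_links = data.frame(
                         variable = c("TN", "TP", "Chla", "PI"),
                         module = c(1L, 2L, 1L, 3L),
                         sign = c(1, 1, 1, -1)),
                       env_noise_sd = 0.3,
                       overdispersion = NULL,
                       seed) {
  if (missing(seed)) abort("`seed` is required")
  cfg <- list(n_samples = as.integer(n_samples), n_taxa = as.integer(n_taxa),
              depth = as.integer(depth), sad_meanlog = sad_meanlog,
              sad_sdlog = sad_sdlog, n_modules = as.integer(n_modules),
              taxa_per_module = as.integer(taxa_per_module), loading = loading,
              noise_sd = noise_sd, forced = forced, env_links = env_links,
              env_noise_sd = env_noise_sd, overdispersion = overdispersion,
              seed = as.integer(seed))
  if (cfg$n_samples < 2L || cfg$n_taxa < 1L || cfg$depth < 1L)
    abort("n_samples, n_taxa and depth must be positive")
  if (!all(names(cfg$forced) %in% category_levels()))
    abort("unknown forced category: %s",
          paste(setdiff(names(cfg$forced), category_levels()), collapse = ", "))
  if (cfg$n_modules * cfg$taxa_per_module + sum(cfg$forced) > cfg$n_taxa)
    abort("module taxa (%d) plus forced taxa (%d) exceed n_taxa (%d)",
          cfg$n_modules * cfg$taxa_per_module, sum(cfg$forced), cfg$n_taxa)
  if (!all(cfg$env_links$module %in% seq_len(cfg$n_modules)))
    abort("env link targets an unknown module")
  if (!is.finite(cfg$loading) || !is.finite(cfg$noise_sd))
    abort("loading and noise_sd must be finite")
  class(cfg) <- "sim_config"
  cfg
}

# mock lineages drawn from the dominant sediment phyla, so taxonomy-dependent
# code paths (rank aggregation, per-phylum summaries) see realistic labels
mock_lineage_pool <- function() {
  data.frame(
    domain = c(rep("Bacteria", 8), rep("Archaea", 2)),
    phylum = c("Proteobacteria", "Bacteroidetes", "Chloroflexi",
               "Acidobacteria", "Planctomycetes", "Verrucomicrobia",
               "Nitrospirae", "Firmicutes", "Euryarchaeota", "Nanoarchaeaeota"),
    genus = c("Dechloromonas", "Flavobacterium", "Anaerolinea",
              "Holophaga", "Pirellula", "Luteolibacter",
              "Nitrospira", "Clostridium", "Methanosaeta", "Woesearchaeia"),
    stringsAsFactors = FALSE)
}

# per-sample expected proportions that force each category with wide margins
# at depths of a few tens of thousands of reads
forced_profile <- function(category, n_samples, some) {
  base <- switch(category,
    AAT = rep(0.02, n_samples),
    CAT = ifelse(some, 0.02, 0.002),
    CRAT = ifelse(some, 0.02, 2e-6),
    MT = rep(0.002, n_samples),
    CRT = ifelse(some, 0.002, 2e-6),
    ART = rep(2e-6, n_samples))
  base
}

#' Simulate an ASV table with planted structure
#'
#' Generates per-sample taxon intensities
#' \eqn{\exp(b_t + \lambda f_{m(t)}(s) + \epsilon_{ts})} -- lognormal
#' baseline \eqn{b_t}, shared latent factor \eqn{f_m} for taxa of module m,
#' independent Gaussian noise -- normalises them to proportions and draws
#' counts multinomially at the configured depth. A configured number of taxa
#' per abundance category are instead given fixed per-sample expected
#' proportions whose margins force the category, providing planted truth for
#' classification tests. Taxonomy strings come from a small fixed pool of
#' dominant sediment lineages.
#'
#' @param config a [sim_config()].
#' @return list with `table` (an [asv_table()]), `tax` (taxonomy
#'   `data.frame`), `truth` (`data.frame`: `asv_id`, `category`, `module`;
#'   `NA` where no label is forced), and `factors` (samples x modules latent
#'   factor matrix, input to [simulate_metadata()]).
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ns <- config$n_samples; nt <- config$n_taxa
    sample_ids <- sprintf("S%02d", seq_len(ns))
    asv_ids <- sprintf("ASV_%05d", seq_len(nt))

    n_forced <- sum(config$forced)
    n_module_taxa <- config$n_modules * config$taxa_per_module
    forced_idx <- seq_len(n_forced)
    module_idx <- n_forced + seq_len(n_module_taxa)
    free_idx <- setdiff(seq_len(nt), c(forced_idx, module_idx))

    truth_cat <- rep(NA_character_, nt)
    truth_mod <- rep(NA_integer_, nt)

    # forced-category taxa: fixed expected proportions
    exp_forced <- matrix(0, nrow = n_forced, ncol = ns)
    i <- 0L
    for (cat in names(config$forced)) {
      for (r in seq_len(config$forced[[cat]])) {
        i <- i + 1L
        some <- seq_len(ns) %in% sample.int(ns, max(1L, ns %/% 4L))
        exp_forced[i, ] <- forced_profile(cat, ns, some)
        truth_cat[forced_idx[i]] <- cat
      }
    }

    # latent factors and intensities for module + free taxa
    factors <- matrix(stats::rnorm(ns * config$n_modules), nrow = ns,
                      dimnames = list(sample_ids,
                                      paste0("module", seq_len(config$n_modules))))
    b <- stats::rnorm(nt, config$sad_meanlog, config$sad_sdlog)
    logint <- matrix(rep(b[c(module_idx, free_idx)], ns),
                     ncol = ns)  # taxa x samples
    rows_mod <- seq_len(n_module_taxa)
    mod_of <- rep(seq_len(config$n_modules), each = config$taxa_per_module)
    truth_mod[module_idx] <- mod_of
    logint[rows_mod, ] <- logint[rows_mod, ] +
      config$loading * t(factors)[mod_of, , drop = FALSE]
    if (config$noise_sd > 0)
      logint <- logint + stats::rnorm(length(logint), 0, config$noise_sd)
    intensity <- exp(logint)

    # per-sample proportions: forced mass fixed, rest shared by intensity
    props <- matrix(0, nrow = nt, ncol = ns,
                    dimnames = list(asv_ids, sample_ids))
    if (n_forced) props[forced_idx, ] <- exp_forced
    spare <- 1 - colSums(props)
    if (any(spare <= 0)) abort("forced proportions exceed 1")
    props[c(module_idx, free_idx), ] <-
      sweep(intensity, 2L, spare / colSums(intensity), "*")

    counts <- matrix(0L, nrow = nt, ncol = ns,
                     dimnames = list(asv_ids, sample_ids))
    for (s in seq_len(ns)) {
      p <- props[, s]
      if (!is.null(config$overdispersion)) {
        a <- stats::rgamma(nt, shape = config$overdispersion * p, rate = 1)
        p <- a / sum(a)
      }
      counts[, s] <- stats::rmultinom(1L, config$depth, p)[, 1L]
    }

    pool <- mock_lineage_pool()
    pick <- sample.int(nrow(pool), nt, replace = TRUE)
    lineages <- sprintf("%s;%s;c_%d;o_%d;f_%d;%s;s_%d",
                        pool$domain[pick], pool$phylum[pick], pick, pick, pick,
                        pool$genus[pick], seq_len(nt))
    tax <- taxonomy_map(asv_ids, lineages)

    truth <- data.frame(asv_id = asv_ids, category = truth_cat,
                        module = truth_mod, stringsAsFactors = FALSE)
    list(table = asv_table(counts), tax = tax, truth = truth,
         factors = factors)
  })
}

# realistic ranges for the water-chemistry variables (units as in field data)
env_ranges <- function() {
  list(WT = c(18, 25), pH = c(7.5, 9), DO = c(5, 10), SD = c(0.8, 2.5),
       COD = c(10, 30), PI = c(2, 6), Chla = c(5, 30),
       TN = c(0.526, 0.677), TP = c(0.024, 0.037), TDN = c(0.4, 0.6),
       NH4 = c(0.02, 0.2), PO4 = c(0.005, 0.02), NP = c(15, 25),
       phyto_density = c(1e6, 1e7), depth = c(0.5, 3))
}

#' Simulate sample metadata with planted environmental links
#'
#' Each linked variable is a monotone transform of its module's latent factor
#' plus Gaussian noise, rescaled into the variable's realistic field range;
#' unlinked variables are independent noise on their ranges. With zero noise
#' a linked variable is a strictly monotone function of the factor, so its
#' Spearman correlation with factor-driven taxa is exactly +/-1.
#'
#' @param config a [sim_config()].
#' @param factors samples x modules latent factor matrix from
#'   [simulate_community()].
#' @return metadata `data.frame` (see [read_metadata()]) with a `units`
#'   attribute.
#' @export
simulate_metadata <- function(config, factors) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(rownames(factors))) abort("`factors` must have sample rownames")
  links <- config$env_links
  if (!all(links$module %in% seq_len(ncol(factors))))
    abort("env link targets an unknown module")
  rng <- env_ranges()
  if (!all(links$variable %in% names(rng)))
    abort("unknown env link target variable: %s",
          paste(setdiff(links$variable, names(rng)), collapse = ", "))
  ns <- nrow(factors)
  with_seed(config$seed + 1L, {
    out <- data.frame(sample_id = rownames(factors), stringsAsFactors = FALSE)
    for (v in names(rng)) {
      li <- match(v, links$variable)
      if (!is.na(li)) {
        z <- links$sign[li] * factors[, links$module[li]] +
          stats::rnorm(ns, 0, config$env_noise_sd)
        u <- stats::pnorm(z / sqrt(1 + config$env_noise_sd^2))
      } else {
        u <- stats::runif(ns)
      }
      out[[v]] <- rng[[v]][1L] + (rng[[v]][2L] - rng[[v]][1L]) * u
    }
    attr(out, "units") <- c(WT = "degC", pH = "", DO = "mg/L", SD = "m",
                            COD = "mg/L", PI = "mg/L", Chla = "ug/L",
                            TN = "mg/L", TP = "mg/L", TDN = "mg/L",
                            NH4 = "mg/L", PO4 = "mg/L", NP = "",
                            phyto_density = "cells/L", depth = "m")
    out
  })
}

#' Proportion matrix with planted correlation-module structure
#'
#' Emits the generative block structure (which taxa share a latent factor)
#' together with the noiseless-count proportion matrix from which the network
#' stage must recover it: module taxa driven by their factor at the
#' configured loading and noise, no forced or free taxa.
#'
#' @param config a [sim_config()].
#' @return list with `props` (taxa x samples proportions), `intensity` (the
#'   pre-normalization intensities, in which the shared-driver monotonicity
#'   is exact), `modules` (named integer vector of true module per taxon)
#'   and `factors`.
#' @export
planted_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_modules < 1L) abort("at least one module is required")
  with_seed(config$seed, {
    ns <- config$n_samples
    nt <- config$n_modules * config$taxa_per_module
    ids <- sprintf("ASV_%05d", seq_len(nt))
    sample_ids <- sprintf("S%02d", seq_len(ns))
    factors <- matrix(stats::rnorm(ns * config$n_modules), nrow = ns,
                      dimnames = list(sample_ids,
                                      paste0("module", seq_len(config$n_modules))))
    mod_of <- rep(seq_len(config$n_modules), each = config$taxa_per_module)
    b <- stats::rnorm(nt, config$sad_meanlog, config$sad_sdlog)
    logint <- matrix(rep(b, ns), ncol = ns) +
      config$loading * t(factors)[mod_of, , drop = FALSE]
    if (config$noise_sd > 0)
      logint <- logint + stats::rnorm(length(logint), 0, config$noise_sd)
    intensity <- exp(logint)
    dimnames(intensity) <- list(ids, sample_ids)
    props <- sweep(intensity, 2L, colSums(intensity), "/")
    list(props = props, intensity = intensity,
         modules = stats::setNames(mod_of, ids), factors = factors)
  })
}

#' Random block-structured graph with planted modules
#'
#' Stochastic block model: nodes in the same block are connected with
#' probability `p_within`, nodes in different blocks with `p_between`. Used
#' to benchmark module detection against known community structure.
#'
#' @param n_blocks,nodes_per_block block structure.
#' @param p_within,p_between edge probabilities.
#' @param seed integer seed.
#' @return list with `net` (a [cooc_network()]; isolated nodes absent) and
#'   `truth` (named integer vector of true blocks over all generated nodes).
#' @export
simulate_block_graph <- function(n_blocks = 4L, nodes_per_block = 30L,
                                 p_within = 0.6, p_between = 0.02, seed) {
  if (missing(seed)) abort("`seed` is required")
  n <- n_blocks * nodes_per_block
  ids <- sprintf("N%03d", seq_len(n))
  block <- rep(seq_len(n_blocks), each = nodes_per_block)
  with_seed(seed, {
    pairs <- utils::combn(n, 2L)
    same <- block[pairs[1L, ]] == block[pairs[2L, ]]
    prob <- ifelse(same, p_within, p_between)
    on <- stats::runif(ncol(pairs)) < prob
    edges <- data.frame(from = ids[pairs[1L, on]], to = ids[pairs[2L, on]],
                        rho = 0.9, p = 1e-9, sign = "positive",
                        stringsAsFactors = FALSE)
    list(net = cooc_network(edges), truth = stats::setNames(block, ids))
  })
}

#' Block graph with planted hub and connector nodes
#'
#' Builds a [simulate_block_graph()] backbone, then rewires designated nodes
#' into keystones: each planted hub keeps only links to a fraction
#' `hub_frac` of its own block (a module hub: high within-module
#' connectivity, zero participation); each planted connector keeps only
#' `connector_links` links into every block (participation
#' \eqn{1 - \sum_s (c/k)^2}, e.g. 0.75 for equal links to 4 blocks).
#' Planted nodes are never wiring targets of one another, so their degrees
#' are exactly as planted.
#'
#' @param n_blocks,nodes_per_block,p_within,p_between backbone structure;
#'   the default background densities (0.25 within, 0.01 between) keep
#'   ordinary members' within-degrees well below the hubs'.
#' @param n_hubs,hub_frac,n_connectors,connector_links keystone planting.
#' @param seed integer seed.
#' @return list with `net`, `truth` (block assignment), `hubs`,
#'   `connectors` (planted node ids).
#' @export
simulate_keystone_graph <- function(n_blocks = 4L, nodes_per_block = 30L,
                                    p_within = 0.25, p_between = 0.01,
                                    n_hubs = 2L, hub_frac = 0.8,
                                    n_connectors = 2L, connector_links = 5L,
                                    seed) {
  if (missing(seed)) abort("`seed` is required")
  n <- n_blocks * nodes_per_block
  ids <- sprintf("N%03d", seq_len(n))
  block <- rep(seq_len(n_blocks), each = nodes_per_block)
  if (n_hubs + n_connectors > n_blocks * 2L)
    abort("too many planted nodes for the block structure")
  hubs <- ids[1L + (seq_len(n_hubs) - 1L) %% n_blocks * nodes_per_block]
  conn <- ids[2L + (seq_len(n_connectors) - 1L) %% n_blocks * nodes_per_block]
  planted <- c(hubs, conn)
  with_seed(seed, {
    pairs <- utils::combn(n, 2L)
    a <- pairs[1L, ]; bb <- pairs[2L, ]
    same <- block[a] == block[bb]
    prob <- ifelse(same, p_within, p_between)
    on <- stats::runif(ncol(pairs)) < prob
    # strip all background edges touching planted nodes
    touches <- ids[a] %in% planted | ids[bb] %in% planted
    on[touches] <- FALSE
    edges <- data.frame(from = ids[a[on]], to = ids[bb[on]],
                        stringsAsFactors = FALSE)
    targets <- function(blk) setdiff(ids[block == blk], planted)
    extra <- list()
    for (h in hubs) {
      cand <- targets(block[match(h, ids)])
      k <- ceiling(hub_frac * length(cand))
      extra[[length(extra) + 1L]] <-
        data.frame(from = h, to = sample(cand, k), stringsAsFactors = FALSE)
    }
    for (cc in conn) {
      for (blk in seq_len(n_blocks)) {
        extra[[length(extra) + 1L]] <-
          data.frame(from = cc, to = sample(targets(blk), connector_links),
                     stringsAsFactors = FALSE)
      }
    }
    edges <- rbind(edges, do.call(rbind, extra))
    edges$rho <- 0.9; edges$p <- 1e-9; edges$sign <- "positive"
    list(net = cooc_network(edges), truth = stats::setNames(block, ids),
         hubs = hubs, connectors = conn)
  })
}

#' Write a simulated study to disk
#'
#' Runs [simulate_community()] and [simulate_metadata()] and writes
#' `table.tsv`, `taxonomy.tsv`, `metadata.tsv` and `truth.json` into `dir`.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return the simulation list, invisibly.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_community(config)
  meta <- simulate_metadata(config, sim$factors)
  write_asv_table(sim$table, file.path(dir, "table.tsv"))
  write_taxonomy(sim$tax, file.path(dir, "taxonomy.tsv"))
  write_metadata(meta, file.path(dir, "metadata.tsv"))
  jsonlite::write_json(
    list(truth = sim$truth, env_links = config$env_links,
         seed = config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(sim, list(meta = meta)))
}
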