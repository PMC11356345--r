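test_that("prevalence filter uses a strict more-than rule", {
  n <- 34
  m <- rbind(half = c(rep(1L, 17), rep(0L, 17)),
             over = c(rep(1L, 18), rep(0L, 16)),
             allz = rep(0L, n),
             full = rep(2L, n))
  colnames(m) <- paste0("S", 1:n)
  tab <- asv_table(m)
  kept <- rownames(prevalence_filter(tab, 0.5))
  expect_setequal(kept, c("over", "full"))
  # min_fraction = 0 removes only all-zero ASVs
  expect_setequal(rownames(prevalence_filter(tab, 0)),
                  c("half", "over", "full"))
  expect_error(prevalence_filter(tab, 1), "min_fraction")
})

test_that("Spearman rho and p match the rank-Pearson oracle, ties included", {
  set.seed(3)
  n <- 12
  X <- matrix(stats::rpois(6 * n, 4), nrow = 6,
              dimnames = list(paste0("A", 1:6), paste0("S", 1:n)))
  X[1, ] <- seq_len(n)                 # monotone
  X[2, ] <- rev(seq_len(n))            # anti-monotone
  corr <- spearman_all_pairs(X)
  for (i in 1:5) for (j in (i + 1):6) {
    o <- oracle_spearman(X[i, ], X[j, ])
    expect_equal(corr$rho[i, j], o$rho, tolerance = 1e-12)
    expect_equal(corr$p[i, j], o$p, tolerance = 1e-12)
  }
  expect_equal(corr$rho[1, 2], -1)
  expect_equal(corr$p[1, 2], 0)
  expect_equal(corr$rho[2, 1], corr$rho[1, 2])
  # documented tie example
  o <- oracle_spearman(c(1, 2, 2, 4), c(1, 3, 2, 4))
  Y <- rbind(x = c(1, 2, 2, 4), y = c(1, 3, 2, 4))
  colnames(Y) <- paste0("S", 1:4)
  cc <- spearman_all_pairs(Y)
  expect_equal(cc$rho["x", "y"], o$rho, tolerance = 1e-12)
  expect_error(spearman_all_pairs(Y[, 1:3]), "at least 4")
})

test_that("constant ASVs are recorded as no-edge", {
  X <- rbind(const = rep(3, 8), var1 = 1:8, var2 = c(2, 1, 4, 3, 6, 5, 8, 7))
  colnames(X) <- paste0("S", 1:8)
  expect_message(corr <- spearman_all_pairs(X), "constant")
  expect_true(is.na(corr$rho["const", "var1"]))
  net <- build_network(corr, r_thresh = 0.5, p_thresh = 0.5)
  expect_false("const" %in% net$nodes$asv_id)
})

test_that("edge set equals the brute-force predicate, with strict thresholds", {
  set.seed(21)
  for (n in c(10, 60)) {
    ids <- paste0("A", seq_len(n))
    rho <- matrix(stats::runif(n * n, -1, 1), n, dimnames = list(ids, ids))
    rho[lower.tri(rho)] <- t(rho)[lower.tri(rho)]
    diag(rho) <- 1
    p <- matrix(stats::runif(n * n, 0, 0.12), n, dimnames = list(ids, ids))
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
    diag(p) <- 0
    net <- build_network(list(rho = rho, p = p, ids = ids))
    got <- paste(net$edges$from, net$edges$to)
    expect_setequal(got, oracle_edges(rho, p))
  }
  # rho exactly at threshold is not an edge; signs follow rho
  ids <- c("a", "b", "c")
  rho <- matrix(c(1, 0.6, -0.9, 0.6, 1, 0.2, -0.9, 0.2, 1), 3,
                dimnames = list(ids, ids))
  p <- matrix(1e-6, 3, 3, dimnames = list(ids, ids)); diag(p) <- 0
  net <- build_network(list(rho = rho, p = p, ids = ids))
  expect_equal(nrow(net$edges), 1L)
  expect_identical(net$edges$sign, "negative")
  expect_setequal(net$nodes$asv_id, c("a", "c"))  # b isolated, dropped
})

test_that("module detection separates cliques and is deterministic", {
  clique_edges <- function(ids) {
    cmb <- utils::combn(ids, 2)
    data.frame(from = cmb[1, ], to = cmb[2, ], stringsAsFactors = FALSE)
  }
  e <- rbind(clique_edges(paste0("a", 1:5)), clique_edges(paste0("b", 1:5)),
             data.frame(from = "a1", to = "b1"))
  net <- cooc_network(e)
  mods <- detect_modules(net, seed = 4)
  expect_equal(length(unique(mods)), 2L)
  expect_equal(length(unique(mods[paste0("a", 1:5)])), 1L)
  expect_equal(length(unique(mods[paste0("b", 1:5)])), 1L)
  expect_identical(detect_modules(net, seed = 4), mods)
  # single clique: one module, labelled 1
  one <- cooc_network(clique_edges(paste0("c", 1:6)))
  expect_identical(unname(unique(detect_modules(one, seed = 1))), 1L)
  # labels ordered by size
  big <- rbind(clique_edges(paste0("x", 1:8)), clique_edges(paste0("y", 1:4)),
               data.frame(from = "x1", to = "y1"))
  mb <- detect_modules(cooc_network(big), seed = 2)
  expect_identical(unname(mb["x2"]), 1L)
  expect_identical(unname(mb["y2"]), 2L)
})

test_that("Zi and Pi match the direct-definition oracle on random graphs", {
  for (s in 1:6) {
    net <- random_graph(n = sample(20:60, 1), p = 0.12, seed = 100 + s)
    ids <- net$nodes$asv_id
    modules <- stats::setNames(sample.int(4, length(ids), replace = TRUE), ids)
    zp <- zi_pi(net, modules)
    o <- oracle_zipi(net, modules)
    expect_equal(zp$zi, o$zi, tolerance = 1e-12)
    expect_equal(zp$pi, o$pi, tolerance = 1e-12)
    expect_equal(zp$degree, o$degree)
    # degree conservation and Pi bounds
    M <- length(unique(modules[ids]))
    expect_true(all(zp$pi <= 1 - 1 / M + 1e-12))
    expect_true(all(zp$pi >= -1e-12))
  }
})

test_that("Pi reflects the spread of links across modules", {
  e <- data.frame(from = c("h", "h", "h", "h"),
                  to = c("m1a", "m1b", "m2a", "m2b"))
  e2 <- rbind(e, data.frame(from = c("m1a", "m2a"), to = c("m1b", "m2b")))
  net <- cooc_network(e2)
  modules <- c(h = 1L, m1a = 1L, m1b = 1L, m2a = 2L, m2b = 2L)
  zp <- zi_pi(net, modules)
  expect_equal(zp$pi[zp$asv_id == "h"], 0.5)     # even split over 2 modules
  expect_equal(zp$pi[zp$asv_id == "m1a"], 0)     # all links inside own module
})

test_that("role classification partitions nodes with peripheral boundaries", {
  zp <- data.frame(asv_id = c("a", "b", "c", "d", "e"),
                   module = 1L, degree = 5L,
                   zi = c(3.0, 0.2, 3.1, 0.5, 2.5),
                   pi = c(0.1, 0.7, 0.8, 0.3, 0.62))
  roles <- classify_roles(zp)
  expect_identical(as.character(roles$role),
                   c("module hub", "connector", "network hub", "peripheral",
                     "peripheral"))  # boundary Zi=2.5, Pi=0.62 -> peripheral
  expect_setequal(keystone_set(roles), c("a", "b", "c"))
  expect_identical(keystone_set(roles[roles$role == "peripheral", ]),
                   character(0))
})

test_that("planted modules and keystones are recovered", {
  bg <- simulate_block_graph(n_blocks = 4, nodes_per_block = 30,
                             p_within = 0.6, p_between = 0.02, seed = 8)
  mods <- detect_modules(bg$net, seed = 1)
  ari <- mclust::adjustedRandIndex(mods, bg$truth[names(mods)])
  expect_gte(ari, 0.9)
  kg <- simulate_keystone_graph(seed = 9)
  net <- annotate_network(kg$net, seed = 2)
  found <- keystone_set(net$nodes)
  planted <- c(kg$hubs, kg$connectors)
  expect_gte(mean(planted %in% found), 0.8)
  # connector Pi near its analytic value 1 - 4 (1/4)^2
  pi_conn <- net$nodes$pi[net$nodes$asv_id %in% kg$connectors]
  expect_true(all(abs(pi_conn - 0.75) <= 0.1))
  # hubs carry high within-module connectivity
  expect_true(all(net$nodes$zi[net$nodes$asv_id %in% kg$hubs] > 2.5))
})

test_that("network summary reports consistent statistics", {
  kg <- simulate_keystone_graph(seed = 12)
  net <- annotate_network(kg$net, seed = 3)
  tax <- taxonomy_map(net$nodes$asv_id,
                      rep(c("Bacteria;Proteobacteria;c;o;f;g;s",
                            "Bacteria;Chloroflexi;c;o;f;g;s"),
                          length.out = nrow(net$nodes)))
  s <- network_summary(net, tax)
  expect_equal(s$n_nodes, nrow(net$nodes))
  expect_equal(s$n_edges, nrow(net$edges))
  expect_equal(s$pct_positive + s$pct_negative, 100)
  expect_equal(sum(s$module_fractions_pct), 100, tolerance = 1e-9)
  expect_equal(unname(sum(s$roles)), s$n_nodes)
  expect_equal(sum(s$phylum_pct), 100, tolerance = 1e-9)
  expect_equal(s$n_keystones, length(keystone_set(net$nodes)))
  # all-positive toy network
  toy <- annotate_network(cooc_network(data.frame(
    from = c("a", "b", "c"), to = c("b", "c", "a"), rho = 0.9, p = 1e-4)),
    seed = 1)
  st <- network_summary(toy)
  expect_equal(st$pct_positive, 100)
  expect_equal(st$pct_negative, 0)
})

test_that("degree conservation holds across modules for every node", {
  net <- random_graph(50, 0.1, seed = 77)
  mods <- detect_modules(net, seed = 5)
  zp <- zi_pi(net, mods)
  # recompute k_is sums via the oracle's adjacency route
  o <- oracle_zipi(net, mods)
  expect_equal(zp$degree, o$degree)
  expect_equal(zp$degree, net$nodes$degree)
})

test_that("network export writes edge, node and GraphML files", {
  kg <- simulate_block_graph(n_blocks = 2, nodes_per_block = 8,
                             p_within = 0.8, p_between = 0.05, seed = 2)
  net <- annotate_network(kg$net, seed = 1)
  dir <- withr::local_tempdir()
  export_network(net, dir)
  expect_true(all(file.exists(file.path(dir, c("edges.tsv", "nodes.tsv",
                                               "network.graphml")))))
  ed <- utils::read.table(file.path(dir, "edges.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(ed), nrow(net$edges))
  g <- igraph::read_graph(file.path(dir, "network.graphml"), format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
})
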