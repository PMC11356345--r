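# Independent oracle implementations used to cross-check the package.
# Each is written from the textbook definition, deliberately taking a
# different computational route than the package code.

# Spearman rho via explicit rank-then-Pearson closed form; p via the
# t approximation on n - 2 df.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(list(rho = NA_real_, p = NA_real_))
  rho <- sum(dx * dy) / den
  n <- length(x)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p)
}

# Zi/Pi recomputed from an explicit adjacency matrix with per-definition
# loops over modules.
oracle_zipi <- function(net, modules) {
  ids <- net$nodes$asv_id
  n <- length(ids)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges$from[e]; j <- net$edges$to[e]
    A[i, j] <- A[i, j] + 1L
    A[j, i] <- A[j, i] + 1L
  }
  mod <- modules[ids]
  mods <- sort(unique(as.integer(mod)))
  zi <- pi_ <- k <- numeric(n)
  own <- numeric(n)
  for (v in seq_len(n)) {
    k[v] <- sum(A[v, ])
    kis <- vapply(mods, function(s) sum(A[v, mod == s]), numeric(1))
    own[v] <- kis[match(mod[v], mods)]
    pi_[v] <- 1 - sum((kis / k[v])^2)
  }
  for (s in mods) {
    members <- which(as.integer(mod) == s)
    mu <- mean(own[members])
    sdev <- if (length(members) > 1) stats::sd(own[members]) else 0
    zi[members] <- if (sdev > 0) (own[members] - mu) / sdev else 0
  }
  data.frame(asv_id = ids, degree = k, zi = zi, pi = pi_,
             stringsAsFactors = FALSE)
}

# textbook Chao & Lee ACE, independent of the package routine
oracle_ace <- function(x, cutoff = 10) {
  x <- x[x > 0]
  rare <- x[x <= cutoff]
  s_abund <- sum(x > cutoff)
  if (!length(rare)) return(s_abund)
  n_rare <- sum(rare)
  f <- tabulate(rare, nbins = cutoff)
  c_ace <- 1 - f[1] / n_rare
  if (c_ace == 0) return(sednet::chao1(x))
  s_rare <- length(rare)
  num <- sum(seq_len(cutoff) * (seq_len(cutoff) - 1) * f)
  g2 <- max(s_rare / c_ace * num / (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f[1] / c_ace * g2
}

# brute-force edge predicate: double loop over unordered pairs
oracle_edges <- function(rho, p, r_thresh = 0.6, p_thresh = 0.05) {
  n <- nrow(rho)
  out <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!is.na(rho[i, j]) && !is.na(p[i, j]) &&
          abs(rho[i, j]) > r_thresh && p[i, j] < p_thresh) {
        out <- c(out, paste(rownames(rho)[i], rownames(rho)[j]))
      }
    }
  }
  out
}

# small deterministic count table used across tests
toy_table <- function() {
  m <- matrix(c(50L, 30L, 20L, 10L,
                5L,  40L, 25L, 30L,
                0L,  1L,  2L,  3L,
                45L, 29L, 53L, 57L),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("ASV", 1:4), paste0("S", 1:4)))
  asv_table(m)
}

toy_taxonomy <- function() {
  taxonomy_map(paste0("ASV", 1:5),
               c("Bacteria;Proteobacteria;c1;o1;f1;Dechloromonas;s1",
                 "Bacteria;Bacteroidetes;c2;o2;f2;Flavobacterium;s2",
                 "Bacteria;Cyanobacteria;Oxyphotobacteria;Chloroplast;f3;g3;s3",
                 "Bacteria;Proteobacteria;c4;o4;f4;;",
                 "unassigned;;;;;;"))
}

random_props <- function(n_asv, n_sample) {
  m <- matrix(stats::rexp(n_asv * n_sample)^2, n_asv, n_sample,
              dimnames = list(paste0("A", seq_len(n_asv)),
                              paste0("S", seq_len(n_sample))))
  sweep(m, 2, colSums(m), "/")
}

# random cooc_network on n nodes with edge probability p (no isolated-node
# guarantee; truth-style module labels drawn uniformly)
random_graph <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("V%03d", seq_len(n))
  pairs <- utils::combn(n, 2)
  on <- stats::runif(ncol(pairs)) < p
  edges <- data.frame(from = ids[pairs[1, on]], to = ids[pairs[2, on]],
                      stringsAsFactors = FALSE)
  cooc_network(edges)
}
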