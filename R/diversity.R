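#' Alpha diversity and coverage estimators
#'
#' Per-sample estimators computed from a single vector of ASV counts:
#' Shannon entropy (natural log), Gini-Simpson diversity, the Chao1 and ACE
#' richness estimators, and Good's coverage. `alpha_diversity()` applies all
#' of them to every sample of an ASV table and also reports the observed
#' richness `S_obs`, singleton count `F1`, doubleton count `F2` and sample
#' total `N`.
#'
#' Shannon and Gini-Simpson are delegated to [vegan::diversity()]. Chao1 uses
#' the classic estimator \eqn{S_{obs} + F_1^2/(2F_2)} with the bias-corrected
#' form \eqn{S_{obs} + F_1(F_1-1)/2} when no doubletons exist. ACE is the
#' Chao & Lee abundance-based coverage estimator with rare cutoff
#' `rare_cutoff` (counts <= cutoff are "rare"); when its sample coverage is
#' zero (all rare taxa are singletons) it falls back to Chao1.
#'
#' @param counts non-negative integer vector of per-ASV counts for one sample
#'   (zeros allowed; the sum must be positive).
#' @param rare_cutoff ACE rare-taxon cutoff, default 10.
#' @return a single numeric value; `alpha_diversity()` returns a `data.frame`
#'   with one row per sample.
#' @examples
#' shannon(c(4, 3, 2, 1))   # ~1.2799
#' simpson(c(4, 3, 2, 1))   # 0.70
#' chao1(c(2, 2, 1, 1, 1))  # S=5, F1=3, F2=2
#' goods_coverage(c(95, rep(1, 5)))
#' @name alpha-diversity
NULL

check_counts <- function(counts) {
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts)))
    abort("`counts` must be non-negative integers")
  if (sum(counts) <= 0) abort("`counts` sums to zero")
  counts[counts > 0]
}

#' @rdname alpha-diversity
#' @export
shannon <- function(counts) {
  x <- check_counts(counts)
  as.numeric(vegan::diversity(x, index = "shannon"))
}

#' @rdname alpha-diversity
#' @export
simpson <- function(counts) {
  x <- check_counts(counts)
  as.numeric(vegan::diversity(x, index = "simpson"))
}

#' @rdname alpha-diversity
#' @export
chao1 <- function(counts) {
  x <- check_counts(counts)
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 == 0) return(as.numeric(s_obs))
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' @rdname alpha-diversity
#' @export
ace <- function(counts, rare_cutoff = 10) {
  x <- check_counts(counts)
  rare <- x[x <= rare_cutoff]
  s_abund <- sum(x > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) return(as.numeric(s_abund))
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) return(chao1(x))  # all rare taxa are singletons
  i <- seq_len(rare_cutoff)
  fi <- vapply(i, function(k) sum(rare == k), numeric(1))
  gamma2 <- max(s_rare / c_ace * sum(i * (i - 1) * fi) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' @rdname alpha-diversity
#' @export
goods_coverage <- function(counts) {
  x <- check_counts(counts)
  1 - sum(x == 1) / sum(x)
}

#' @rdname alpha-diversity
#' @param table an [asv_table()].
#' @export
alpha_diversity <- function(table, rare_cutoff = 10) {
  stopifnot(is_asv_table(table))
  one <- function(x) {
    pos <- x[x > 0]
    data.frame(S_obs = length(pos), shannon = shannon(x), simpson = simpson(x),
               chao1 = chao1(x), ace = ace(x, rare_cutoff),
               goods_coverage = goods_coverage(x),
               F1 = sum(pos == 1), F2 = sum(pos == 2), N = sum(pos))
  }
  res <- do.call(rbind, apply(unclass(table), 2L, one, simplify = FALSE))
  cbind(data.frame(sample_id = colnames(table), stringsAsFactors = FALSE),
        res, row.names = NULL)
}
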