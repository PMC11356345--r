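#' Six-way abundance classification of ASVs
#'
#' Classifies every ASV from its per-sample relative abundances into one of
#' six categories, using the two standard thresholds of the rare-biosphere
#' literature: abundant means at least `abund_cut` (1%) of a sample, rare
#' means below `rare_cut` (0.01%). With `m` the minimum and `M` the maximum
#' proportion of an ASV across samples:
#'
#' * `AAT` (always abundant): `m >= abund_cut`;
#' * `ART` (always rare): `M < rare_cut`;
#' * `CRAT` (conditionally rare and abundant): `M >= abund_cut` and
#'   `m < rare_cut`;
#' * `CAT` (conditionally abundant): `M >= abund_cut` (and `m >= rare_cut`);
#' * `CRT` (conditionally rare): `m < rare_cut` (and `M < abund_cut`);
#' * `MT` (moderate): everything else, i.e. always between the thresholds.
#'
#' The rules are tested in that order, so the six categories partition the
#' ASV set. Coarse groups follow the usual simplification: AAT/CAT/CRAT are
#' `abundant`, ART/CRT are `rare`, MT is `moderate`. A zero proportion counts
#' as below `rare_cut`; an ASV sitting exactly at `rare_cut` in every sample
#' is MT.
#'
#' @param props proportion matrix (ASV x sample), each column summing to 1;
#'   typically `relative_abundance(rarefied_table)`.
#' @param rare_cut rare threshold as a proportion, default `1e-4` (0.01%).
#' @param abund_cut abundant threshold as a proportion, default `0.01` (1%).
#' @return a `category_assignment`: `data.frame` with columns `asv_id`,
#'   `category` (factor with the six levels) and `group` (factor
#'   abundant/rare/moderate), plus a `thresholds` attribute.
#' @examples
#' p <- matrix(c(0.02, 0.011, 0.5, 0.989, 5e-5, 0,
#'               0.48, 0, 0.0005, 0.0005), nrow = 5, byrow = TRUE,
#'             dimnames = list(paste0("ASV", 1:5), c("S1", "S2")))
#' classify_asvs(p)
#' @export
classify_asvs <- function(props, rare_cut = 1e-4, abund_cut = 0.01) {
  props <- as.matrix(props)
  csum <- colSums(props)
  if (any(abs(csum - 1) > 1e-8))
    abort("`props` columns must sum to 1 (sample '%s' sums to %.6f)",
          colnames(props)[which.max(abs(csum - 1))], csum[which.max(abs(csum - 1))])
  m <- apply(props, 1L, min)
  M <- apply(props, 1L, max)
  cat <- ifelse(m >= abund_cut, "AAT",
         ifelse(M < rare_cut, "ART",
         ifelse(M >= abund_cut & m < rare_cut, "CRAT",
         ifelse(M >= abund_cut, "CAT",
         ifelse(m < rare_cut, "CRT", "MT")))))
  grp <- c(AAT = "abundant", CAT = "abundant", CRAT = "abundant",
           ART = "rare", CRT = "rare", MT = "moderate")[cat]
  out <- data.frame(asv_id = rownames(props),
                    category = factor(cat, levels = category_levels()),
                    group = factor(grp, levels = group_levels()),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(rare_cut = rare_cut, abund_cut = abund_cut)
  class(out) <- c("category_assignment", "data.frame")
  out
}

#' @rdname classify_asvs
#' @export
category_levels <- function() c("AAT", "CAT", "CRAT", "ART", "CRT", "MT")

#' @rdname classify_asvs
#' @export
group_levels <- function() c("abundant", "rare", "moderate")

#' Contribution of each abundance category to the community
#'
#' For every category (and coarse group) reports the number of member ASVs
#' and the average relative abundance: the mean over samples of the summed
#' proportion of member ASVs, expressed in percent. Group rows aggregate
#' their categories, so abundant + rare + moderate sums to 100%.
#'
#' @param assignment a `category_assignment` from [classify_asvs()].
#' @param props the proportion matrix the assignment was computed from.
#' @return `data.frame` with columns `level` (`"category"` or `"group"`),
#'   `label`, `n_asvs`, `avg_rel_abund_pct`.
#' @export
summarize_partition <- function(assignment, props) {
  props <- as.matrix(props)
  idx <- match(rownames(props), assignment$asv_id)
  if (anyNA(idx))
    abort("ASV '%s' missing from assignment", rownames(props)[which(is.na(idx))[1L]])
  contrib <- function(keep) {
    if (!any(keep)) return(0)
    mean(colSums(props[keep, , drop = FALSE])) * 100
  }
  cat <- as.character(assignment$category)[idx]
  grp <- as.character(assignment$group)[idx]
  rows_c <- lapply(category_levels(), function(lv)
    data.frame(level = "category", label = lv, n_asvs = sum(cat == lv),
               avg_rel_abund_pct = contrib(cat == lv)))
  rows_g <- lapply(group_levels(), function(lv)
    data.frame(level = "group", label = lv, n_asvs = sum(grp == lv),
               avg_rel_abund_pct = contrib(grp == lv)))
  out <- do.call(rbind, c(rows_c, rows_g))
  rownames(out) <- NULL
  out
}

#' Cross-tabulate keystone taxa against abundance groups
#'
#' Counts how many keystone ASVs fall in each coarse abundance group --
#' the standard check of whether network-structural importance concentrates
#' in the rare or the abundant fraction of the community.
#'
#' @param assignment a `category_assignment` from [classify_asvs()].
#' @param keystones character vector of keystone ASV ids (see
#'   [keystone_set()]).
#' @return named integer vector over `abundant`, `rare`, `moderate`.
#' @export
category_of_keystones <- function(assignment, keystones) {
  idx <- match(keystones, assignment$asv_id)
  if (anyNA(idx))
    abort("keystone '%s' not in assignment", keystones[which(is.na(idx))[1L]])
  tab <- table(factor(assignment$group[idx], levels = group_levels()))
  stats::setNames(as.integer(tab), group_levels())
}
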