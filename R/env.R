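#' Trophic state index of each sample
#'
#' Two established composites are available:
#'
#' * `"tli_composite"` (default): the Chinese comprehensive trophic level
#'   index. Component sub-indices
#'   \eqn{TLI(Chl) = 10(2.5 + 1.086 \ln Chl)} (Chl-a in ug/L),
#'   \eqn{TLI(TP) = 10(9.436 + 1.624 \ln TP)} (mg/L),
#'   \eqn{TLI(TN) = 10(5.453 + 1.694 \ln TN)} (mg/L),
#'   \eqn{TLI(SD) = 10(5.118 - 1.94 \ln SD)} (m),
#'   \eqn{TLI(COD_{Mn}) = 10(0.109 + 2.661 \ln PI)} (permanganate index,
#'   mg/L), combined with Chl-a-correlation weights
#'   \eqn{W_j = r_j^2 / \sum r^2} where r = (1, 0.84, 0.82, -0.83, 0.83).
#' * `"carlson"`: Carlson-style components
#'   \eqn{TSI(SD) = 60 - 14.41 \ln SD}, \eqn{TSI(Chl) = 9.81 \ln Chl + 30.6},
#'   \eqn{TSI(TP) = 14.42 \ln(1000\,TP) + 4.15} (TP in mg/L), averaged.
#'
#' Both composites live on the 0--100 trophic scale (roughly: < 30
#' oligotrophic, 30--50 mesotrophic, > 50 eutrophic). Components missing for
#' a sample (absent column or `NA`) are dropped with weight renormalization
#' and a message.
#'
#' @param meta metadata `data.frame` with `sample_id` and (a subset of) the
#'   columns `Chla`, `TP`, `TN`, `SD`, `PI`.
#' @param method `"tli_composite"` or `"carlson"`.
#' @return a `data.frame` with `sample_id`, one column per component
#'   sub-index, and the composite `TSI`; `method` attribute records the
#'   formula used.
#' @export
trophic_state_index <- function(meta, method = c("tli_composite", "carlson")) {
  method <- match.arg(method)
  comp_val <- function(var, f) {
    if (!var %in% names(meta)) return(rep(NA_real_, nrow(meta)))
    x <- meta[[var]]
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad))
      abort("nonpositive %s for sample '%s': cannot take log",
            var, meta$sample_id[bad[1L]])
    ifelse(is.na(x), NA_real_, f(x))
  }
  if (method == "tli_composite") {
    comps <- cbind(
      TLI_Chla = comp_val("Chla", function(x) 10 * (2.5 + 1.086 * log(x))),
      TLI_TP   = comp_val("TP",   function(x) 10 * (9.436 + 1.624 * log(x))),
      TLI_TN   = comp_val("TN",   function(x) 10 * (5.453 + 1.694 * log(x))),
      TLI_SD   = comp_val("SD",   function(x) 10 * (5.118 - 1.940 * log(x))),
      TLI_PI   = comp_val("PI",   function(x) 10 * (0.109 + 2.661 * log(x))))
    r <- c(1, 0.84, 0.82, -0.83, 0.83)
    w <- r^2 / sum(r^2)
    wm <- matrix(w, nrow = nrow(comps), ncol = 5L, byrow = TRUE)
    wm[is.na(comps)] <- 0
    tot <- rowSums(wm)
    if (any(tot == 0)) abort("no TLI component available for sample '%s'",
                             meta$sample_id[which(tot == 0)[1L]])
    tsi <- rowSums(comps * wm, na.rm = TRUE) / tot
  } else {
    comps <- cbind(
      TSI_SD   = comp_val("SD",   function(x) 60 - 14.41 * log(x)),
      TSI_Chla = comp_val("Chla", function(x) 9.81 * log(x) + 30.6),
      TSI_TP   = comp_val("TP",   function(x) 14.42 * log(x * 1000) + 4.15))
    k <- rowSums(!is.na(comps))
    if (any(k == 0)) abort("no TSI component available for sample '%s'",
                           meta$sample_id[which(k == 0)[1L]])
    tsi <- rowMeans(comps, na.rm = TRUE)
  }
  if (anyNA(comps))
    message(sprintf("%d missing component value(s) dropped with weight renormalization",
                    sum(is.na(comps))))
  out <- data.frame(sample_id = meta$sample_id, comps, TSI = tsi,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  out
}

# Long-format Spearman screen of feature rows against environmental columns.
# features: matrix, rows = features, cols = samples; env: data.frame with
# sample_id plus numeric variables. Pairs with fewer than min_n complete
# observations, or zero-variance features, yield NA rho/p (not computed).
env_screen_core <- function(features, env, min_n = 5L) {
  common <- intersect(colnames(features), env$sample_id)
  if (length(common) < min_n)
    abort("only %d samples shared between features and metadata", length(common))
  F <- features[, common, drop = FALSE]
  E <- env[match(common, env$sample_id), setdiff(names(env), "sample_id"),
           drop = FALSE]
  num <- vapply(E, is.numeric, logical(1))
  E <- E[num]
  out <- vector("list", length(E))
  for (v in seq_along(E)) {
    y <- E[[v]]
    ok <- !is.na(y)
    if (sum(ok) >= min_n && nrow(F) > 0) {
      res <- spearman_engine(t(F[, ok, drop = FALSE]),
                             matrix(y[ok], ncol = 1L))
      rho <- res$rho[, 1L]
      p <- res$p[, 1L]
      n <- sum(ok)
    } else {
      rho <- rep(NA_real_, nrow(F)); p <- rho; n <- sum(ok)
    }
    out[[v]] <- data.frame(feature = rownames(F),
                           variable = rep(names(E)[v], length(rho)),
                           rho = rho, p = p, n = rep(n, length(rho)),
                           stringsAsFactors = FALSE)
  }
  scr <- do.call(rbind, out)
  scr$star <- p_stars(scr$p)
  scr$direction <- ifelse(is.na(scr$rho), NA_character_,
                          ifelse(scr$rho > 0, "positive", "negative"))
  rownames(scr) <- NULL
  class(scr) <- c("correlation_screen", "data.frame")
  scr
}

#' Screen alpha-diversity indices against environmental variables
#'
#' Spearman rho, p and significance stars for every (diversity index,
#' environmental variable) pair. Pairs with fewer than 5 complete
#' observations are left `NA`.
#'
#' @param alpha `data.frame` from [alpha_diversity()].
#' @param meta metadata `data.frame` with `sample_id`.
#' @param indices which index columns to screen.
#' @return a `correlation_screen` `data.frame`: `feature`, `variable`, `rho`,
#'   `p`, `n`, `star`, `direction`.
#' @export
diversity_env_screen <- function(alpha, meta,
                                 indices = c("S_obs", "shannon", "simpson",
                                             "chao1", "ace", "goods_coverage")) {
  F <- t(as.matrix(alpha[indices]))
  colnames(F) <- alpha$sample_id
  env_screen_core(F, meta)
}

#' Screen taxa against environmental variables and trophic state
#'
#' Spearman screen of a taxon x sample proportion table (typically an
#' [aggregate_rank()] output at phylum or genus level) against every
#' environmental variable, with the composite TSI appended as an extra
#' variable when supplied.
#'
#' @param rank_table taxon x sample proportion matrix.
#' @param meta metadata `data.frame`.
#' @param tsi optional [trophic_state_index()] result; its `TSI` column is
#'   appended as variable `"TSI"`.
#' @return a `correlation_screen` `data.frame`.
#' @export
taxa_env_screen <- function(rank_table, meta, tsi = NULL) {
  env <- meta
  if (!is.null(tsi))
    env$TSI <- tsi$TSI[match(env$sample_id, tsi$sample_id)]
  env_screen_core(as.matrix(rank_table), env)
}

#' Screen keystone ASVs against environmental variables and trophic state
#'
#' @param props ASV x sample proportion matrix (all ASVs; keystone rows are
#'   selected from it).
#' @param keystones character vector of keystone ASV ids.
#' @param meta metadata `data.frame`.
#' @param tsi optional [trophic_state_index()] result.
#' @return a `correlation_screen` `data.frame` (zero rows when no keystones).
#' @export
keystone_env_screen <- function(props, keystones, meta, tsi = NULL) {
  env <- meta
  if (!is.null(tsi))
    env$TSI <- tsi$TSI[match(env$sample_id, tsi$sample_id)]
  missing_ks <- setdiff(keystones, rownames(props))
  if (length(missing_ks))
    abort("keystone '%s' not in proportion matrix", missing_ks[1L])
  F <- as.matrix(props)[keystones, , drop = FALSE]
  env_screen_core(F, env)
}

#' Eutrophication indicator calls from a correlation screen
#'
#' Taxa (or ASVs) whose correlation with the trophic state index is starred
#' (p < 0.05), annotated with the direction of the association. The result is
#' invariant to the row order of the screen.
#'
#' @param screen a `correlation_screen`.
#' @param target variable name to call indicators against, default `"TSI"`.
#' @return `data.frame` with `taxon`, `direction`, `rho`, `p`, `star`,
#'   ordered by taxon.
#' @export
indicator_call <- function(screen, target = "TSI") {
  if (!target %in% screen$variable)
    abort("screen does not contain variable '%s'", target)
  sel <- screen$variable == target & !is.na(screen$star) & screen$star != ""
  out <- screen[sel, c("feature", "direction", "rho", "p", "star")]
  names(out)[1L] <- "taxon"
  out <- out[order(out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}
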