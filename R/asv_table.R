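#' Construct an ASV count table
#'
#' The central data container: a non-negative integer matrix of read counts
#' with amplicon sequence variants (ASVs) as rows and samples as columns.
#' Row and column names must be unique, non-empty identifiers.
#'
#' @param counts numeric matrix of non-negative integer counts with rownames
#'   (ASV ids) and colnames (sample ids).
#' @return an `asv_table` object (an integer matrix with class attribute).
#' @examples
#' m <- matrix(c(5L, 0L, 1L, 2L, 0L, 7L), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("ASV", 1:3), c("S1", "S2")))
#' asv_table(m)
#' @export
asv_table <- function(counts) {
  if (!is.matrix(counts)) abort("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("`counts` must have ASV rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) abort("duplicate ASV ids")
  if (anyDuplicated(colnames(counts))) abort("duplicate sample ids")
  if (any(rownames(counts) == "") || any(colnames(counts) == ""))
    abort("empty ASV or sample id")
  if (!is.numeric(counts)) abort("counts must be numeric")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    abort("invalid count at ASV '%s', sample '%s': %s",
          rownames(counts)[i[1L]], colnames(counts)[i[2L]],
          format(counts[bad[1L]]))
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("asv_table", "matrix", "array"))
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV table: %d ASVs x %d samples, %s total reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  depth <- colSums(x)
  cat(sprintf("sample depth: min %s, median %s, max %s\n",
              format(min(depth), big.mark = ","),
              format(stats::median(depth), big.mark = ","),
              format(max(depth), big.mark = ",")))
  invisible(x)
}

#' Test whether an object is an ASV table
#' @param x object.
#' @return logical scalar.
#' @export
is_asv_table <- function(x) inherits(x, "asv_table")

#' Read an ASV count table
#'
#' Two dialects are supported: `tsv` (ASVs as rows, samples as columns, first
#' column header `#ASV_ID` -- the QIIME feature-table export convention) and
#' `biom-json` (the JSON flavour of the BIOM format, parsed with the
#' \pkg{biomformat} package).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"biom-json"`.
#' @return an [asv_table()].
#' @seealso [write_asv_table()]
#' @export
read_asv_table <- function(path, dialect = c("tsv", "biom-json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort("file not found: %s", path)
  if (dialect == "tsv") {
    if (file.size(path) == 0L) abort("empty ASV table file: %s", path)
    df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                            comment.char = "", quote = "", stringsAsFactors = FALSE)
    if (ncol(df) < 2L) abort("malformed ASV table header in %s", path)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
      abort("non-numeric counts in column '%s' of %s", colnames(df)[-1L][bad], path)
    }
    rownames(m) <- ids
    asv_table(m)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      abort("the biomformat package is required for the biom-json dialect")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))
    asv_table(m)
  }
}

#' Write an ASV count table
#'
#' @param table an [asv_table()].
#' @param path output path.
#' @param dialect `"tsv"` or `"biom-json"`; see [read_asv_table()].
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(table, path, dialect = c("tsv", "biom-json")) {
  dialect <- match.arg(dialect)
  stopifnot(is_asv_table(table))
  if (dialect == "tsv") {
    df <- data.frame(`#ASV_ID` = rownames(table), unclass(table),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      abort("the biomformat package is required for the biom-json dialect")
    b <- biomformat::make_biom(data = unclass(table))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Read a taxonomy table
#'
#' Parses a two-column TSV (`ASV id <TAB> lineage`) where the lineage is a
#' semicolon-delimited ranked string, optionally with QIIME-style rank prefixes
#' (`d__`, `p__`, ...). Ranks left empty, bare prefixes, and the literal labels
#' `unassigned`/`unclassified`/`unknown` are recorded as `NA` (unassigned).
#'
#' @param path file path.
#' @return a `data.frame` with columns `asv_id` and the seven canonical ranks
#'   `domain, phylum, class, order, family, genus, species`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort("taxonomy file needs id and lineage columns: %s", path)
  taxonomy_map(df[[1L]], df[[2L]])
}

#' Build a taxonomy map from lineage strings
#'
#' @param asv_ids character vector of ASV ids.
#' @param lineages character vector of semicolon-delimited lineages.
#' @return a taxonomy `data.frame`; see [read_taxonomy()].
#' @export
taxonomy_map <- function(asv_ids, lineages) {
  if (anyDuplicated(asv_ids)) abort("duplicate ASV ids in taxonomy")
  ranks <- tax_ranks()
  parts <- strsplit(as.character(lineages), ";", fixed = TRUE)
  clean1 <- function(x) {
    x <- trimws(x)
    x <- sub("^[dkpcofgs]__", "", x)
    x[x == "" | tolower(x) %in% c("unassigned", "unclassified", "unknown", "na")] <- NA_character_
    length(x) <- 7L  # pad with NA
    x
  }
  m <- t(vapply(parts, clean1, character(7L)))
  out <- data.frame(asv_id = as.character(asv_ids), m, stringsAsFactors = FALSE)
  names(out) <- c("asv_id", ranks)
  rownames(out) <- NULL
  out
}

#' Canonical taxonomic ranks, domain to species
#' @return character vector of length 7.
#' @export
tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

#' Write a taxonomy table
#' @param tax taxonomy `data.frame` from [read_taxonomy()]/[taxonomy_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  lin <- apply(as.matrix(tax[tax_ranks()]), 1L, function(x) {
    x[is.na(x)] <- "unassigned"
    paste(x, collapse = ";")
  })
  utils::write.table(data.frame(`#ASV_ID` = tax$asv_id, taxonomy = lin,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with one header line of variable names (first column `sample_id`), an
#' optional second line starting with `#units` giving per-variable units, and
#' one row per sample. Non-numeric cells in measurement columns become `NA`.
#'
#' @param path file path.
#' @return a `data.frame` with a `sample_id` column, numeric measurement
#'   columns, and a `units` attribute (named character vector, possibly empty).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  lines <- readLines(path)
  if (!length(lines)) abort("empty metadata file: %s", path)
  units <- character(0)
  hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  if (length(body) && startsWith(body[[1L]], "#units")) {
    u <- strsplit(body[[1L]], "\t", fixed = TRUE)[[1L]]
    units <- stats::setNames(u[-1L], hdr[-1L])
    body <- body[-1L]
  }
  df <- utils::read.table(text = paste(body, collapse = "\n"), sep = "\t",
                          header = FALSE, col.names = hdr, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  names(df)[1L] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) abort("duplicate sample ids in metadata")
  for (j in seq_along(df)[-1L]) df[[j]] <- suppressWarnings(as.numeric(df[[j]]))
  neg <- vapply(df[-1L], function(x) any(x < 0, na.rm = TRUE), logical(1))
  if (any(neg) && any(names(neg)[neg] != "WT"))
    warning("negative values in metadata column(s): ",
            paste(setdiff(names(neg)[neg], "WT"), collapse = ", "))
  attr(df, "units") <- units
  df
}

#' Write a sample metadata table
#' @param meta metadata `data.frame` (see [read_metadata()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(meta), collapse = "\t"), con)
  units <- attr(meta, "units")
  if (!is.null(units) && length(units)) {
    u <- units[names(meta)[-1L]]
    u[is.na(u)] <- ""
    writeLines(paste(c("#units", u), collapse = "\t"), con)
  }
  utils::write.table(meta, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# validate that metadata covers (a subset relation with) the table's samples
match_samples <- function(table, meta) {
  common <- intersect(colnames(table), meta$sample_id)
  if (!length(common))
    abort("no samples shared between ASV table and metadata")
  common
}
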