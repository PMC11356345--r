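test_that("asv_table validates counts and identifiers", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  expect_s3_class(asv_table(m), "asv_table")
  expect_error(asv_table(matrix(1:4, 2, 2)), "rownames")
  m2 <- m; m2[1, 1] <- -1
  expect_error(asv_table(m2), "ASV 'A', sample 'S1'")
  m3 <- m; m3[2, 2] <- 1.5
  expect_error(asv_table(m3), "ASV 'B', sample 'S2'")
  m4 <- m; rownames(m4) <- c("A", "A")
  expect_error(asv_table(m4), "duplicate")
})

test_that("TSV read-back reproduces counts and column sums", {
  m <- matrix(c(5L, 0L, 1L, 2L, 0L, 7L), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("ASV", 1:3), c("S1", "S2")))
  tab <- asv_table(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_asv_table(tab, path)
  back <- read_asv_table(path)
  expect_identical(unclass(back), unclass(tab))
  expect_equal(unname(colSums(back)), c(6, 9))
  expect_match(readLines(path, 1), "^#ASV_ID\t")
})

test_that("round trips are identity for both dialects", {
  tab <- toy_table()
  for (dialect in c("tsv", "biom-json")) {
    path <- withr::local_tempfile()
    write_asv_table(tab, path, dialect = dialect)
    back <- read_asv_table(path, dialect = dialect)
    expect_identical(unclass(back)[rownames(tab), colnames(tab)],
                     unclass(tab), info = dialect)
  }
})

test_that("malformed table files are rejected with informative errors", {
  empty <- withr::local_tempfile()
  file.create(empty)
  expect_error(read_asv_table(empty), "empty")
  bad <- withr::local_tempfile()
  writeLines(c("#ASV_ID\tS1\tS2", "ASV1\t3\tx"), bad)
  expect_error(read_asv_table(bad), "non-numeric")
  dup <- withr::local_tempfile()
  writeLines(c("#ASV_ID\tS1", "ASV1\t3", "ASV1\t4"), dup)
  expect_error(read_asv_table(dup), "duplicate")
  expect_error(read_asv_table(withr::local_tempfile()), "not found")
})

test_that("lineage exclusion drops organelles and domain-unassigned ASVs", {
  m <- matrix(10L, 5, 2,
              dimnames = list(paste0("ASV", 1:5), c("S1", "S2")))
  tab <- asv_table(m)
  tax <- toy_taxonomy()
  out <- exclude_lineages(tab, tax)
  # ASV3 is chloroplast, ASV5 is unassigned at domain
  expect_identical(rownames(out), c("ASV1", "ASV2", "ASV4"))
  # terms matching nothing: identity
  expect_identical(rownames(exclude_lineages(tab, tax, terms = "archaea")),
                   rownames(tab))
  # idempotence
  expect_identical(unclass(exclude_lineages(out, tax)), unclass(out))
  # ASV missing from the taxonomy counts as unknown
  tax2 <- tax[tax$asv_id != "ASV1", ]
  expect_false("ASV1" %in% rownames(exclude_lineages(tab, tax2)))
  expect_true("ASV1" %in%
                rownames(exclude_lineages(tab, tax2, terms = "chloroplast")))
})

test_that("rarefaction conserves depth, never exceeds input, is seeded", {
  tab <- toy_table()
  r <- rarefy_table(tab, depth = 50, seed = 1)
  expect_true(all(colSums(r) == 50))
  expect_true(all(unclass(r) <= unclass(tab)))
  expect_identical(unclass(rarefy_table(tab, depth = 50, seed = 1)),
                   unclass(r))
  expect_false(identical(unclass(rarefy_table(tab, depth = 50, seed = 2)),
                         unclass(r)))
  # depth equal to a sample total leaves that sample untouched
  full <- rarefy_table(tab, depth = min(colSums(tab)), seed = 3)
  jmin <- which.min(colSums(tab))
  expect_identical(full[, jmin], tab[, jmin])
  expect_error(rarefy_table(tab, depth = 1e6, seed = 1), "exceeds")
  expect_error(rarefy_table(tab, depth = 50), "seed")
  expect_identical(attr(r, "rarefaction"), list(depth = 50L, seed = 1L))
})

test_that("mean rarefied count matches the hypergeometric expectation", {
  tab <- toy_table()
  depth <- 40
  draws <- vapply(1:300, function(s) unclass(rarefy_table(tab, depth, seed = s)),
                  matrix(0L, nrow(tab), ncol(tab)))
  avg <- apply(draws, c(1, 2), mean)
  N <- matrix(colSums(tab), nrow(tab), ncol(tab), byrow = TRUE)
  expectation <- depth * unclass(tab) / N
  v <- depth * (unclass(tab) / N) * (1 - unclass(tab) / N) * (N - depth) / (N - 1)
  se <- sqrt(v / 300)
  expect_true(all(abs(avg - expectation) <= 3 * se + 1e-9))
})

test_that("relative abundance normalises every sample to 1", {
  tab <- toy_table()
  p <- relative_abundance(tab)
  expect_equal(unname(colSums(p)), rep(1, ncol(tab)), tolerance = 1e-12)
  expect_equal(unname(p[, 1]), c(50, 5, 0, 45) / 100)
  zero <- asv_table(matrix(c(1L, 0L), 1, 2,
                           dimnames = list("A", c("S1", "S2"))))
  expect_error(relative_abundance(zero), "zero total")
})

test_that("rank aggregation sums proportions and preserves column sums", {
  m <- matrix(c(10L, 20L, 30L, 40L, 60L, 40L), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("ASV", c(1, 2, 4)), c("S1", "S2")))
  tab <- asv_table(m)
  tax <- toy_taxonomy()
  phy <- aggregate_rank(tab, tax, "phylum")
  expect_equal(phy["Proteobacteria", ],
               c(S1 = (10 + 60) / 100, S2 = (20 + 40) / 100))
  expect_equal(unname(colSums(phy)), c(1, 1), tolerance = 1e-12)
  # unassigned pooling: ASV4 has empty genus
  gen <- aggregate_rank(tab, tax, "genus")
  expect_equal(unname(gen["unassigned", ]), unname(phy["Proteobacteria", ] -
                 relative_abundance(tab)["ASV1", ]))
  expect_true(rownames(gen)[nrow(gen)] == "unassigned")
  expect_error(aggregate_rank(tab, tax, "kingdom"), "unknown rank")
})

test_that("sub-community split partitions ASVs and is a fixed point", {
  tab <- toy_table()
  p <- relative_abundance(tab)
  asg <- classify_asvs(p)
  parts <- split_subcommunities(tab, asg)
  expect_setequal(unlist(lapply(parts, rownames)), rownames(tab))
  expect_identical(sum(vapply(parts, nrow, integer(1))), nrow(tab))
  for (g in names(parts)) {
    if (nrow(parts[[g]]) > 0) {
      again <- split_subcommunities(parts[[g]], asg)
      expect_identical(unclass(again[[g]]), unclass(parts[[g]]))
      others <- setdiff(names(parts), g)
      expect_true(all(vapply(again[others], nrow, integer(1)) == 0L))
    }
  }
  expect_error(split_subcommunities(tab, asg[-1, ]), "missing")
})

test_that("metadata round trip keeps units and numeric columns", {
  meta <- data.frame(sample_id = c("S1", "S2"), TN = c(0.6, 0.55),
                     TP = c(0.03, NA), stringsAsFactors = FALSE)
  attr(meta, "units") <- c(TN = "mg/L", TP = "mg/L")
  path <- withr::local_tempfile()
  write_metadata(meta, path)
  back <- read_metadata(path)
  expect_equal(back$TN, meta$TN)
  expect_true(is.na(back$TP[2]))
  expect_identical(unname(attr(back, "units")["TN"]), "mg/L")
})
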