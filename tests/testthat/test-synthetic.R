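test_that("largest-remainder allocation is exact and deterministic", {
  expect_equal(unname(largest_remainder(c(TNL = 0.5, CN = 0.25, L = 0.25),
                                        20)),
               c(10L, 5L, 5L))
  expect_equal(sum(largest_remainder(c(a = 1/3, b = 1/3, c = 1/3), 10)),
               10L)
  expect_error(largest_remainder(c(a = 0.4, b = 0.4), 10), "sum to 1")
  # allocation never differs from proportions by a whole item
  set.seed(91)
  for (rep in 1:20) {
    p <- runif(4); p <- p / sum(p)
    n <- sample(1:200, 1)
    got <- largest_remainder(p, n)
    expect_equal(sum(got), n)
    expect_true(all(abs(got - p * n) < 1))
  }
})

test_that("generator plants exact class counts and valid outputs", {
  blocks <- list(species_block("Aus aus", n_genes = 20,
                               class_props = c(TNL = 0.5, CN = 0.25,
                                               L = 0.25)))
  g <- generate_proteomes(synthetic_spec(blocks, seed = 7))
  expect_equal(unname(table(g$truth$class)[c("TNL", "CN", "L")]),
               c(10L, 5L, 5L), ignore_attr = TRUE)
  # hits carry exactly the planted role accessions (no decoys configured)
  roles <- default_role_map()
  for (i in seq_len(nrow(g$truth))) {
    planted <- strsplit(g$truth$roles[i], ",")[[1]]
    accs <- g$annotations$hits$interpro_id[
      g$annotations$hits$protein_id == g$truth$protein_id[i]]
    expect_setequal(accs, unlist(roles[planted], use.names = FALSE))
  }
  # coordinates are 0-based half-open within the chromosome
  expect_true(all(g$coordinates$start >= 0))
  expect_true(all(g$coordinates$start < g$coordinates$end))

  # n = 0 gives four empty outputs
  empty <- generate_proteomes(synthetic_spec(list(), seed = 1))
  expect_equal(nrow(empty$annotations$proteins), 0L)
  expect_equal(length(empty$sequences), 0L)
  expect_equal(nrow(empty$coordinates), 0L)
  expect_equal(nrow(empty$truth), 0L)
})

test_that("generation is fully deterministic under a fixed seed", {
  spec <- emulate_survey_shape("fabaceae9", factor = 0.02, seed = 99)
  g1 <- generate_proteomes(spec)
  g2 <- generate_proteomes(spec)
  expect_identical(g1, g2)
  # and the written artifacts are byte-identical
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_table(g1$truth, f1)
  write_table(g2$truth, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the sequences
  g3 <- generate_proteomes(emulate_survey_shape("fabaceae9", factor = 0.02,
                                               seed = 100))
  expect_false(identical(g1$sequences, g3$sequences))
})

test_that("generator validates its spec", {
  expect_error(species_block("A a", 10, class_props = c(TNL = 0.7)),
               "sum to 1")
  expect_error(species_block("A a", 10, class_props = c(BOGUS = 1)),
               "unknown class")
  expect_error(species_block("A a", 10, n_proteins = 5), "n_proteins")
  expect_silent(synthetic_spec(list(species_block("A a", 5)), seed = 1))
  expect_error(
    synthetic_spec(list(species_block("A a", 5,
                                      decoy_pool = "IPR002182")),
                   seed = 1),
    "overlaps role accessions")
  expect_error(synthetic_spec(list(species_block("A a", 5))),
               "seed is mandatory")
})

test_that("the nine-species preset mirrors the published totals", {
  spec1 <- emulate_survey_shape("fabaceae9", factor = 1, seed = 5)
  n_prot <- vapply(spec1$blocks, `[[`, integer(1), "n_proteins")
  n_gene <- vapply(spec1$blocks, `[[`, integer(1), "n_genes")
  expect_equal(sum(n_prot), 9038L)
  expect_equal(sum(n_gene), 7829L)

  # scaled by 0.1 the totals stay within per-species rounding error
  spec01 <- emulate_survey_shape("fabaceae9", factor = 0.1, seed = 5)
  tot <- sum(vapply(spec01$blocks, `[[`, integer(1), "n_proteins"))
  expect_lte(abs(tot - 903.8), 9)

  expect_error(emulate_survey_shape("poaceae"), "unknown preset")
  expect_error(emulate_survey_shape("fabaceae9", factor = 1),
               "seed is mandatory")
})

test_that("classifier recovers planted labels over random specs", {
  set.seed(92)
  decoys <- sprintf("IPR7%05d", 1:20)
  for (rep in 1:10) {
    labels <- sample(setdiff(CLASS_LABELS, "UNCLASSIFIED"),
                     sample(2:5, 1))
    p <- runif(length(labels)); p <- p / sum(p)
    blocks <- list(species_block("Aus aus", n_genes = sample(10:40, 1),
                                 class_props = stats::setNames(p, labels),
                                 decoy_pool = decoys, decoy_prob = 0.3))
    g <- generate_proteomes(synthetic_spec(blocks, seed = sample(1e6, 1)))
    cl <- classify_all(g$annotations)
    m <- merge(cl[, c("protein_id", "class")],
               g$truth[, c("protein_id", "class")], by = "protein_id")
    expect_equal(m$class.x, m$class.y)
  }
})
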