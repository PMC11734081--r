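test_that("presence flags reflect role hits exactly", {
  tab <- make_annotation(list(
    a = c("IPR002182", "IPR001611"),                      # N + L1
    b = character(),                                      # nothing
    c = c("IPR002182", "IPR001611", "IPR011713",          # every role
          "IPR013210", "IPR025875", "IPR041118", "IPR000157")
  ))
  f <- derive_flags(tab)
  fa <- f[f$protein_id == "a", ]
  expect_true(fa$has_N && fa$L1 && !fa$L2 && !fa$has_C && !fa$has_T)
  fb <- f[f$protein_id == "b", ]
  expect_false(any(unlist(fb[, c("has_N", "has_C", "has_T",
                                 "L1", "L2", "L3", "L4")])))
  fc <- f[f$protein_id == "c", ]
  expect_true(all(unlist(fc[, c("has_N", "has_C", "has_T",
                                "L1", "L2", "L3", "L4", "has_L")])))
})

test_that("classify matches the exhaustive truth-table oracle", {
  # every combination of N, C, T and the 16 L-subtype subsets
  grid <- expand.grid(has_N = c(FALSE, TRUE), has_C = c(FALSE, TRUE),
                      has_T = c(FALSE, TRUE), L1 = c(FALSE, TRUE),
                      L2 = c(FALSE, TRUE), L3 = c(FALSE, TRUE),
                      L4 = c(FALSE, TRUE))
  grid$has_L <- grid$L1 | grid$L2 | grid$L3 | grid$L4
  got <- classify(grid)
  want <- mapply(classify_oracle, grid$has_N, grid$has_L, grid$has_C,
                 grid$has_T)
  expect_equal(got$class, unname(want))
  expect_true(all(got$class %in% CLASS_LABELS))
  # ambiguity flagged exactly when C and T are both present
  expect_equal(got$ambiguous, grid$has_C & grid$has_T)
  # worked classes: (T,N,L) -> TNL; (N,C) -> CN
  expect_equal(classify(c(has_N = TRUE, has_L = TRUE, has_C = FALSE,
                          has_T = TRUE))$class, "TNL")
  expect_equal(classify(c(has_N = TRUE, has_L = FALSE, has_C = TRUE,
                          has_T = FALSE))$class, "CN")
})

test_that("classify is a pure function of the flags", {
  set.seed(31)
  flags <- data.frame(has_N = sample(c(TRUE, FALSE), 200, TRUE),
                      has_L = sample(c(TRUE, FALSE), 200, TRUE),
                      has_C = sample(c(TRUE, FALSE), 200, TRUE),
                      has_T = sample(c(TRUE, FALSE), 200, TRUE))
  expect_identical(classify(flags), classify(flags))
  key <- paste(flags$has_N, flags$has_L, flags$has_C, flags$has_T)
  lab <- classify(flags)$class
  expect_true(all(tapply(lab, key, function(v) length(unique(v)) == 1)))
})

test_that("classify_all recovers planted counts and partitions the input", {
  blocks <- list(species_block("Aus aus", n_genes = 20,
                               class_props = c(TNL = 0.5, CN = 0.25, L = 0.25)))
  g <- generate_proteomes(synthetic_spec(blocks, seed = 7))
  cl <- classify_all(g$annotations)
  expect_equal(sum(cl$class == "TNL"), 10L)
  expect_equal(sum(cl$class == "CN"), 5L)
  expect_equal(sum(cl$class == "L"), 5L)
  # partition: every protein exactly once; label sums = candidate count
  expect_equal(nrow(cl), nrow(g$annotations$proteins))
  expect_equal(anyDuplicated(cl$protein_id), 0L)
  counts <- class_counts(cl)
  per <- counts[counts$species != "Total", CLASS_LABELS]
  expect_equal(sum(per), nrow(cl))

  empty <- make_annotation(stats::setNames(list(), character()))
  expect_equal(nrow(classify_all(empty)), 0L)

  expect_match(attr(cl, "role_map_hash"), "^[0-9a-f]{32}$")
})

test_that("audit flags the published discordant architectures", {
  # E3WF10: asserted CN but carries only the coiled-coil domain
  # Q9FKN7: asserted NL but carries TIR + NB-ARC + an LRR -> derived TNL
  tab <- make_annotation(list(
    E3WF10 = "IPR041118",
    Q9FKN7 = c("IPR000157", "IPR002182", "IPR001611"),
    P00001 = "IPR002182",
    K00001 = "IPR000719"
  ))
  classes <- classify_all(tab)
  ref <- data.frame(
    accession = c("E3WF10", "Q9FKN7", "P00001", "P99999", "K00001"),
    asserted_class = c("CN", "NL", "N", "N", "LYK"),
    stringsAsFactors = FALSE)
  got <- audit_classes(ref, classes)

  e <- got[got$accession == "E3WF10", ]
  expect_false(e$concordant)
  expect_equal(e$derived_class, "UNCLASSIFIED")  # C alone defines no class
  expect_match(e$note, "missing role\\(s\\): N")

  q <- got[got$accession == "Q9FKN7", ]
  expect_false(q$concordant)
  expect_equal(q$derived_class, "TNL")

  expect_true(got$concordant[got$accession == "P00001"])
  expect_match(got$note[got$accession == "P99999"], "unscored")
  expect_match(got$note[got$accession == "K00001"], "not auditable")

  expect_error(audit_classes(data.frame(accession = "x",
                                        asserted_class = "BOGUS"),
                             classes),
               "vocabulary")
})
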