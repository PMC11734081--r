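test_that("candidates are exactly the proteins with a tracked-role hit", {
  tab <- make_annotation(list(
    a = "IPR013210",            # L3 alone is enough
    b = c("IPR000001", "IPR041118"),  # decoy + coiled-coil: not tracked
    c = "IPR002182",
    d = character()
  ))
  got <- select_candidates(tab)
  expect_setequal(got$proteins$protein_id, c("a", "c"))

  # brute-force scan oracle on a random table
  set.seed(21)
  tab2 <- random_annotation(30)
  tracked <- unlist(default_role_map()[c("N", "L1", "L2", "L3", "L4")])
  oracle <- unique(tab2$hits$protein_id[tab2$hits$interpro_id %in% tracked])
  expect_setequal(select_candidates(tab2)$proteins$protein_id, oracle)
})

test_that("selection is a subset and monotone under added hits", {
  set.seed(22)
  for (rep in 1:5) {
    tab <- random_annotation(25)
    sel <- select_candidates(tab)
    expect_true(all(sel$proteins$protein_id %in% tab$proteins$protein_id))
    # add an NB-ARC hit to a random protein: no candidate may disappear
    extra <- tab$proteins$protein_id[sample(nrow(tab$proteins), 1)]
    tab2 <- annotation_table(tab$proteins, rbind(
      tab$hits,
      data.frame(protein_id = extra, interpro_id = "IPR002182",
                 signature_id = "PF00931", start = 1L, end = 9L,
                 score = NA_real_)))
    sel2 <- select_candidates(tab2)
    expect_true(all(sel$proteins$protein_id %in% sel2$proteins$protein_id))
  }
})

test_that("deduplication keeps one protein per distinct sequence per species", {
  seqs <- c(a = "MKVLLA", b = "MKVLLA", c = "MDDEY")
  tab <- make_annotation(list(a = "IPR002182", b = "IPR002182",
                              c = "IPR002182"), sequences = seqs)
  got <- deduplicate_candidates(tab)
  expect_setequal(got$proteins$protein_id, c("a", "c"))  # survivor = smallest id

  # distinct sequences: identity
  tab2 <- make_annotation(list(a = "IPR002182", c = "IPR002182"),
                          sequences = c(a = "MKV", c = "MDD"))
  expect_setequal(deduplicate_candidates(tab2)$proteins$protein_id,
                  c("a", "c"))

  # idempotence
  again <- deduplicate_candidates(got)
  expect_equal(sort(again$proteins$protein_id),
               sort(got$proteins$protein_id))

  # same sequence in different species is never collapsed
  p <- rbind(
    data.frame(protein_id = "x1", species = "Aus aus", gene_id = "g1",
               sequence = "MKV", stringsAsFactors = FALSE),
    data.frame(protein_id = "x2", species = "Bus bus", gene_id = "g2",
               sequence = "MKV", stringsAsFactors = FALSE))
  tab3 <- annotation_table(p, data.frame(
    protein_id = character(), interpro_id = character(),
    signature_id = character(), start = integer(), end = integer()))
  expect_equal(nrow(deduplicate_candidates(tab3)$proteins), 2L)
})

test_that("count summary separates proteins from genes and conserves totals", {
  # 5 genes x 2 transcripts each -> 5 genes, 10 proteins
  genes <- rep(sprintf("g%d", 1:5), each = 2)
  ids <- sprintf("p%02d", 1:10)
  hits <- stats::setNames(rep(list("IPR002182"), 10), ids)
  tab <- make_annotation(hits, gene_ids = stats::setNames(genes, ids))
  s <- summarize_counts(tab)
  expect_equal(s$n_genes[s$species != "Total"], 5L)
  expect_equal(s$n_proteins[s$species != "Total"], 10L)

  # empty input -> all-zero summary
  empty <- make_annotation(stats::setNames(list(), character()))
  s0 <- summarize_counts(empty)
  expect_equal(s0$n_proteins[s0$species == "Total"], 0L)

  # totals row equals the sum of per-species rows
  multi <- bind_annotations(
    random_annotation(12, "Aus aus"),
    random_annotation(7, "Bus bus"))
  sm <- summarize_counts(multi)
  per <- sm[sm$species != "Total", ]
  expect_equal(sm$n_proteins[sm$species == "Total"], sum(per$n_proteins))
  expect_equal(sm$n_genes[sm$species == "Total"], sum(per$n_genes))

  # missing gene_id goes to a sentinel bucket with a warning
  p <- data.frame(protein_id = c("p1", "p2"), species = "Aus aus",
                  gene_id = c("", "g1"), stringsAsFactors = FALSE)
  tab2 <- annotation_table(p, data.frame(
    protein_id = character(), interpro_id = character(),
    signature_id = character(), start = integer(), end = integer()))
  expect_warning(s2 <- summarize_counts(tab2), "no_gene")
  expect_equal(s2$n_genes[s2$species != "Total"], 2L)
})
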