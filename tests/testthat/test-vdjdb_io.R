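test_that("reading round-trips a toy table and rejects bad rows into the error list", {
  rec <- toy_records(3, cdr3 = c("CASSL", "CASRG", "CASKD"))
  path <- write_toy_tsv(rec)
  out <- read_vdjdb_table(path)
  expect_equal(nrow(out$records), 3)
  expect_equal(out$records$cdr3, rec$cdr3)
  expect_equal(out$records$v_gene, rec$v_gene)
  expect_equal(out$records$confidence_score, rec$confidence_score)
  expect_equal(nrow(out$errors), 0)

  # header-only table
  empty <- read_vdjdb_table(write_toy_tsv(toy_records(0)))
  expect_equal(nrow(empty$records), 0)

  # unparseable score: row diverted, remaining rows parsed
  raw <- readLines(path)
  raw[3] <- sub("\t2$", "\tx", raw[3])
  path2 <- tempfile(fileext = ".tsv")
  writeLines(raw, path2)
  out2 <- read_vdjdb_table(path2)
  expect_equal(nrow(out2$records), 2)
  expect_equal(out2$errors$row, 2L)
  expect_match(out2$errors$reason, "confidence score")
})

test_that("missing mandatory columns raise a configuration error naming the column", {
  rec <- toy_records(2)
  path <- write_toy_tsv(rec)
  tab <- read.delim(path, sep = "\t", check.names = FALSE)
  tab[["v.segm"]] <- NULL
  path2 <- tempfile(fileext = ".tsv")
  write.table(tab, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_vdjdb_table(path2), "v_gene")
})

test_that("filter cascade applies each step in order with per-step accounting", {
  clean <- toy_records(4, cdr3 = c("CASSA", "CASSL", "CASSC", "CASSD"))
  score0 <- toy_records(1, cdr3 = "CASSE", score = 0L)
  tra <- toy_records(1, cdr3 = "CASSF", chain = "TRA")
  wrong_host <- toy_records(1, cdr3 = "CASSG", host_species = "MacacaMulatta")
  denied <- toy_records(1, cdr3 = "CASSH", epitope_species = "HomoSapiens")
  dup <- clean[c(1, 1), ]
  all <- rbind(clean, score0, tra, wrong_host, denied, dup[2, , drop = FALSE])
  all$record_id <- seq_len(nrow(all))

  res <- apply_filters(all)
  rep <- res$report
  expect_equal(rep$step,
               c("raw", "remove_missing", "host_species", "confidence_score",
                 "epitope_species_denylist", "deduplicate", "trb_chain"))
  expect_equal(rep$remaining,
               c(9L, 9L, 8L, 7L, 6L, 5L, 4L))
  expect_setequal(res$records$cdr3, clean$cdr3)

  # the score-0 record dies exactly at the score step
  solo <- apply_filters(score0)
  expect_equal(solo$report$remaining[solo$report$step == "host_species"], 1L)
  expect_equal(solo$report$remaining[solo$report$step == "confidence_score"], 0L)

  # a TRA record passing all earlier steps dies at the chain step
  solo_tra <- apply_filters(tra)
  expect_equal(solo_tra$report$remaining[solo_tra$report$step == "deduplicate"], 1L)
  expect_equal(solo_tra$report$remaining[solo_tra$report$step == "trb_chain"], 0L)

  # empty input: every step reports 0
  none <- apply_filters(toy_records(0))
  expect_equal(none$report$remaining, rep(0L, 7))
})

test_that("filter report counts are monotone non-increasing for random contaminated inputs", {
  for (seed in 1:5) {
    cfg <- synthetic_config(num_classes = 3, class_sizes = 40,
                            contamination = list(tra = 0.1, duplicate = 0.1,
                                                 score0 = 0.2),
                            score_probs = c(0.1, 0.4, 0.3, 0.2), seed = seed)
    tab <- generate(cfg)
    path <- tempfile(fileext = ".tsv")
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    rep <- apply_filters(read_vdjdb_table(path)$records)$report
    expect_true(all(diff(rep$remaining) <= 0))
  }
})

test_that("deduplication keeps the first occurrence on the full key and is idempotent", {
  a <- toy_records(2, cdr3 = "CASSL")           # identical full key
  b <- toy_records(1, cdr3 = "CASSL", v_gene = "TRBV7")  # differs in V
  rec <- rbind(a, b)
  rec$record_id <- 1:3
  out <- deduplicate(rec)
  expect_equal(out$record_id, c(1L, 3L))
  expect_identical(deduplicate(out), out)
  expect_equal(nrow(deduplicate(toy_records(0))), 0)
})

test_that("class labels are the space-joined epitope triple", {
  rec <- toy_records(2, epitope_species = "MCMV", epitope_gene = "m139",
                     epitope_seq = "TVYGFCLL")
  out <- assign_class_labels(rec)
  expect_equal(unique(out$records$class_label), "MCMV m139 TVYGFCLL")

  rec2 <- toy_records(1, epitope_species = "X", epitope_gene = "Y",
                      epitope_seq = "Z")
  # invalid epitope_seq letters are caught at read time, not here; the label
  # is a plain join
  expect_equal(assign_class_labels(rec2)$records$class_label, "X Y Z")

  bad <- toy_records(1)
  bad$epitope_gene <- ""
  res <- assign_class_labels(rbind(rec[1, ], bad))
  expect_equal(nrow(res$records), 1)
  expect_equal(nrow(res$errors), 1)
})

test_that("minimum class size bound is inclusive", {
  big <- toy_records(50, epitope_gene = "A")
  small <- toy_records(49, epitope_gene = "B")
  rec <- rbind(big, small)
  rec$record_id <- seq_len(nrow(rec))
  lab <- assign_class_labels(rec)$records
  kept <- min_class_size_filter(lab, min_n = 50)
  expect_setequal(unique(kept$epitope_gene), "A")
  expect_equal(nrow(min_class_size_filter(lab, min_n = 1)), nrow(lab))
})

test_that("difficulty categorization puts the 100-count boundary in 'hard'", {
  counts <- c(a = 101L, b = 100L, c = 99L)
  expect_equal(unname(categorize_difficulty(counts)),
               c("easy", "hard", "hard"))
})

test_that("stratified split obeys the per-class floor rule and is seeded", {
  rec <- rbind(
    assign_class_labels(toy_records(10, epitope_gene = "A"))$records,
    assign_class_labels(toy_records(20, epitope_gene = "B"))$records
  )
  rec$record_id <- seq_len(nrow(rec))
  sp <- stratified_split(rec, seed = 3)
  tab <- table(sp$partition$class_label, sp$partition$partition)
  expect_equal(unname(tab["InfluenzaA A GILGFVFTL", c("train", "validation", "test")]),
               c(7L, 1L, 2L))
  expect_equal(unname(tab["InfluenzaA B GILGFVFTL", c("train", "validation", "test")]),
               c(14L, 3L, 3L))

  # disjoint and exhaustive
  expect_equal(sort(sp$partition$record_id), rec$record_id)
  expect_true(all(sp$partition$partition %in% c("train", "validation", "test")))

  # determinism
  sp2 <- stratified_split(rec, seed = 3)
  expect_identical(sp$partition, sp2$partition)
  sp3 <- stratified_split(rec, seed = 4)
  expect_false(identical(sp$partition$partition, sp3$partition$partition))

  # class too small to split
  tiny <- assign_class_labels(toy_records(2, epitope_gene = "C"))$records
  tiny$record_id <- 1:2
  expect_error(stratified_split(tiny), "fewer than 3")
})

test_that("partition-size arithmetic matches the floor rule", {
  expect_equal(unname(partition_sizes(10)), c(7, 1, 2))
  expect_equal(unname(partition_sizes(20)), c(14, 3, 3))
  expect_equal(sum(partition_sizes(2674)), 2674)
})

test_that("gene vocabulary is a sorted bijection with table size n + 2", {
  vocab <- build_gene_vocabulary(c("TRBV9", "TRBV2", "TRBV9", "TRBV11"))
  expect_equal(vocab$names, sort(unique(c("TRBV9", "TRBV2", "TRBV11"))))
  expect_equal(unname(vocab$index_of[vocab$names]), 1:3)
  expect_equal(vocab$padding_index, 0L)
  expect_equal(vocab$special_index, 4L)
  expect_equal(vocab$table_size, 5L)

  one <- build_gene_vocabulary("TRBV1")
  expect_equal(one$table_size, 3L)

  # encode/decode identity on the vocabulary; unknown -> special slot
  ords <- encode_genes(vocab, vocab$names)
  expect_equal(decode_genes(vocab, ords), vocab$names)
  expect_equal(encode_genes(vocab, "TRBV999"), vocab$special_index)
})

test_that("63 V names and 13 J names give table sizes 65 and 15", {
  cfg <- synthetic_config(num_classes = 5, class_sizes = 400,
                          gene_signal = "none", seed = 2)
  tab <- generate(cfg)
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_vdjdb_table(path)$records
  expect_equal(build_gene_vocabulary(rec, "v_gene")$table_size, 65L)
  expect_equal(build_gene_vocabulary(rec, "j_gene")$table_size, 15L)
})

test_that("a clean generator dataset passes the whole cascade untouched", {
  cfg <- synthetic_config(num_classes = 3, class_sizes = 60, seed = 5)
  tab <- generate(cfg)
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- apply_filters(read_vdjdb_table(path)$records)
  expect_equal(res$report$remaining[1],
               res$report$remaining[nrow(res$report)])
  expect_equal(nrow(res$records), 180)
})

test_that("json artifacts serialize without error", {
  rec <- assign_class_labels(toy_records(10))$records
  rec$record_id <- 1:10
  sp <- stratified_split(rec, seed = 1)
  vocab <- build_gene_vocabulary(rec, "v_gene")
  rep <- apply_filters(rec)$report
  for (x in list(sp, vocab, rep)) {
    path <- tempfile(fileext = ".json")
    write_json_artifact(x, path)
    expect_true(file.exists(path))
    expect_silent(jsonlite::read_json(path))
  }
})
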