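test_that("read_fasta parses records in order and upper-cases", {
  tf <- write_tmp_fasta(c(">p1", "ACDE", ">p2", "www"))
  out <- read_fasta(tf)
  expect_equal(out$id, c("p1", "p2"))
  expect_equal(nchar(out$sequence), c(4L, 3L))
  expect_equal(out$sequence[2], "WWW")
})

test_that("read_fasta handles wrapping, empty files and malformed input", {
  tf <- write_tmp_fasta(c(">p1", "ACDEFG", "HIKL", "", ">p2", "MNP"))
  out <- read_fasta(tf)
  expect_equal(out$sequence[1], "ACDEFGHIKL")

  empty <- write_tmp_fasta(character())
  expect_equal(nrow(read_fasta(empty)), 0L)

  headerless <- write_tmp_fasta(c("ACDE", ">p1", "AC"))
  expect_error(read_fasta(headerless), "line 1")

  bodyless <- write_tmp_fasta(c(">p1", ">p2", "ACDE"))
  expect_error(read_fasta(bodyless), "empty record 'p1'")
})

test_that("non-canonical residues error in strict mode, drop in lenient", {
  tf <- write_tmp_fasta(c(">ok", "ACDE", ">bad", "ABDE"))
  expect_error(read_fasta(tf), "bad")
  expect_warning(out <- read_fasta(tf, strict = FALSE), "dropping 1")
  expect_equal(out$id, "ok")
})

test_that("FASTA write/read round-trips id and sequence", {
  set.seed(7)
  data <- tibble::tibble(
    id = sprintf("pep%02d", 1:8),
    sequence = random_peptides(8, min_len = 3, max_len = 130, seed = 7)
  )
  tf <- tempfile(fileext = ".fasta")
  write_fasta(data, tf, wrap = 60)
  # wrapped lines must not exceed 60 columns
  expect_true(all(nchar(readLines(tf)) <= 61))
  back <- read_fasta(tf)
  expect_equal(back$id, data$id)
  expect_equal(back$sequence, data$sequence)
})

test_that("make_labeled_dataset counts, labels and id collisions", {
  pos <- tibble::tibble(id = c("a", "b", "c"),
                        sequence = c("ACD", "WWW", "KLM"))
  neg <- tibble::tibble(id = c("a", "d"), sequence = c("EEE", "PPP"))
  ds <- make_labeled_dataset(pos, neg, "demo")
  expect_equal(nrow(ds), 5L)
  expect_equal(sum(ds$label), 3L)
  expect_false(anyDuplicated(ds$id) > 0)

  none <- tibble::tibble(id = character(), sequence = character())
  ds2 <- make_labeled_dataset(none, neg)
  expect_equal(sum(ds2$label), 0L)
  expect_error(make_labeled_dataset(none, none), "empty")
})

test_that("label tables attach to peptides", {
  ds <- tiny_dataset()
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(ds[, c("id", "label")], tf, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  lab <- read_label_table(tf)
  out <- attach_labels(ds[, c("id", "sequence")], lab)
  expect_equal(out$label, ds$label)
  expect_error(attach_labels(tibble::tibble(id = "zz", sequence = "AC"), lab),
               "no label")
})

test_that("truncate_n_terminus takes prefixes and is idempotent", {
  ds <- tibble::tibble(id = c("a", "b"),
                       sequence = c(strrep("ACDEW", 8), "ACDEFGHIKL"),
                       label = c(1L, 0L))
  out <- truncate_n_terminus(ds, 15)
  expect_equal(nchar(out$sequence), c(15L, 10L))
  expect_equal(out$sequence[1], substr(ds$sequence[1], 1, 15))
  expect_identical(truncate_n_terminus(out, 15), out)
  one <- truncate_n_terminus(ds, 1)
  expect_equal(one$sequence, substr(ds$sequence, 1, 1))
})

test_that("stratified_split preserves class proportions and partitions", {
  set.seed(3)
  big <- tibble::tibble(
    id = sprintf("x%03d", 1:212),
    sequence = random_peptides(212, seed = 3),
    label = c(rep(1L, 105), rep(0L, 107))
  )
  sp <- stratified_split(big, fraction = 0.8, seed = 5)
  # test gets floor(0.2 * class size) per class: 21 + 21
  expect_equal(nrow(sp$dev), 170L)
  expect_equal(nrow(sp$test), 42L)
  expect_equal(sum(sp$test$label), 21L)
  # partition: no loss, no duplication
  expect_setequal(c(sp$dev$id, sp$test$id), big$id)
  expect_length(intersect(sp$dev$id, sp$test$id), 0L)
  # determinism
  sp2 <- stratified_split(big, fraction = 0.8, seed = 5)
  expect_identical(sp$dev$id, sp2$dev$id)

  ten <- big[c(1:10, 106:115), ]
  half <- stratified_split(ten, fraction = 0.5, seed = 1)
  expect_equal(nrow(half$dev), 10L)
  expect_equal(sum(half$dev$label), 5L)

  expect_error(stratified_split(big[c(1, 106:110), ], 0.8, 1), "at least 2")
})
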