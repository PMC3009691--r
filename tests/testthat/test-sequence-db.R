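test_that("flat-file parsing extracts EC tokens from DE lines", {
  lines <- c(
    flat_entry("A00001", "RecName: Full=Alcohol dehydrogenase (EC 1.1.1.1).",
               strrep("ACDEFGHIKL", 12)),
    flat_entry("A00002", "Full=Bifunctional thing (EC 1.2.3.4) (EC 2.2.27.-).",
               strrep("MKVLATTGHE", 15)),
    flat_entry("A00003", "RecName: Full=Something plain.",
               strrep("WYVRNDCEQG", 11)))
  recs <- read_flatfile(text = lines)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$ec[[1]], "1.1.1.1")
  expect_equal(recs$ec[[2]], c("1.2.3.4", "2.2.27.-"))
  expect_equal(recs$ec[[3]], character(0))
  expect_equal(nchar(recs$sequence[1]), 120L)
})

test_that("EC= token dialect and duplicate tokens are handled", {
  lines <- flat_entry("B00001", "EC=1.1.1.1; Flags: stuff (EC 1.1.1.1)",
                      strrep("ACDEFGHIKL", 10))
  recs <- read_flatfile(text = lines)
  expect_equal(recs$ec[[1]], "1.1.1.1")
})

test_that("malformed entries are skipped with a warning, not a crash", {
  lines <- c("DE   orphan description", "//",
             flat_entry("C00001", "Full=Fine (EC 3.1.1.3).",
                        strrep("ACDEFGHIKL", 20)))
  expect_warning(recs <- read_flatfile(text = lines), "malformed")
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$id, "C00001")
})

test_that("classification routes on keywords, EC presence and length", {
  mk <- function(ec, len, desc = "") {
    classify_records(make_record("X", strrep("A", len), ec = ec,
                                 description = desc))$group
  }
  expect_equal(mk("1.1.1.1", 350), "ENZYME")
  expect_equal(mk(character(0), 200, "hypothetical protein"), "PUTATIVE")
  expect_equal(mk(character(0), 200), "NON_ENZYME")
  # EC-bearing entries outside the length window are neutral evidence
  expect_equal(mk("1.1.1.1", 80), "PUTATIVE")
  expect_equal(mk("1.1.1.1", 7500), "PUTATIVE")
  # length bounds are inclusive
  expect_equal(mk("1.1.1.1", 100), "ENZYME")
  expect_equal(mk("1.1.1.1", 7000), "ENZYME")
  expect_equal(mk("1.1.1.1", 99), "PUTATIVE")
  expect_equal(mk("1.1.1.1", 7001), "PUTATIVE")
  # keyword matching is case-insensitive and beats the EC route
  expect_equal(mk("1.1.1.1", 350, "Probable kinase"), "PUTATIVE")
  expect_equal(mk(character(0), 150, "FRAGMENT of something"), "PUTATIVE")
})

test_that("redundancy requires identical sequence and EC subset", {
  q <- make_record("Q", "AAAA", ec = c("1.2.3.4", "2.2.27.-"))
  r <- make_record("R", "AAAA", ec = "1.2.3.4")
  expect_true(is_redundant(q, r))
  expect_false(is_redundant(r, q))           # superset is not redundant
  r2 <- make_record("R2", "AAAA", ec = c("1.2.3.4", "2.2.27.-"))
  expect_true(is_redundant(q, r2))           # equal sets both ways
  expect_true(is_redundant(r2, q))
  expect_false(is_redundant(q, make_record("S", "AAAT", ec = "1.2.3.4")))
  expect_false(is_redundant(make_record("Q2", "AAAA", ec = "1.2.3.4"),
                            make_record("R3", "AAAA", ec = "1.2.3.5")))
  expect_error(is_redundant(q, make_record("N", "AAAA", group = "NON_ENZYME")),
               "group")
})

test_that("non-enzyme redundancy is sequence identity alone", {
  a <- make_record("A", "MKVL", group = "NON_ENZYME")
  b <- make_record("B", "MKVL", group = "NON_ENZYME")
  expect_true(is_redundant(a, b))
  dd <- deduplicate_records(make_records(a, b))
  expect_equal(nrow(dd), 1L)
})

test_that("deduplication keeps the EC-superset record and collapses chains", {
  seqs <- strrep("ACDEFGHIKL", 15)
  recs <- make_records(
    make_record("rA", seqs, ec = "1.2.3.4"),
    make_record("rB", seqs, ec = c("1.2.3.4", "2.6.1.2")),
    make_record("rC", seqs, ec = c("1.2.3.4", "2.6.1.2", "3.1.1.3")))
  dd <- deduplicate_records(recs)
  expect_equal(dd$id, "rC")
  # distinct sequences all retained
  recs2 <- make_records(
    make_record("n1", "MKVA", group = "NON_ENZYME"),
    make_record("n2", "MKVC", group = "NON_ENZYME"),
    make_record("n3", "MKVD", group = "NON_ENZYME"))
  expect_equal(nrow(deduplicate_records(recs2)), 3L)
})

test_that("EC updates transfer, chain, delete and drop emptied enzymes", {
  recs <- make_records(
    make_record("u1", strrep("A", 100), ec = "1.1.1.5"),
    make_record("u2", strrep("C", 100), ec = "1.2.3.4"),
    make_record("u3", strrep("D", 100), ec = c("1.2.3.4", "5.5.5.5")))
  upd <- list(transferred = list("1.1.1.5" = "1.1.1.303"),
              deleted = "1.2.3.4")
  out <- apply_ec_updates(recs, upd)
  expect_equal(out$ec[[which(out$id == "u1")]], "1.1.1.303")
  expect_false("u2" %in% out$id)             # EC set emptied by deletion
  expect_equal(out$ec[[which(out$id == "u3")]], "5.5.5.5")
  # identity under empty map
  none <- list(transferred = list(), deleted = character(0))
  expect_equal(apply_ec_updates(recs, none)$id, recs$id)
  # chains dereference, cycles error out
  chain <- list(transferred = list("1.1.1.1" = "1.1.1.2",
                                   "1.1.1.2" = "1.1.1.3"),
                deleted = character(0))
  r <- apply_ec_updates(make_record("c1", strrep("A", 100), ec = "1.1.1.1"),
                        chain)
  expect_equal(r$ec[[1]], "1.1.1.3")
  cyc <- list(transferred = list("1.1.1.1" = "1.1.1.2",
                                 "1.1.1.2" = "1.1.1.1"),
              deleted = character(0))
  expect_error(
    apply_ec_updates(make_record("c2", strrep("A", 100), ec = "1.1.1.1"), cyc),
    "depth")
})

test_that("EC update maps read from TSV; overlapping actions rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("old_ec\taction\tnew_ecs",
               "1.1.1.5\ttransfer\t1.1.1.303",
               "9.9.9.9\ttransfer\t1.1.1.1;2.2.2.2",
               "1.2.3.4\tdelete\t"), path)
  upd <- read_ec_updates(path)
  expect_equal(upd$transferred[["9.9.9.9"]], c("1.1.1.1", "2.2.2.2"))
  expect_equal(upd$deleted, "1.2.3.4")
  writeLines(c("old_ec\taction\tnew_ecs",
               "1.1.1.1\ttransfer\t1.1.1.2",
               "1.1.1.1\tdelete\t"), path)
  expect_error(read_ec_updates(path), "transferred and deleted")
})

test_that("group counts are invariant under input permutation", {
  set.seed(7)
  lines <- unlist(lapply(1:12, function(i) {
    de <- sample(c("Full=Enzyme (EC 1.1.1.1).", "Full=putative thing.",
                   "Full=plain protein."), 1)
    flat_entry(sprintf("P%05d", i), de, random_sequence(150))
  }))
  recs <- classify_records(read_flatfile(text = lines))
  perm <- recs[sample(nrow(recs)), ]
  expect_equal(table(classify_records(perm)$group), table(recs$group))
})

test_that("groups round-trip through the FASTA + manifest writer", {
  recs <- classify_records(make_records(
    make_record("w1", strrep("ACDEFGHIKL", 12), ec = "1.1.1.1"),
    make_record("w2", strrep("MKVLATTGHE", 12)),
    make_record("w3", strrep("WYVRNDCEQG", 12),
                description = "putative protein")))
  dir <- withr::local_tempdir()
  man <- write_groups(recs, dir)
  expect_equal(sort(man$group), sort(recs$group))
  fa <- Biostrings::readAAStringSet(file.path(dir, "enzyme.fasta"))
  expect_equal(names(fa), "w1")
  expect_equal(as.character(fa[[1]]), recs$sequence[recs$id == "w1"])
})
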