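test_that("conservation classes follow the star/colon conventions", {
  cc <- conservation_classes(c("GMG-A", "GIG-A", "GLGGA"))
  expect_equal(cc$class, c("STAR", "COLON", "STAR", "NONE", "STAR"))
  expect_equal(cc$residues[2], "ILM")        # observed set, sorted
  # gap breaks conservation even for identical residues
  expect_equal(conservation_classes(c("G-", "GG"))$class[2], "NONE")
  # residues from different strong groups are unconserved
  expect_equal(conservation_classes(c("FY", "YW", "WH"))$class, c("COLON", "NONE"))
  expect_error(conservation_classes(c("AB", "ABC")), "ragged")
  expect_error(conservation_classes("AA"))   # needs >= 2 rows
})

test_that("identical rows build an all-literal pattern", {
  msa <- c(a = "GKSTACDEFW", b = "GKSTACDEFW", c = "GKSTACDEFW")
  p <- build_pattern(msa, ec_set = "1.1.1.1")
  expect_s3_class(p, "enz_pattern")
  expect_equal(p$n_conserved, 10L)
  expect_equal(pattern_format(p), "G-K-S-T-A-C-D-E-F-W.")
})

test_that("strongly conserved columns become observed-residue classes", {
  msa <- c(a = "ACDEKRFGHIKL", b = "ACDEKRYGHIKL")
  p <- build_pattern(msa, ec_set = "1.1.1.1")
  expect_equal(pattern_format(p), "A-C-D-E-K-R-[FY]-G-H-I-K-L.")
})

test_that("too few conserved positions reject the pattern, with reason", {
  # 7 conserved columns, the 8th spoiled by a gap
  msa <- c(a = "GKSTACD-", b = "GKSTACDE")
  p <- build_pattern(msa, ec_set = "1.1.1.1", min_conserved = 8L)
  expect_true(is_rejected(p))
  expect_match(p$reason, "7 conserved")
  # exactly 8 conserved positions are kept
  msa8 <- c(a = "GKSTACDE", b = "GKSTACDE")
  expect_s3_class(build_pattern(msa8, ec_set = "1.1.1.1"), "enz_pattern")
  msa0 <- c(a = "AC", b = "CA")
  expect_match(build_pattern(msa0, ec_set = "1.1.1.1")$reason,
               "no conserved")
})

test_that("unconserved runs become x(min,max) gap elements", {
  # middle run: row a carries 3 residues, row b carries 1 (two gaps)
  msa <- c(a = "GKSTAWFWCDEFGHIK", b = "GKSTAC--CDEFGHIK")
  p <- build_pattern(msa, ec_set = "1.1.1.1")
  gap <- p$elements[p$elements$type == "GAP", ]
  expect_equal(nrow(gap), 1L)
  expect_equal(gap$min, 1L)
  expect_equal(gap$max, 3L)
  expect_match(pattern_format(p), "x\\(1,3\\)")
  # pattern is trimmed to the conserved span: no leading/trailing gaps
  expect_false(p$elements$type[1] == "GAP")
  expect_false(p$elements$type[nrow(p$elements)] == "GAP")
})

test_that("pattern text round-trips through format and parse", {
  set.seed(21)
  for (rep in 1:25) {
    p <- random_pattern()
    q <- pattern_parse(pattern_format(p))
    expect_equal(q$elements, p$elements)
    expect_equal(pattern_format(q), pattern_format(p))
  }
  # fixed-width and single wildcards
  p <- pattern_parse("G-K-[ST]-x(2,4)-A-x-C-x(3)-W.")
  expect_equal(p$elements$type,
               c("LITERAL", "LITERAL", "CLASS", "GAP", "LITERAL", "GAP",
                 "LITERAL", "GAP", "LITERAL"))
  expect_equal(pattern_format(p), "G-K-[ST]-x(2,4)-A-x-C-x(3)-W.")
  expect_error(pattern_parse("G-?-A."), "token")
})

test_that("matcher agrees with the enumeration oracle on crafted cases", {
  p <- pattern_parse("A-x-C.")
  expect_true(pattern_match(p, "TACC"))
  expect_equal(attr(pattern_match(p, "TACC"), "match")$start, 2L)
  expect_false(pattern_match(pattern_parse("G-G-G."), "GAGAG"))
  expect_true(oracle_match(p, "TACC"))
  expect_false(oracle_match(pattern_parse("G-G-G."), "GAGAG"))
  # zero-width gap
  p0 <- pattern_parse("A-x(0,2)-C.")
  expect_true(pattern_match(p0, "AC"))
  expect_true(oracle_match(p0, "AC"))
})

test_that("exact-sequence patterns are the full sequence as literals", {
  rec <- make_record("s1", random_sequence(150), ec = "1.2.3.4")
  p <- exact_sequence_pattern(rec)
  expect_equal(p$n_conserved, 150L)
  expect_true(all(p$elements$type == "LITERAL"))
  expect_true(pattern_match(p, rec$sequence))
  expect_true(self_recognition(p, rec$sequence))
  expect_equal(p$ec_set, "1.2.3.4")
})

test_that("self-recognition catches artificially narrowed gap bounds", {
  msa <- c(a = "GKSTAWFWCDEFGHIK", b = "GKSTAC--CDEFGHIK")
  p <- build_pattern(msa, ec_set = "1.1.1.1")
  seqs <- gsub("-", "", msa)
  expect_true(self_recognition(p, seqs))
  bad <- p
  gi <- which(bad$elements$type == "GAP")
  bad$elements$max[gi] <- bad$elements$min[gi]   # narrow below observed run
  expect_false(self_recognition(bad, seqs))
})

test_that("qualified nodes need the root or a strictly smaller EC set", {
  mknode <- function(id, left, right, parent, members, ec, ev = 1e-10) {
    list(node_id = id, left = left, right = right, parent = parent,
         members = members, merge_evalue = ev, ec_set = ec,
         record_id = NA_character_, pattern_id = NA_character_,
         tried = FALSE)
  }
  # root (3 ECs) -> childA (3 ECs, internal), childA -> two leaves;
  # root's other child is a leaf
  nodes <- list(
    "5" = mknode(5L, 4L, 3L, NA, c("a", "b", "c"), c("1.1.1.1", "1.1.1.2", "1.1.1.3"), 1e-5),
    "4" = mknode(4L, 1L, 2L, 5L, c("a", "b"), c("1.1.1.1", "1.1.1.2", "1.1.1.3"), 1e-8),
    "3" = mknode(3L, NA, NA, 5L, "c", "1.1.1.3"),
    "1" = mknode(1L, NA, NA, 4L, "a", "1.1.1.1"),
    "2" = mknode(2L, NA, NA, 4L, "b", "1.1.1.2"))
  tree <- list(tree_id = 1L, root = 5L, nodes = nodes,
               members = c("a", "b", "c"), singleton = FALSE)
  expect_equal(qualified_nodes(tree), 5L)   # childA has equally many ECs
  tree$nodes[["4"]]$ec_set <- c("1.1.1.1", "1.1.1.2")
  expect_equal(qualified_nodes(tree), c(5L, 4L))
  # the sequence cap excludes large nodes (boundary at 1000)
  tree$nodes[["4"]]$members <- sprintf("m%04d", 1:999)
  expect_equal(qualified_nodes(tree), c(5L, 4L))
  tree$nodes[["4"]]$members <- sprintf("m%04d", 1:1000)
  expect_equal(qualified_nodes(tree), 5L)
  tree$nodes[["5"]]$members <- sprintf("m%04d", 1:1200)
  expect_equal(qualified_nodes(tree), integer(0))
  expect_equal(qualified_nodes(list(singleton = TRUE)), integer(0))
})

test_that("pce counts members below pattern-bearing nodes once", {
  nodes <- list(
    "3" = list(node_id = 3L, left = 1L, right = 2L, parent = NA,
               members = c("a", "b", "c"), merge_evalue = 1e-5,
               ec_set = "1.1.1.1", pattern_id = NA_character_, tried = FALSE),
    "1" = list(node_id = 1L, left = NA, right = NA, parent = 3L,
               members = c("a", "b"), merge_evalue = 1e-8,
               ec_set = "1.1.1.1", pattern_id = NA_character_, tried = FALSE),
    "2" = list(node_id = 2L, left = NA, right = NA, parent = 3L,
               members = "c", merge_evalue = NA_real_,
               ec_set = "1.1.1.1", pattern_id = NA_character_, tried = FALSE))
  tree <- list(tree_id = 1L, root = 3L, nodes = nodes,
               members = c("a", "b", "c"), singleton = FALSE)
  expect_equal(pce(tree), 0)
  tree$nodes[["1"]]$pattern_id <- "P1"
  expect_equal(pce(tree), 2 / 3)
  tree$nodes[["3"]]$pattern_id <- "P2"
  expect_equal(pce(tree), 1)
})

test_that("the coverage loop tries worst-E-value nodes in batches, once each", {
  # family of 6 with two subfamilies; root pattern is impossible because
  # one member is unrelated (forcing descent into the tree)
  set.seed(77)
  base <- random_sequence(160)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(length(ch), k)
    ch[at] <- vapply(ch[at], function(r) sample(setdiff(enzpat:::AA20, r), 1), "")
    paste(ch, collapse = "")
  }
  seqs <- c(vapply(1:5, function(i) mut(base, 12), ""), random_sequence(160))
  ids <- sprintf("q%d", 1:6)
  recs <- do.call(rbind, lapply(1:6, function(i)
    make_record(ids[i], seqs[i], ec = "1.1.1.1")))
  # force the outlier into the tree with a fake distance table
  pairs <- utils::combn(ids, 2)
  d <- data.frame(id_a = pairs[1, ], id_b = pairs[2, ],
                  evalue = 1e-30, stringsAsFactors = FALSE)
  d$evalue[d$id_a == "q1" & d$id_b == "q6" ] <- 1e-4   # outlier joins last
  f <- complete_linkage(d, ids, ec_sets = setNames(recs$ec, ids))
  res <- compute_patterns(f, recs, pce_threshold = 0.9)
  tr <- res$forest$trees[[1]]
  tried <- vapply(tr$nodes, `[[`, logical(1), "tried")
  internal <- vapply(tr$nodes, function(nd) !is.na(nd$left), logical(1))
  # root tried (qualified) and, because the random outlier wrecks root
  # conservation, deeper nodes were attempted too
  expect_true(tr$nodes[[as.character(tr$root)]]$tried)
  expect_true(any(!is.na(vapply(tr$nodes, `[[`, "", "pattern_id"))))
  expect_true(all(!tried | internal))        # leaves are never attempted
  expect_gte(pce(tr), 0.5)
})
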