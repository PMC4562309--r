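test_that("TSV round trip preserves the matrix bit-exactly", {
  set.seed(11)
  m <- random_profile(7, 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_matrix(m, path)
  m2 <- read_profile_matrix(path)
  expect_identical(m2$occurrence, m$occurrence)
  expect_identical(genome_ids(m2), genome_ids(m))
  # direct parse check: column sums of a hand-written file
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tfa\tfb\tfc", "g1\t1\t0\t1", "g2\t0\t0\t1"), path2)
  m3 <- read_profile_matrix(path2)
  expect_equal(unname(colSums(m3$occurrence)), c(1, 0, 2))
})

test_that("reader accepts Y/N tokens and rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tfa\tfb", "g1\tY\tN", "g2\tN\tY"), path)
  m <- read_profile_matrix(path)
  expect_equal(unname(m$occurrence), matrix(c(1L, 0L, 0L, 1L), 2))

  writeLines(c("genome_id\tfa", "g1\t1", "g1\t0"), path)
  expect_error(read_profile_matrix(path), "duplicate genome id 'g1'")

  writeLines(c("genome_id\tfa\tfb", "g1\t1\t2"), path)
  expect_error(read_profile_matrix(path), "genome 'g1', family 'fb'")

  writeLines("genome_id\tfa", path)
  expect_error(read_profile_matrix(path), "empty")
  expect_error(read_profile_matrix(tempfile()), "not found")
})

test_that("constructor enforces binary cells and unique ids", {
  occ <- matrix(c(1, 2), 1, 2, dimnames = list("g1", c("a", "b")))
  expect_error(profile_matrix(occ), "non-binary")
  occ <- matrix(0:1, 1, 2, dimnames = list("g1", c("a", "a")))
  expect_error(profile_matrix(occ), "duplicate family id")
  occ <- matrix(c(1, NA), 1, 2, dimnames = list("g1", c("a", "b")))
  expect_error(profile_matrix(occ), "missing")
})

test_that("negation augmentation yields complementary literal pairs", {
  m <- make_profile(matrix(c(1L, 0L), 2, 1), families = "fa")
  lit <- augment_with_negations(m)
  expect_equal(unname(lit[, "fa"]), c(1L, 0L))
  expect_equal(unname(lit[, "!fa"]), c(0L, 1L))

  # all-present family: absence column all zero
  m1 <- make_profile(matrix(1L, 3, 1), families = "fa")
  expect_equal(unname(augment_with_negations(m1)[, "!fa"]), rep(0L, 3))

  # every literal pair sums to 1 in every genome of a random 6x4 matrix
  set.seed(5)
  m6 <- random_profile(6, 4)
  lit <- augment_with_negations(m6)
  for (f in family_ids(m6))
    expect_equal(unname(lit[, f] + lit[, paste0("!", f)]), rep(1L, 6))

  # negating twice recovers the original occurrence column
  expect_identical(1L - (1L - m6$occurrence), m6$occurrence)
})

test_that("filter_genomes evaluates boolean expressions over families", {
  occ <- rbind(c(1, 1, 0), c(0, 0, 1), c(1, 0, 0), c(0, 0, 0), c(1, 1, 1))
  m <- make_profile(occ, genomes = paste0("g", 1:5),
                    families = c("urah", "urad", "uox"))
  kept <- filter_genomes(m, ~ (urah & urad) | uox)
  expect_identical(genome_ids(kept), c("g1", "g2", "g5"))
  # oracle: brute-force evaluation per genome
  manual <- (occ[, 1] & occ[, 2]) | occ[, 3]
  expect_identical(genome_ids(kept), paste0("g", which(manual)))

  expect_identical(filter_genomes(m, TRUE)$occurrence, m$occurrence)
  expect_equal(n_genomes(filter_genomes(m, FALSE)), 0L)
  expect_error(filter_genomes(m, ~ xyz & urah), "xyz")

  # string input and formula input agree
  expect_identical(genome_ids(filter_genomes(m, "(urah & urad) | uox")),
                   genome_ids(kept))
})

test_that("filtering by a conjunction equals sequential filtering", {
  set.seed(17)
  for (i in 1:20) {
    m <- random_profile(12, 4)
    e1 <- ~ (f01 & !f02) | f03
    e2 <- ~ f04 | f02
    both <- filter_genomes(m, ~ (((f01 & !f02) | f03) & (f04 | f02)))
    seq2 <- filter_genomes(filter_genomes(m, e1), e2)
    expect_identical(genome_ids(both), genome_ids(seq2))
  }
})

test_that("capacity classification follows the explained/unexplained logic", {
  occ <- rbind(
    c(1, 1, 0, 0, 0, 1),  # urah+urad+COG3748 -> {COG3748}
    c(1, 1, 0, 0, 0, 0),  # urah+urad, nothing else -> unexplained
    c(1, 1, 1, 0, 0, 1),  # uox and COG3748 both present -> multi-label
    c(1, 0, 0, 0, 0, 0),  # downstream incomplete
    c(0, 0, 1, 0, 0, 0))  # uox alone -> {uox}
  m <- make_profile(occ, families = c("urah", "urad", "uox", "hpxO",
                                      "hpyO", "COG3748"))
  cls <- classify_capacity(m, capacity_scheme())
  expect_equal(cls$labels[[1]], "COG3748")
  expect_equal(cls$labels[[2]], "unexplained")
  expect_true(cls$unexplained[2])
  expect_setequal(cls$labels[[3]], c("uox", "COG3748"))
  expect_true(cls$downstream_incomplete[4])
  expect_equal(cls$labels[[5]], "uox")
  expect_error(classify_capacity(make_profile(occ[, 1:2, drop = FALSE],
                                              families = c("urah", "urad")),
                                 capacity_scheme()),
               "missing from matrix")
})

test_that("'unexplained' is mutually exclusive with any explainer label", {
  set.seed(23)
  scheme <- capacity_scheme(c("d1", "d2"), c("e1", "e2"))
  for (i in 1:20) {
    m <- make_profile(matrix(rbinom(40, 1, 0.5), 10, 4),
                      families = c("d1", "d2", "e1", "e2"))
    cls <- classify_capacity(m, scheme)
    for (j in seq_len(10)) {
      if (cls$unexplained[j])
        expect_length(intersect(cls$labels[[j]], scheme$explainers), 0)
      expect_false(cls$unexplained[j] && cls$downstream_incomplete[j])
    }
  }
})

test_that("summarize_by_class matches hand counts and conserves totals", {
  occ <- rbind(
    c(1, 1, 1, 0), c(1, 1, 0, 1), c(1, 1, 0, 0), c(0, 0, 1, 0),
    c(1, 0, 0, 0), c(1, 1, 1, 1), c(0, 0, 0, 0), c(0, 0, 0, 1))
  md <- data.frame(membrane = rep(c("monoderm", "diderm"), each = 4),
                   row.names = sprintf("g%02d", 1:8))
  m <- profile_matrix(`dimnames<-`(occ, list(sprintf("g%02d", 1:8),
                                             c("d1", "d2", "e1", "e2"))), md)
  scheme <- capacity_scheme(c("d1", "d2"), c("e1", "e2"))
  tab <- summarize_by_class(m, scheme, "membrane")
  # hand enumeration: g1 {e1}, g2 {e2}, g3 {unexplained}, g4 {e1},
  # g5 {downstream_incomplete}, g6 {e1,e2}, g7 {}, g8 {e2}
  expect_equal(tab["e1", "monoderm"], 2)
  expect_equal(tab["unexplained", "monoderm"], 1)
  expect_equal(tab["e1", "diderm"], 1)
  expect_equal(tab["e2", "diderm"], 2)
  expect_equal(tab["downstream_incomplete", "diderm"], 1)
  cls <- classify_capacity(m, scheme)
  expect_equal(sum(tab), sum(lengths(cls$labels)))

  # single genome: exactly one nonzero cell
  m1 <- profile_matrix(m$occurrence[1, , drop = FALSE],
                       md[1, , drop = FALSE])
  expect_equal(sum(summarize_by_class(m1, scheme, "membrane")), 1)
})

test_that("species deduplication keeps the first genome per species", {
  md <- data.frame(species = c("A", "A", "B"),
                   row.names = c("g1", "g2", "g3"))
  m <- profile_matrix(`dimnames<-`(diag(3L), list(c("g1", "g2", "g3"),
                                                  c("fa", "fb", "fc"))), md)
  expect_message(m2 <- dedupe_species(m), "dropped 1")
  expect_identical(genome_ids(m2), c("g1", "g3"))
})

test_that("tree ordering follows leaf order and appends unmatched genomes", {
  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((gC,(gA,gE)),(gB,gD));", nwk)
  ids <- paste0("g", LETTERS[1:5])
  ord <- order_genomes_by_tree(ids, nwk)
  # manual cladewise traversal of the written tree
  expect_identical(ord, c("gC", "gA", "gE", "gB", "gD"))
  expect_warning(ord2 <- order_genomes_by_tree(c(ids, "gX"), nwk), "gX")
  expect_identical(ord2[6], "gX")
})
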