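write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".a3m")
  writeLines(lines, f)
  f
}

test_that("a3m parsing strips insertions, parses OX tokens and validates", {
  f <- write_lines_tmp(c(">query protein", "ACDEF",
                         ">tr|X|X_HUMAN OX=9606 GN=ABC", "AxCDE-",
                         ">hit_no_ox", "-CDE-"))
  m <- read_a3m(f)
  expect_equal(n_rows(m), 3L)
  expect_equal(query_length(m), 5L)
  expect_equal(m$sequence, c("ACDEF", "ACDE-", "-CDE-"))
  expect_equal(m$organism_id, c(NA_integer_, 9606L, NA_integer_))
  expect_equal(m$rank, 0:2)

  empty <- tempfile(fileext = ".a3m")
  file.create(empty)
  expect_error(read_a3m(empty), "empty")

  bad <- write_lines_tmp(c(">q", "ACDEF", ">short", "AC"))
  expect_error(read_a3m(bad), "differ in length")
})

test_that("write/read round trip preserves rows, headers and organism ids", {
  m <- msa(c("q", "h1 OX=9606", "h2 OX=10090"),
           c("ACDEFGH", "AC-EFGH", "-CDEF--"))
  f <- tempfile(fileext = ".a3m")
  write_a3m(m, f)
  back <- read_a3m(f)
  expect_equal(back$sequence, m$sequence)
  expect_equal(back$header, m$header)
  expect_equal(back$organism_id, m$organism_id)
  # uppercase-only single-line records round-trip byte-identically
  f2 <- tempfile(fileext = ".a3m")
  write_a3m(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # an alignment without rows cannot exist, let alone be written
  expect_error(msa(character(0), character(0)), "at least the query")
})

test_that("gap filtering removes rows with more than the cutoff, never the query", {
  mk_row <- function(gaps) paste0(strrep("-", gaps), strrep("A", 100 - gaps))
  m <- msa(c("q", "g91", "g90", "g100"),
           c(strrep("A", 100), mk_row(91), mk_row(90), strrep("-", 100)))
  out <- filter_gapped_rows(m, 0.9)
  expect_equal(out$header, c("q", "g90"))   # >90% removed, exactly 90% kept
  # idempotent
  expect_equal(filter_gapped_rows(out, 0.9)$sequence, out$sequence)
  # query exempt even when itself heavily gapped
  qg <- msa(c("q", "h"), c(paste0(strrep("-", 95), strrep("A", 5)),
                           strrep("A", 100)))
  expect_equal(n_rows(filter_gapped_rows(qg, 0.9)), 2L)
})

test_that("organism pairing takes the best-ranked hit per shared organism", {
  a <- msa(c("qa", "a1 OX=9606", "a2 OX=9606", "a3 OX=10090"),
           c("AAAA", "CCCC", "DDDD", "EEEE"))
  b <- msa(c("qb", "b1 OX=10090", "b2 OX=9606"),
           c("WWW", "YYY", "KKK"))
  p <- pair_by_organism(a, b)
  expect_s3_class(p, "paired_msa")
  expect_equal(n_rows(p), 3L)                      # query + 2 shared organisms
  expect_equal(p$sequence[1L], "AAAAWWW")
  expect_equal(p$sequence[2L], "CCCCKKK")          # 9606: A rank 1 with B rank 2
  expect_equal(p$sequence[3L], "EEEEYYY")          # 10090: A rank 3 with B rank 1
  prov <- attr(p, "provenance")
  expect_equal(prov$organism_id, c(9606L, 10090L))
  expect_equal(prov$rank_a, c(1L, 3L))
  expect_equal(prov$rank_b, c(2L, 1L))

  # disjoint organisms: query-only result, empty provenance
  d <- pair_by_organism(a, msa(c("qb", "b1 OX=562"), c("WWW", "YYY")))
  expect_equal(n_rows(d), 1L)
  expect_equal(nrow(attr(d, "provenance")), 0L)

  # single shared organism
  s <- pair_by_organism(a, msa(c("qb", "b1 OX=9606"), c("WWW", "YYY")))
  expect_equal(n_rows(s), 2L)
})

test_that("paired row count is bounded by shared organisms (property)", {
  for (seed in 1:10) {
    orgs_a <- withr::with_seed(seed, sample(1:8, 10, replace = TRUE))
    orgs_b <- withr::with_seed(seed + 100, sample(1:8, 7, replace = TRUE))
    mp <- make_toy_msa_pair(orgs_a, orgs_b, 12L, 15L, seed = seed,
                            gap_rate = 0)
    p <- pair_by_organism(mp$a3m_a, mp$a3m_b)
    expect_equal(n_rows(p), 1L + mp$expected_pairs)
    expect_equal(nrow(attr(p, "provenance")), mp$expected_pairs)
  }
})

test_that("block diagonalization pads correctly and conserves residues", {
  a <- make_toy_msa_pair(rep(1L, 2), rep(2L, 3), 50L, 70L, seed = 4)
  msa_a <- a$a3m_a; msa_b <- a$a3m_b          # 3 rows x 50 and 4 rows x 70
  blk <- block_diagonalize(msa_a, msa_b)
  expect_equal(n_rows(blk), 6L)
  expect_equal(query_length(blk), 120L)
  # A-derived rows end in 70 gaps; B-derived start with 50 gaps
  expect_true(all(grepl("-{70}$", blk$sequence[2:3])))
  expect_true(all(grepl("^-{50}", blk$sequence[4:6])))
  count_res <- function(m) sum(nchar(gsub("-", "", m$sequence)))
  expect_equal(count_res(blk),
               count_res(msa_a) + count_res(msa_b) -
                 0)  # query residues appear once in the concatenated row 0
  # queries-only input collapses to the concatenated query
  qa <- msa("qa", "AAA"); qb <- msa("qb", "CC")
  expect_equal(block_diagonalize(qa, qb)$sequence, "AAACC")
})

test_that("fusing alignments keeps one query and all hit rows", {
  a <- make_toy_msa_pair(1:4, 1:3, 20L, 25L, seed = 5)
  paired <- pair_by_organism(a$a3m_a, a$a3m_b)   # 1 + 3 rows
  blk <- block_diagonalize(a$a3m_a, a$a3m_b)     # 1 + 4 + 3 rows
  fused <- fuse_msas(list(paired, blk))
  expect_equal(n_rows(fused), 1L + (n_rows(paired) - 1L) + (n_rows(blk) - 1L))
  expect_equal(fused$sequence[1L], paired$sequence[1L])
  # identity on a single part
  expect_equal(fuse_msas(list(blk))$sequence, blk$sequence)
  # mismatched queries refuse to fuse
  other <- msa("q", strrep("K", query_length(blk)))
  expect_error(fuse_msas(list(blk, other)), "query mismatch")
})
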