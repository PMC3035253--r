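qg <- genome("qg", c(q = strrep("A", 1000)))
sg <- genome("sg", c(s = strrep("A", 1000)))

test_that("BLAST tabular coordinates and identities convert correctly", {
  p <- write_tmp("q\ts\t90.00\t200\t20\t0\t101\t300\t1\t200\t1e-50\t370")
  ms <- parse_blast_tabular(p, qg, sg)
  m <- ms$matches
  expect_equal(nrow(m), 1L)
  expect_equal(m$q_start, 100); expect_equal(m$q_end, 300)
  expect_equal(m$s_start, 0);   expect_equal(m$s_end, 200)
  expect_equal(m$strand, "+")
  expect_equal(m$length, 200)
  expect_equal(m$identities, 180)   # round(0.90 * 200)
  expect_equal(m$score, 370)
  expect_equal(m$evalue, 1e-50)
})

test_that("BLAST minus-strand HSPs are stored forward-strand", {
  p <- write_tmp("q\ts\t95.00\t100\t5\t0\t1\t100\t500\t401\t1e-20\t180")
  m <- parse_blast_tabular(p, qg, sg)$matches
  expect_equal(m$strand, "-")
  expect_equal(m$s_start, 400)
  expect_equal(m$s_end, 500)
})

test_that("BLAST parser handles comments, empty input and bad lines", {
  p <- write_tmp(c("# comment", ""))
  expect_equal(nrow(parse_blast_tabular(p, qg, sg)$matches), 0L)
  bad <- write_tmp(c("q\ts\t90.00\t200\t20\t0\t101\t300\t1\t200\t1e-50\t370",
                     "q\ts\tonly\tthree"))
  expect_error(parse_blast_tabular(bad, qg, sg), "line 2")
  nonnum <- write_tmp("q\ts\tNOPE\t200\t20\t0\t101\t300\t1\t200\t1e-50\t370")
  expect_error(parse_blast_tabular(nonnum, qg, sg), "non-numeric")
  unknown <- write_tmp("zz\ts\t90.00\t200\t20\t0\t101\t300\t1\t200\t1e-50\t370")
  expect_error(parse_blast_tabular(unknown, qg, sg), "replicon")
})

test_that("mummer forward and reverse sections convert to forward-strand", {
  # columns: reference (subject) position, query position, length
  qg2 <- genome("qg2", c(q = strrep("A", 300)))
  p <- write_tmp(c("> q", "101 51 40", "> q Reverse", "101 101 30"))
  m <- parse_mummer_mums(p, qg2, sg)$matches
  expect_equal(nrow(m), 2L)
  fwd <- m[m$strand == "+", ]
  expect_equal(fwd$q_start, 50);  expect_equal(fwd$q_end, 90)
  expect_equal(fwd$s_start, 100); expect_equal(fwd$s_end, 140)
  expect_equal(fwd$identities, 40)
  expect_equal(fwd$score, 40)      # MUM length stands in for the score
  expect_true(is.na(fwd$evalue))
  # reverse: query position 101 on the reversed 300 bp query, length 30
  # -> forward interval [170, 200)
  rev <- m[m$strand == "-", ]
  expect_equal(rev$q_start, 170); expect_equal(rev$q_end, 200)
  expect_equal(rev$s_start, 100); expect_equal(rev$s_end, 130)
})

test_that("mummer parser rejects malformed input and accepts empty input", {
  expect_equal(nrow(parse_mummer_mums(write_tmp(character(0)), qg, sg)$matches), 0L)
  expect_error(parse_mummer_mums(write_tmp(c("> q", "10 10 0")), qg, sg),
               "positive")
  expect_error(parse_mummer_mums(write_tmp(c("> q", "1 2 3 4 5")), qg, sg),
               "columns")
  expect_error(parse_mummer_mums(write_tmp(c("> q", "a b c")), qg, sg),
               "non-numeric")
})

test_that("match TSV serialization round-trips both parsed formats", {
  pb <- write_tmp(c("q\ts\t90.00\t200\t20\t0\t101\t300\t1\t200\t1e-50\t370",
                    "q\ts\t95.00\t100\t5\t0\t1\t100\t500\t401\t1e-20\t180"))
  ms <- parse_blast_tabular(pb, qg, sg)
  tp <- tempfile(fileext = ".tsv")
  write_match_tsv(ms, tp)
  ms2 <- read_match_tsv(tp, qg, sg)
  expect_equal(ms2$matches, ms$matches)

  pm <- write_tmp(c("> q", "101 51 40", "> q Reverse", "101 101 30"))
  qg2 <- genome("qg2", c(q = strrep("A", 300)))
  mm <- parse_mummer_mums(pm, qg2, sg)
  tp2 <- tempfile(fileext = ".tsv")
  write_match_tsv(mm, tp2)
  expect_equal(read_match_tsv(tp2, qg2, sg)$matches, mm$matches)
})

test_that("e-value filter keeps low e-values and passes MUMs through", {
  m <- data.frame(q_replicon = "q", s_replicon = "s",
                  q_start = c(0, 100), q_end = c(50, 150),
                  s_start = c(0, 100), s_end = c(50, 150),
                  strand = "+", length = 50, identities = 45,
                  score = 100, evalue = c(1e-50, 0.5),
                  stringsAsFactors = FALSE)
  ms <- match_set(qg, sg, m)
  f <- filter_by_evalue(ms, 1e-2)
  expect_equal(nrow(f$matches), 1L)
  expect_equal(f$matches$evalue, 1e-50)

  m$evalue <- NA_real_
  mum <- match_set(qg, sg, m)
  expect_warning(f2 <- filter_by_evalue(mum, 1e-2), "no effect")
  expect_equal(f2$matches, mum$matches)

  empty <- match_set(qg, sg)
  expect_equal(nrow(filter_by_evalue(empty)$matches), 0L)
})

test_that("match invariants are enforced at construction", {
  base <- data.frame(q_replicon = "q", s_replicon = "s",
                     q_start = 0, q_end = 50, s_start = 0, s_end = 50,
                     strand = "+", length = 50, identities = 45,
                     score = 100, evalue = NA_real_,
                     stringsAsFactors = FALSE)
  ok <- match_set(qg, sg, base)
  expect_s3_class(ok, "gbdp_matchset")
  bad <- base; bad$identities <- 60
  expect_error(match_set(qg, sg, bad), "identities")
  bad <- base; bad$q_end <- 0
  expect_error(match_set(qg, sg, bad), "interval")
  bad <- base; bad$s_end <- 2000
  expect_error(match_set(qg, sg, bad), "beyond replicon end")
  bad <- base; bad$score <- 0
  expect_error(match_set(qg, sg, bad), "score")
})
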