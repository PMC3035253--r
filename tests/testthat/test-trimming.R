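mk_set <- function(rows, glen = 1200L) {
  gq <- genome("q", c(r1 = strrep("A", glen)))
  gs <- genome("s", c(r1 = strrep("A", glen)))
  match_set(gq, gs, do.call(rbind, rows))
}
row_m <- function(qs, qe, ss, se, score, identities = qe - qs,
                  strand = "+", q_rep = "r1", s_rep = "r1") {
  data.frame(q_replicon = q_rep, s_replicon = s_rep,
             q_start = qs, q_end = qe, s_start = ss, s_end = se,
             strand = strand, length = qe - qs, identities = identities,
             score = score, evalue = NA_real_, stringsAsFactors = FALSE)
}

test_that("trimming clips a candidate against an accepted match", {
  # accepted A covers q:[100,300); candidate B q:[250,400), s:[0,150),
  # identities 135 -> clipped to q:[300,400), s:[50,150), identities
  # floor(135 * 100/150) = 90
  s <- mk_set(list(row_m(100, 300, 300, 500, score = 500),
                   row_m(250, 400, 0, 150, score = 300, identities = 135)))
  out <- greedy_trim(s)
  m <- out$matches
  expect_equal(nrow(m), 2L)
  b <- m[m$q_start == 300, ]
  expect_equal(b$q_end, 400)
  expect_equal(b$s_start, 50); expect_equal(b$s_end, 150)
  expect_equal(b$identities, 90)
})

test_that("disjoint matches pass unchanged; duplicates are dropped", {
  s <- mk_set(list(row_m(0, 100, 0, 100, score = 200),
                   row_m(200, 300, 200, 300, score = 100)))
  out <- greedy_trim(s)
  expect_equal(nrow(out$matches), 2L)
  expect_equal(out$h_total, 200)

  dup <- mk_set(list(row_m(0, 100, 0, 100, score = 200),
                     row_m(0, 100, 0, 100, score = 100)))
  expect_equal(nrow(greedy_trim(dup)$matches), 1L)

  expect_equal(greedy_trim(mk_set(list(row_m(0, 10, 0, 10, score = 1))))$h_total, 10)
  empty <- match_set(genome("q", c(r1 = "ACGTACGTAC")),
                     genome("s", c(r1 = "ACGTACGTAC")))
  expect_equal(greedy_trim(empty)$h_total, 0)
})

test_that("an internal split keeps the longest remaining fragment", {
  # accepted covers q:[100,200); candidate q:[0,300) splits into [0,100)
  # and [200,300); equal lengths -> leftmost kept
  s <- mk_set(list(row_m(100, 200, 500, 600, score = 500),
                   row_m(0, 300, 0, 300, score = 100)))
  out <- greedy_trim(s)
  cand <- out$matches[out$matches$score < 500, ]
  expect_equal(c(cand$q_start, cand$q_end), c(0, 100))
  # uneven split keeps the bigger piece
  s2 <- mk_set(list(row_m(100, 200, 500, 600, score = 500),
                    row_m(50, 400, 0, 350, score = 100)))
  cand2 <- greedy_trim(s2)$matches
  cand2 <- cand2[cand2$q_start == 200, ]
  expect_equal(cand2$q_end, 400)
})

test_that("trimmed output never overlaps, never grows, and is idempotent", {
  set.seed(42)
  for (i in 1:200) {
    s <- random_match_set(sample(2:50, 1L), two_replicons = i %% 5L == 0L)
    out <- greedy_trim(s)
    expect_false(oracle_overlaps(out$matches))
    expect_lte(sum(out$matches$length), sum(s$matches$length))
    # overlap-free input comes back unchanged in total
    if (!oracle_overlaps(s$matches))
      expect_equal(out$h_total, sum(s$matches$length))
    # idempotence: re-trimming the trimmed set changes nothing
    if (nrow(out$matches)) {
      gq <- genome("q", c(r1 = strrep("A", 1200), r2 = strrep("A", 1200)))
      gs <- genome("s", c(r1 = strrep("A", 1200), r2 = strrep("A", 1200)))
      again <- greedy_trim(match_set(gq, gs, out$matches))
      expect_equal(again$matches, out$matches)
    }
  }
})

test_that("overlap-free inputs give identical totals for trim and coverage", {
  set.seed(9)
  for (i in 1:20) {
    rows <- lapply(1:5, function(j)
      row_m(200 * (j - 1), 200 * (j - 1) + 100,
            200 * (j - 1) + 50, 200 * (j - 1) + 150,
            score = j * 10, identities = 90))
    s <- mk_set(rows)
    tr <- greedy_trim(s)
    cv <- coverage_reduce(s)
    expect_equal(tr$h_total, cv$h_total)
    expect_equal(tr$i_total, cv$i_total)
  }
})

test_that("coverage mode counts each genomic position once per side", {
  # overlapping query footprints: union length 150
  s <- mk_set(list(row_m(0, 100, 0, 100, score = 10),
                   row_m(50, 150, 300, 400, score = 10)))
  expect_equal(coverage_reduce(s)$h_total, 150)
  # one match: identical to input
  one <- mk_set(list(row_m(0, 100, 0, 100, score = 10, identities = 80)))
  cv1 <- coverage_reduce(one)
  expect_equal(cv1$h_total, 100); expect_equal(cv1$i_total, 80)
  # two identical repeats hitting the same subject interval: subject-side
  # footprint counted once
  rep2 <- mk_set(list(row_m(0, 100, 0, 100, score = 10),
                      row_m(200, 300, 0, 100, score = 10)))
  expect_equal(coverage_reduce(rep2)$h_total, 100)
  # raw mode multi-counts
  expect_equal(coverage_reduce(rep2, mode = "raw")$h_total, 200)
})

test_that("a duplicated repeat cannot multiply the trimmed totals", {
  set.seed(31)
  base <- random_seq(4000)
  rep_seg <- substr(base, 1001, 1400)            # 400 bp repeat
  with_dup <- paste0(base, rep_seg)              # extra copy appended
  other <- mutate_seq(base, 0.01)
  g1 <- genome("g1", c(chr = base))
  g1d <- genome("g1d", c(chr = with_dup))
  g2 <- genome("g2", c(chr = other))
  h_plain <- greedy_trim(find_exact_matches(g1, g2, 20))$h_total
  h_dup <- greedy_trim(find_exact_matches(g1d, g2, 20))$h_total
  expect_lte(abs(h_dup - h_plain), 400)
})
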