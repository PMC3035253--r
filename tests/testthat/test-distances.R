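test_that("the ten distance functions evaluate the reconstructed formulas", {
  cmp <- gbdp_components(h_xy = 400, h_yx = 500, i_xy = 360, i_yx = 450,
                         len_x = 1000, len_y = 800)
  d <- suppressWarnings(ggd_all(cmp))
  expect_identical(d[["d0"]], 1 - 900 / 1800)          # 0.5
  expect_identical(d[["d1"]], 1 - 900 / 1600)          # 0.4375
  expect_identical(d[["d4"]], 1 - 810 / 900)           # 0.1
  expect_identical(d[["d6"]], 1 - 810 / 1800)          # 0.55
  expect_identical(d[["d7"]], 1 - 810 / 1600)          # 0.49375
  # each log variant is exactly -ln(1 - d) of its base variant
  expect_identical(d[["d2"]], -log(1 - d[["d0"]]))
  expect_identical(d[["d3"]], -log(1 - d[["d1"]]))
  expect_identical(d[["d5"]], -log(1 - d[["d4"]]))
  expect_identical(d[["d8"]], -log(1 - d[["d6"]]))
  expect_identical(d[["d9"]], -log(1 - d[["d7"]]))
})

test_that("the canonical 0-9 numbering maps to family/denominator/log", {
  specs <- lapply(0:9, gbdp_spec_from_index)
  expect_equal(vapply(specs, `[[`, integer(1L), "family"),
               c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L))
  twomin <- vapply(specs, function(s) s$denominator == "twice_min_length",
                   logical(1L))
  expect_equal(which(twomin) - 1L, c(1L, 3L, 7L, 9L))
  lg <- vapply(specs, `[[`, logical(1L), "log_transform")
  expect_equal(which(lg) - 1L, c(2L, 3L, 5L, 8L, 9L))
  expect_equal(vapply(specs, `[[`, integer(1L), "gbdp_index"), 0:9)
})

test_that("degenerate components map to maximal distance", {
  cmp <- gbdp_components(0, 0, 0, 0, 1000, 800)
  d <- ggd_all(cmp)
  expect_equal(unname(d[c("d0", "d1", "d4", "d6", "d7")]), rep(1, 5))
  expect_true(all(d[c("d2", "d3", "d5", "d8", "d9")] > 20))  # -ln(1e-12)
})

test_that("self-comparison yields distance 0 for all ten functions", {
  set.seed(5)
  g <- genome("g", c(chr = random_seq(3000)))
  ms <- find_exact_matches(g, g, 20)
  r <- greedy_trim(ms)
  cmp <- compute_components(r, r, g, g)
  expect_equal(unname(suppressWarnings(ggd_all(cmp))), rep(0, 10))
})

test_that("family 2 warns on identity-only match sets", {
  cmp <- gbdp_components(100, 100, 100, 100, 1000, 1000)
  expect_warning(ggd(cmp, gbdp_spec(family = 2)), "identity-only")
})

test_that("log transform never changes Kendall correlations", {
  set.seed(77)
  for (rep in 1:10) {
    n <- 30
    comps <- lapply(1:n, function(i) {
      lx <- sample(5000:20000, 1L); ly <- sample(5000:20000, 1L)
      h1 <- runif(1, 0, lx); h2 <- runif(1, 0, ly)
      gbdp_components(h1, h2, runif(1, 0, h1), runif(1, 0, h2), lx, ly)
    })
    ref <- runif(n)
    for (base_idx in c(0L, 1L, 4L, 6L, 7L)) {
      log_idx <- c(`0` = 2L, `1` = 3L, `4` = 5L, `6` = 8L, `7` = 9L)[as.character(base_idx)]
      db <- vapply(comps, function(cm)
        ggd(cm, gbdp_spec_from_index(base_idx))$distance, numeric(1L))
      dl <- vapply(comps, function(cm)
        ggd(cm, gbdp_spec_from_index(log_idx))$distance, numeric(1L))
      expect_identical(kendall_tau(db, ref), kendall_tau(dl, ref))
    }
  }
})

test_that("all functions are monotone in the identity and match totals", {
  set.seed(13)
  for (rep in 1:50) {
    lx <- sample(5000:20000, 1L); ly <- sample(5000:20000, 1L)
    h1 <- runif(1, 100, lx); h2 <- runif(1, 100, ly)
    i1 <- runif(1, 0, h1); i2 <- runif(1, 0, h2)
    cmp <- gbdp_components(h1, h2, i1, i2, lx, ly)
    up_i <- gbdp_components(h1, h2, min(h1, i1 * 1.1 + 1), i2, lx, ly)
    d0 <- suppressWarnings(ggd_all(cmp)); di <- suppressWarnings(ggd_all(up_i))
    expect_true(all(di <= d0 + 1e-12))          # non-increasing in I
    up_h <- gbdp_components(h1 * 1.05, h2, i1, i2, lx, ly)
    dh <- suppressWarnings(ggd_all(up_h))
    expect_true(all(dh[c("d0", "d1", "d6", "d7")] <=
                      d0[c("d0", "d1", "d6", "d7")] + 1e-12))
  }
})

test_that("family 2 ignores genome length; families 1 and 3 do not", {
  set.seed(21)
  base <- random_seq(20000)
  other <- mutate_seq(base, 0.02)
  gx <- genome("x", c(chr = base))
  gy <- genome("y", c(chr = other))
  gy_ext <- genome("y", c(chr = paste0(other, random_seq(10000))))
  d_of <- function(a, b) {
    sxy <- find_exact_matches(a, b, 20)
    syx <- find_exact_matches(b, a, 20)
    cmp <- compute_components(greedy_trim(sxy), greedy_trim(syx), a, b)
    suppressWarnings(ggd_all(cmp))
  }
  d1 <- d_of(gx, gy)
  d2 <- d_of(gx, gy_ext)
  expect_lt(abs(d2[["d4"]] - d1[["d4"]]), 1e-9)
  expect_gt(d2[["d0"]], d1[["d0"]])
  expect_gt(d2[["d6"]], d1[["d6"]])
})

test_that("distance_matrix is symmetric, logs failures, and flags duplicates", {
  set.seed(3)
  g1 <- genome("g1", c(chr = random_seq(2000)))
  g2 <- genome("g2", c(chr = mutate_seq(g1$replicons[["chr"]], 0.05)))
  g3 <- genome("g3", c(chr = random_seq(2000)))
  mats <- distance_matrix(list(g1, g2, g3), gbdp_spec(), min_length = 15)
  for (m in mats) {
    expect_true(isSymmetric(m))
    expect_equal(unname(diag(m)), rep(0, 3))
  }
  expect_equal(nrow(attr(mats, "pair_stats")), 6L)  # 3 pairs x 2 directions

  # identical genome duplicated: family 2 distance 0
  g1b <- genome("g1copy", c(chr = g1$replicons[["chr"]]))
  mats2 <- distance_matrix(list(g1, g1b), gbdp_spec(), indices = 4L,
                           min_length = 20)
  expect_equal(mats2$d4["g1", "g1copy"], 0)

  # provider failure leaves NA and a log record, and the run continues
  flaky <- function(x, y) {
    if (x$genome_id == "g1" && y$genome_id == "g3") stop("boom")
    find_exact_matches(x, y, 15)
  }
  mats3 <- distance_matrix(list(g1, g2, g3), gbdp_spec(), flaky, indices = 0L)
  expect_true(is.na(mats3$d0["g1", "g3"]))
  expect_false(anyNA(mats3$d0["g1", "g2"]))
  expect_equal(nrow(attr(mats3, "failures")), 1L)
})

test_that("distance matrices serialize to PHYLIP and long TSV", {
  m <- matrix(c(0, 0.1, 0.1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- tempfile(fileext = ".phylip")
  write_phylip(m, p)
  lines <- readLines(p)
  expect_match(lines[1L], "^\\s*2$")
  expect_equal(length(lines), 3L)
  tp <- tempfile(fileext = ".tsv")
  write_distance_tsv(list(d0 = m), tp)
  tab <- read.delim(tp)
  expect_equal(tab$distance, 0.1)
  expect_equal(tab$gbdp_index, 0L)
})
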