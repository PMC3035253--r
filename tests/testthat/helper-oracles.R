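# Independent reference implementations used only to check the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

mutate_seq <- function(s, rate) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

# Brute-force maximal-exact-match enumeration: walks every diagonal of the
# comparison matrix on both strands, no seeding involved.
oracle_mems <- function(qseq, sseq, min_length) {
  qv <- strsplit(qseq, "", fixed = TRUE)[[1L]]
  n <- length(qv)
  one_strand <- function(sv, strand, slen) {
    m <- length(sv)
    rows <- list()
    for (d in (-(m - 1L)):(n - 1L)) {
      qi <- max(1L, 1L + d):min(n, m + d)
      if (length(qi) < min_length) next
      si <- qi - d
      eq <- qv[qi] == sv[si] & qv[qi] != "N"
      run_start <- NULL
      for (t in seq_along(eq)) {
        if (eq[t] && is.null(run_start)) run_start <- t
        if ((!eq[t] || t == length(eq)) && !is.null(run_start)) {
          run_end <- if (eq[t]) t else t - 1L
          len <- run_end - run_start + 1L
          if (len >= min_length) {
            q0 <- qi[run_start] - 1L
            s0 <- si[run_start] - 1L
            if (strand == "+") {
              rows[[length(rows) + 1L]] <-
                c(q0, q0 + len, s0, s0 + len, len)
            } else {
              rows[[length(rows) + 1L]] <-
                c(q0, q0 + len, slen - s0 - len, slen - s0, len)
            }
          }
          run_start <- NULL
        }
      }
    }
    if (!length(rows)) return(NULL)
    df <- as.data.frame(do.call(rbind, rows))
    names(df) <- c("q_start", "q_end", "s_start", "s_end", "length")
    df$strand <- strand
    df
  }
  rc <- chartr("ACGTN", "TGCAN",
               paste(rev(strsplit(sseq, "", fixed = TRUE)[[1L]]), collapse = ""))
  slen <- nchar(sseq)
  out <- rbind(one_strand(strsplit(sseq, "", fixed = TRUE)[[1L]], "+", slen),
               one_strand(strsplit(rc, "", fixed = TRUE)[[1L]], "-", slen))
  if (is.null(out)) return(out)
  out <- out[order(out$q_start, out$q_end, out$s_start, out$strand), ]
  rownames(out) <- NULL
  out
}

# naive tau-b: explicit double loop with tie correction
oracle_kendall <- function(a, b) {
  n <- length(a)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    da <- a[i] - a[j]; db <- b[i] - b[j]
    if (da == 0 && db == 0) next
    if (da == 0) { tx <- tx + 1; next }
    if (db == 0) { ty <- ty + 1; next }
    if (sign(da) == sign(db)) C <- C + 1 else D <- D + 1
  }
  (C - D) / sqrt((C + D + tx) * (C + D + ty))
}

oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# O(k^2) pairwise interval-intersection check, per replicon and side
oracle_overlaps <- function(m) {
  if (nrow(m) < 2L) return(FALSE)
  for (side in c("q", "s")) {
    rep_col <- paste0(side, "_replicon")
    st <- m[[paste0(side, "_start")]]; en <- m[[paste0(side, "_end")]]
    for (i in 1:(nrow(m) - 1L)) for (j in (i + 1L):nrow(m)) {
      if (m[[rep_col]][i] != m[[rep_col]][j]) next
      if (st[i] < en[j] && st[j] < en[i]) return(TRUE)
    }
  }
  FALSE
}

# random valid match set over two synthetic genomes
random_match_set <- function(k, genome_len = 1200L, two_replicons = FALSE) {
  reps <- if (two_replicons) c("r1", "r2") else "r1"
  seqs <- setNames(lapply(reps, function(x) strrep("A", genome_len)), reps)
  gq <- genome("q", unlist(seqs))
  gs <- genome("s", unlist(seqs))
  rows <- lapply(seq_len(k), function(i) {
    len <- sample(20:200, 1L)
    qs <- sample.int(genome_len - len, 1L) - 1L
    ss <- sample.int(genome_len - len, 1L) - 1L
    ident <- sample.int(len, 1L)
    data.frame(q_replicon = sample(reps, 1L), s_replicon = sample(reps, 1L),
               q_start = qs, q_end = qs + len, s_start = ss, s_end = ss + len,
               strand = sample(c("+", "-"), 1L), length = len,
               identities = ident, score = stats::runif(1L, 1, 1000),
               evalue = NA_real_, stringsAsFactors = FALSE)
  })
  match_set(gq, gs, do.call(rbind, rows))
}

# exhaustive threshold-scan oracle: independent FP/FN counting at every
# grid point (the grid itself is taken as given so the check is about the
# error evaluation and the argmin, not about seq() arithmetic)
oracle_threshold_scan <- function(records, grid, ddh_cutoff = 70) {
  errs <- numeric(length(grid))
  for (g in seq_along(grid)) {
    fp <- 0L; fn <- 0L
    for (i in seq_len(nrow(records))) {
      pred_same <- records$ggd[i] <= grid[g]
      truly_same <- records$ddh[i] >= ddh_cutoff
      if (pred_same && !truly_same) fp <- fp + 1L
      if (!pred_same && truly_same) fn <- fn + 1L
    }
    errs[g] <- (fp + fn) / nrow(records)
  }
  best <- which(errs == min(errs))[1L]
  list(optimal_T = grid[best], min_error_ratio = errs[best], errs = errs,
       grid = grid)
}

# minimum error ratio over the piecewise-constant regimes of T within the
# observed [min, max] range: the error changes only at observed ggd values,
# so each value (and each midpoint above it) represents one regime the
# threshold grid can reach
oracle_midpoint_min <- function(records, ddh_cutoff = 70) {
  v <- sort(unique(records$ggd))
  cand <- c(v, (v[-1L] + v[-length(v)]) / 2)
  min(vapply(cand, function(T) error_ratio(records, T, ddh_cutoff),
             numeric(1L)))
}

write_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
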