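# Maximal exact matches between two sequences, found by k-mer anchoring of
# candidate diagonals followed by a vectorized run scan along each anchored
# diagonal. On a diagonal an exact match is maximal iff its run of equal
# characters is maximal, so scanning whole runs yields exactly the maximal
# matches; any match of length >= min_length contains a shared k-mer
# (k <= min_length), so anchoring misses nothing. N never counts as equal.

kmer_starts <- function(sraw, k) {
  n <- length(sraw)
  if (n < k) return(integer(0L))
  seq_len(n - k + 1L)
}

# shared-diagonal detection via k-mer hashing on character substrings
anchored_diagonals <- function(xseq, yseq, k) {
  nx <- nchar(xseq); ny <- nchar(yseq)
  if (nx < k || ny < k) return(integer(0L))
  xi <- seq_len(nx - k + 1L)
  yi <- seq_len(ny - k + 1L)
  xk <- substring(xseq, xi, xi + k - 1L)
  yk <- substring(yseq, yi, yi + k - 1L)
  keep_x <- !grepl("N", xk, fixed = TRUE)
  keep_y <- !grepl("N", yk, fixed = TRUE)
  xk <- xk[keep_x]; xi <- xi[keep_x]
  yk <- yk[keep_y]; yi <- yi[keep_y]
  if (!length(xk) || !length(yk)) return(integer(0L))
  ypos_by_kmer <- split(yi, yk)
  hit <- xk %in% names(ypos_by_kmer)
  if (!any(hit)) return(integer(0L))
  diags <- unlist(lapply(which(hit), function(ii) {
    xi[ii] - ypos_by_kmer[[xk[ii]]]
  }), use.names = FALSE)
  sort(unique(diags))
}

# maximal equal runs (length >= min_length) between x and y along diagonals;
# returns 0-based starts. Equality excludes N on either side.
scan_diagonals <- function(xraw, yraw, diags, min_length) {
  nx <- length(xraw); ny <- length(yraw)
  Nbyte <- charToRaw("N")
  out <- vector("list", length(diags))
  for (t in seq_along(diags)) {
    d <- diags[t]                     # d = xpos - ypos (1-based offsets)
    i0 <- max(1L, 1L + d); i1 <- min(nx, ny + d)
    if (i1 - i0 + 1L < min_length) next
    xi <- i0:i1
    yi <- xi - d
    eq <- (xraw[xi] == yraw[yi]) & (xraw[xi] != Nbyte)
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_length
    if (!any(keep)) next
    out[[t]] <- data.frame(
      q_start = xi[starts[keep]] - 1L,     # 0-based
      s_start = yi[starts[keep]] - 1L,
      len = r$lengths[keep])
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Find all maximal exact matches between two genomes
#'
#' A built-in exact matcher so the full distance pipeline can run without
#' external alignment programs. It reports every maximal exact match of
#' length at least \code{min_length} between each query replicon and each
#' subject replicon, on both strands (the behaviour of \code{mummer
#' -maxmatch}: matches need not be unique in either genome; the downstream
#' trimming step handles repeats). Exact matches have identities equal to
#' length, and the match length stands in for the score. \code{N} never
#' participates in a match.
#'
#' @param query_genome,subject_genome \code{gbdp_genome} objects.
#' @param min_length minimum match length in bp; must be >= 8 (shorter
#'   seeds make anchoring unreliable and are dominated by chance matches).
#' @return a \code{gbdp_matchset} in deterministic order (sorted by query
#'   replicon, query interval, subject replicon, subject interval, strand).
#' @examples
#' a <- genome("a", c(chr = "AAACCCGGGTTTAAACCCGG"))
#' b <- genome("b", c(chr = "CCCGGGTTTAAACCCGGGTT"))
#' find_exact_matches(a, b, min_length = 9)$matches
#' @export
find_exact_matches <- function(query_genome, subject_genome, min_length) {
  stopifnot(inherits(query_genome, "gbdp_genome"),
            inherits(subject_genome, "gbdp_genome"))
  if (min_length < 8)
    stop("min_length must be at least 8")
  min_length <- as.integer(min_length)
  k <- min(min_length, 32L)
  res <- list()
  for (qr in names(query_genome$replicons)) {
    xseq <- query_genome$replicons[[qr]]
    xraw <- charToRaw(xseq)
    for (sr in names(subject_genome$replicons)) {
      sseq <- subject_genome$replicons[[sr]]
      slen <- nchar(sseq)
      # forward strand
      fwd <- scan_diagonals(xraw, charToRaw(sseq),
                            anchored_diagonals(xseq, sseq, k), min_length)
      if (!is.null(fwd)) {
        res[[length(res) + 1L]] <- data.frame(
          q_replicon = qr, s_replicon = sr,
          q_start = fwd$q_start, q_end = fwd$q_start + fwd$len,
          s_start = fwd$s_start, s_end = fwd$s_start + fwd$len,
          strand = "+", length = fwd$len, identities = fwd$len,
          score = fwd$len, evalue = NA_real_, stringsAsFactors = FALSE)
      }
      # reverse strand: match query against the reverse complement of the
      # subject, then reflect subject coordinates to the forward strand
      rcs <- revcomp(sseq)
      rev <- scan_diagonals(xraw, charToRaw(rcs),
                            anchored_diagonals(xseq, rcs, k), min_length)
      if (!is.null(rev)) {
        res[[length(res) + 1L]] <- data.frame(
          q_replicon = qr, s_replicon = sr,
          q_start = rev$q_start, q_end = rev$q_start + rev$len,
          s_start = slen - rev$s_start - rev$len,
          s_end = slen - rev$s_start,
          strand = "-", length = rev$len, identities = rev$len,
          score = rev$len, evalue = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  m <- if (length(res)) sort_matches(do.call(rbind, res)) else empty_matches()
  match_set(query_genome, subject_genome, m)
}
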