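#' Lander-Waterman read count for a target retained proportion
#'
#' Number of reads of fixed length \code{read_length} whose expected
#' Lander-Waterman coverage fraction \eqn{1 - e^{-NL/G}} equals the target
#' proportion: \eqn{N = \lceil G \cdot (-\ln(1 - p)) / L \rceil}.
#'
#' @param genome_length replicon length G in bp.
#' @param proportion target retained fraction p, strictly between 0 and 1.
#' @param read_length fixed read length L in bp (default 700, a realistic
#'   single read length).
#' @return integer read count.
#' @examples
#' lw_read_count(700000, 0.99, 700)  # ceil(1000 * ln 100) = 4606
#' @export
lw_read_count <- function(genome_length, proportion, read_length = 700L) {
  stopifnot(genome_length >= 1, read_length >= 1)
  if (proportion <= 0 || proportion >= 1)
    stop("proportion must be strictly between 0 and 1")
  as.integer(ceiling(genome_length * (-log(1 - proportion)) / read_length))
}

#' Simulate incomplete sequencing of a genome
#'
#' Emulates a partially sequenced genome: per replicon, every position
#' starts 'not sequenced'; the Lander-Waterman read count for the target
#' proportion is drawn as uniformly placed read start positions (with
#' replacement), each marking \code{read_length} downstream positions as
#' 'sequenced' (reads truncate at the linear replicon end); unsequenced
#' positions are then removed, leaving disjoint contigs. Reads are
#' error-free and the contigs are exact substrings of the input, so the
#' simulation isolates the effect of missing sequence from sequencing
#' error.
#'
#' @param g a \code{gbdp_genome}.
#' @param proportion target retained fraction in (0, 1).
#' @param read_length fixed read length in bp (default 700).
#' @return a \code{gbdp_genome} of contigs named
#'   \code{<replicon_id>_ctg<k>}, with attributes \code{"retained_fraction"}
#'   (retained bp / original bp) and \code{"n_contigs"}. Uses the current
#'   RNG state; call \code{set.seed} for reproducibility.
#' @export
simulate_incomplete <- function(g, proportion, read_length = 700L) {
  stopifnot(inherits(g, "gbdp_genome"))
  contigs <- character(0L)
  retained <- 0
  for (rep_id in names(g$replicons)) {
    s <- g$replicons[[rep_id]]
    L <- nchar(s)
    n_reads <- lw_read_count(L, proportion, read_length)
    covered <- logical(L)
    starts <- sample.int(L, n_reads, replace = TRUE)
    for (st in starts) covered[st:min(L, st + read_length - 1L)] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    begins <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (length(runs)) {
      ctg <- substring(s, begins[runs], ends[runs])
      names(ctg) <- paste0(rep_id, "_ctg", seq_along(runs))
      contigs <- c(contigs, ctg)
      retained <- retained + sum(r$lengths[runs])
    }
  }
  if (length(contigs) == 0L)
    stop("simulation retained no sequence; proportion too small for this genome")
  out <- genome(paste0(g$genome_id, "_incomplete"), contigs)
  attr(out, "retained_fraction") <- retained / g$total_length
  attr(out, "n_contigs") <- length(contigs)
  out
}

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic pair of related genomes
#'
#' Emulates two closely related strains so the whole pipeline is testable
#' without downloads: genome A is sampled uniformly over \{A,C,G,T\};
#' genome B derives from A by iid point substitutions (each mutated site
#' switches to a uniformly chosen different base), a configurable number of
#' segment deletions, and optional extra copies of a repeat segment
#' appended to B (shared repeats are what the trimming algorithm must
#' neutralize). Realized event counts are returned so tests can check
#' calibration.
#'
#' @param genome_length length of genome A in bp.
#' @param substitution_rate per-site substitution probability in [0, 1].
#' @param n_segment_deletions number of non-overlapping segments deleted
#'   from B.
#' @param deletion_length length of each deleted segment in bp.
#' @param repeat_copies extra copies of a repeat segment appended to B.
#' @param repeat_length length of the repeat segment in bp.
#' @return list with \code{genome_a}, \code{genome_b} (single-replicon
#'   \code{gbdp_genome}s) and \code{report} (realized substitution count,
#'   deleted bp, repeat bp). Uses the current RNG state.
#' @export
generate_genome_pair <- function(genome_length = 50000L,
                                 substitution_rate = 0.01,
                                 n_segment_deletions = 0L,
                                 deletion_length = 1000L,
                                 repeat_copies = 0L,
                                 repeat_length = 500L) {
  stopifnot(genome_length >= 100,
            substitution_rate >= 0, substitution_rate <= 1,
            n_segment_deletions >= 0, repeat_copies >= 0)
  if (n_segment_deletions * deletion_length >= genome_length)
    stop("deletions would remove the whole genome")
  a_chars <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
  b_chars <- a_chars
  mut <- which(stats::runif(genome_length) < substitution_rate)
  for (i in mut) {
    b_chars[i] <- sample(setdiff(c("A", "C", "G", "T"), b_chars[i]), 1L)
  }
  deleted_bp <- 0L
  if (n_segment_deletions > 0L) {
    # partition B into equal blocks and delete one segment inside each of
    # n random blocks, guaranteeing non-overlap
    blocks <- floor(genome_length / n_segment_deletions)
    if (blocks <= deletion_length)
      stop("deletions too long to place without overlap")
    del <- logical(genome_length)
    for (k in seq_len(n_segment_deletions)) {
      lo <- (k - 1L) * blocks + 1L
      st <- lo + sample.int(blocks - deletion_length, 1L) - 1L
      del[st:(st + deletion_length - 1L)] <- TRUE
    }
    b_chars <- b_chars[!del]
    deleted_bp <- sum(del)
  }
  b_seq <- paste(b_chars, collapse = "")
  repeat_bp <- 0L
  if (repeat_copies > 0L) {
    st <- sample.int(nchar(b_seq) - repeat_length, 1L)
    rep_seq <- substring(b_seq, st, st + repeat_length - 1L)
    b_seq <- paste0(b_seq, paste(rep(rep_seq, repeat_copies), collapse = ""))
    repeat_bp <- repeat_copies * repeat_length
  }
  list(
    genome_a = genome("synthA", c(chr = paste(a_chars, collapse = ""))),
    genome_b = genome("synthB", c(chr = b_seq)),
    report = list(substitutions = length(mut),
                  deleted_bp = deleted_bp,
                  repeat_bp = repeat_bp))
}
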