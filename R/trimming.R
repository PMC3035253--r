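# interval helpers: intervals are numeric matrices with columns start, end
# (0-based half-open), kept disjoint and sorted within a union

iv_empty <- function() matrix(numeric(0), ncol = 2L,
                              dimnames = list(NULL, c("start", "end")))

# fragments of [s, e) not covered by the disjoint sorted union u
iv_subtract <- function(s, e, u) {
  if (nrow(u) == 0L) return(matrix(c(s, e), ncol = 2L))
  frags <- iv_empty()
  cur <- s
  for (i in seq_len(nrow(u))) {
    us <- u[i, 1L]; ue <- u[i, 2L]
    if (ue <= cur) next
    if (us >= e) break
    if (us > cur) frags <- rbind(frags, c(cur, min(us, e)))
    cur <- max(cur, ue)
    if (cur >= e) break
  }
  if (cur < e) frags <- rbind(frags, c(cur, e))
  frags
}

# insert [s, e) into the union, merging neighbours
iv_insert <- function(u, s, e) {
  u <- rbind(u, c(s, e))
  u <- u[order(u[, 1L]), , drop = FALSE]
  out <- u[1L, , drop = FALSE]
  if (nrow(u) > 1L) for (i in 2L:nrow(u)) {
    k <- nrow(out)
    if (u[i, 1L] <= out[k, 2L]) {
      out[k, 2L] <- max(out[k, 2L], u[i, 2L])
    } else out <- rbind(out, u[i, , drop = FALSE])
  }
  out
}

union_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0)
  u <- iv_empty()
  for (i in order(starts)) u <- iv_insert(u, starts[i], ends[i])
  sum(u[, 2L] - u[, 1L])
}

new_reduced <- function(set, matches, h_total, i_total, reduction,
                        provenance = NULL, footprints = NULL) {
  structure(
    list(query_genome_id = set$query_genome_id,
         subject_genome_id = set$subject_genome_id,
         matches = matches,
         h_total = h_total, i_total = i_total,
         reduction = reduction, provenance = provenance,
         footprints = footprints,
         query_length = set$query_length,
         subject_length = set$subject_length),
    class = "gbdp_reduced")
}

#' @export
print.gbdp_reduced <- function(x, ...) {
  cat("gbdp reduced match set ", x$query_genome_id, " -> ",
      x$subject_genome_id, " (", x$reduction, "): ",
      nrow(x$matches), " match(es), H = ", format(x$h_total),
      ", I = ", format(x$i_total), "\n", sep = "")
  invisible(x)
}

#' Greedy-with-trimming overlap removal
#'
#' Reduces a directed match set to parts that are non-overlapping in both
#' genomes. Matches are visited in descending score order (ties: longer
#' first, then lexicographic coordinates); each candidate is clipped against
#' the union of already-accepted query intervals and accepted subject
#' intervals. Clipping removes the overlapping prefix/suffix; if an accepted
#' interval splits a candidate internally, the single longest remaining
#' fragment is kept. When one side of a match is clipped, the other side's
#' interval, the alignment length and the identity count are scaled
#' proportionally to the retained fraction (identities rounded down).
#' Fully covered candidates are dropped. Because a greedy pass accepts each
#' match only after both of its sides are disjoint from everything accepted
#' before, the output has zero pairwise overlap on the query side and on the
#' subject side, which removes the multiplicative effect of repetitive
#' sequences on the distance components.
#'
#' @param set a \code{gbdp_matchset}.
#' @return an object of class \code{"gbdp_reduced"} with elements
#'   \code{matches} (the trimmed matches), \code{h_total} (sum of retained
#'   alignment lengths), \code{i_total} (sum of retained identities) and
#'   \code{provenance} (per output match: source row in the input and bp
#'   clipped from each query end).
#' @export
greedy_trim <- function(set) {
  stopifnot(inherits(set, "gbdp_matchset"))
  m <- set$matches
  if (nrow(m) == 0L)
    return(new_reduced(set, m, 0, 0, "trim",
                       provenance = data.frame(source = integer(),
                                               q_trim_left = numeric(),
                                               q_trim_right = numeric())))
  ord <- order(-m$score, -m$length, m$q_replicon, m$q_start, m$q_end,
               m$s_replicon, m$s_start, m$strand)
  q_union <- list(); s_union <- list()
  out <- vector("list", nrow(m))
  prov <- vector("list", nrow(m))
  for (idx in ord) {
    r <- m[idx, ]
    qs <- r$q_start; qe <- r$q_end; ss <- r$s_start; se <- r$s_end
    len <- r$length; ident <- r$identities; score <- r$score
    f_total <- 1
    dropped <- FALSE
    qu <- q_union[[r$q_replicon]] %||% iv_empty()
    su <- s_union[[r$s_replicon]] %||% iv_empty()

    clip <- function(cs, ce, u) {
      frags <- iv_subtract(cs, ce, u)
      if (nrow(frags) == 0L) return(NULL)
      lens <- frags[, 2L] - frags[, 1L]
      best <- which.max(lens)           # ties: which.max takes the leftmost
      frags[best, ]
    }

    # pass 1: query side; pass 2: subject side; pass 3: query re-check.
    # Each pass shrinks both sides to sub-intervals, so a side once disjoint
    # stays disjoint and the fixed point is reached within these passes.
    for (pass in 1:3) {
      if (pass %% 2L == 1L) {           # clip against query union
        frag <- clip(qs, qe, qu)
        if (is.null(frag) || frag[2L] - frag[1L] < 1) { dropped <- TRUE; break }
        qlen <- qe - qs
        fL <- (frag[1L] - qs) / qlen; fR <- (qe - frag[2L]) / qlen
        if (fL == 0 && fR == 0) { if (pass == 3L) break else next }
        f <- (frag[2L] - frag[1L]) / qlen
        slen <- se - ss
        tL <- round(slen * fL); tR <- round(slen * fR)
        if (r$strand == "+") { ss2 <- ss + tL; se2 <- se - tR }
        else { ss2 <- ss + tR; se2 <- se - tL }
        if (se2 - ss2 < 1) { dropped <- TRUE; break }
        qs <- frag[1L]; qe <- frag[2L]; ss <- ss2; se <- se2
        f_total <- f_total * f
      } else {                          # clip against subject union
        frag <- clip(ss, se, su)
        if (is.null(frag) || frag[2L] - frag[1L] < 1) { dropped <- TRUE; break }
        slen <- se - ss
        fL <- (frag[1L] - ss) / slen; fR <- (se - frag[2L]) / slen
        if (fL == 0 && fR == 0) next
        f <- (frag[2L] - frag[1L]) / slen
        qlen <- qe - qs
        tL <- round(qlen * fL); tR <- round(qlen * fR)
        if (r$strand == "+") { qs2 <- qs + tL; qe2 <- qe - tR }
        else { qs2 <- qs + tR; qe2 <- qe - tL }
        if (qe2 - qs2 < 1) { dropped <- TRUE; break }
        ss <- frag[1L]; se <- frag[2L]; qs <- qs2; qe <- qe2
        f_total <- f_total * f
      }
    }
    if (dropped) next
    new_len <- max(round(len * f_total), qe - qs, se - ss)
    new_id <- min(floor(ident * f_total), new_len)
    out[[idx]] <- data.frame(
      q_replicon = r$q_replicon, s_replicon = r$s_replicon,
      q_start = qs, q_end = qe, s_start = ss, s_end = se,
      strand = r$strand, length = new_len, identities = new_id,
      score = score * f_total, evalue = r$evalue,
      stringsAsFactors = FALSE)
    prov[[idx]] <- data.frame(source = idx,
                              q_trim_left = qs - m$q_start[idx],
                              q_trim_right = m$q_end[idx] - qe)
    q_union[[r$q_replicon]] <- iv_insert(qu, qs, qe)
    s_union[[r$s_replicon]] <- iv_insert(su, ss, se)
  }
  keep <- !vapply(out, is.null, logical(1L))
  matches <- if (any(keep)) sort_matches(do.call(rbind, out[keep])) else empty_matches()
  provenance <- if (any(keep)) do.call(rbind, prov[keep]) else
    data.frame(source = integer(), q_trim_left = numeric(), q_trim_right = numeric())
  new_reduced(set, matches, sum(matches$length), sum(matches$identities),
              "trim", provenance = provenance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coverage (no-trimming) reduction
#'
#' The coverage variant of the distance computation skips greedy trimming.
#' In the default \code{"union"} mode the match footprints are collapsed so
#' every genomic position counts once per side: with \eqn{|U_q|} and
#' \eqn{|U_s|} the lengths of the query- and subject-side footprint unions
#' and \eqn{L_q}, \eqn{L_s} the raw span sums, the totals are scaled by
#' \eqn{c = \min(1, |U_q|/L_q, |U_s|/L_s)}, giving \eqn{H = c \sum length}
#' and \eqn{I = c \sum identities}; the identity fraction \eqn{I/H} is
#' preserved and overlap-free input is returned with \eqn{c = 1}, identical
#' to trimming. \code{"raw"} mode sums lengths and identities as-is
#' (overlaps counted multiply, as a literal no-trimming reading; the
#' resulting similarity can exceed 1 for repeat-rich genomes, in which case
#' the distance clamps at 0).
#'
#' @param set a \code{gbdp_matchset}.
#' @param mode \code{"union"} (default) or \code{"raw"}.
#' @return a \code{"gbdp_reduced"} object; \code{footprints} holds the
#'   per-replicon footprint unions in union mode.
#' @export
coverage_reduce <- function(set, mode = c("union", "raw")) {
  stopifnot(inherits(set, "gbdp_matchset"))
  mode <- match.arg(mode)
  m <- set$matches
  if (nrow(m) == 0L)
    return(new_reduced(set, m, 0, 0, paste0("coverage-", mode)))
  if (mode == "raw")
    return(new_reduced(set, m, sum(m$length), sum(m$identities),
                       "coverage-raw"))
  uq_len <- sum(vapply(split(m, m$q_replicon), function(g)
    union_length(g$q_start, g$q_end), numeric(1L)))
  us_len <- sum(vapply(split(m, m$s_replicon), function(g)
    union_length(g$s_start, g$s_end), numeric(1L)))
  lq <- sum(m$q_end - m$q_start)
  ls <- sum(m$s_end - m$s_start)
  cfac <- min(1, uq_len / lq, us_len / ls)
  footprints <- list(
    query = lapply(split(m, m$q_replicon), function(g) {
      u <- iv_empty()
      for (i in order(g$q_start)) u <- iv_insert(u, g$q_start[i], g$q_end[i])
      u
    }),
    subject = lapply(split(m, m$s_replicon), function(g) {
      u <- iv_empty()
      for (i in order(g$s_start)) u <- iv_insert(u, g$s_start[i], g$s_end[i])
      u
    }))
  new_reduced(set, m, cfac * sum(m$length), cfac * sum(m$identities),
              paste0("coverage-", mode), footprints = footprints)
}

#' Reduce a match set by trimming or coverage
#' @param set a \code{gbdp_matchset}.
#' @param reduction \code{"trim"} or \code{"coverage"}.
#' @param coverage_mode passed to \code{\link{coverage_reduce}}.
#' @return a \code{"gbdp_reduced"} object.
#' @export
reduce_matches <- function(set, reduction = c("trim", "coverage"),
                           coverage_mode = "union") {
  reduction <- match.arg(reduction)
  if (reduction == "trim") greedy_trim(set)
  else coverage_reduce(set, coverage_mode)
}
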