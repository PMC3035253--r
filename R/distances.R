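#' Specify one of the ten GBDP distance functions
#'
#' A distance function is determined by the formula family, the
#' normalizing denominator \eqn{\lambda}, and an optional logarithmic
#' transform. With \eqn{H_{xy}}/\eqn{I_{xy}} the total match length and
#' total identical base pairs from querying x against y (and vice versa),
#' the base similarities are
#' \deqn{s_1 = (H_{xy}+H_{yx})/\lambda, \quad
#'       s_2 = (I_{xy}+I_{yx})/(H_{xy}+H_{yx}), \quad
#'       s_3 = (I_{xy}+I_{yx})/\lambda,}
#' with \eqn{\lambda} either the sum of the two genome lengths or twice the
#' length of the shorter genome; the distance is \eqn{d = 1 - s} (clamped to
#' [0, 1]) and the log variant is \eqn{-\ln(1 - d)}. Family 2 is the only
#' one independent of genome length. The canonical GBDP index runs 0-9:
#' indices 0-3 are family 1, 4-5 family 2, 6-9 family 3; within that,
#' 0, 2, 6, 8 use the length sum and 1, 3, 7, 9 twice the minimum length,
#' and 2, 3, 5, 8, 9 are the log variants.
#'
#' @param family formula family, 1, 2 or 3.
#' @param denominator \code{"sum_lengths"} or \code{"twice_min_length"}
#'   (ignored by family 2, which has no length term).
#' @param log_transform logical.
#' @param reduction \code{"trim"} (greedy-with-trimming) or
#'   \code{"coverage"}.
#' @param evalue_filter drop matches with e-value above
#'   \code{evalue_threshold} before reduction.
#' @param evalue_threshold e-value cutoff used when filtering.
#' @return an object of class \code{"gbdp_spec"} whose \code{gbdp_index}
#'   element is the canonical 0-9 index.
#' @examples
#' gbdp_spec(family = 3, denominator = "sum_lengths")  # index 6
#' @export
gbdp_spec <- function(family = 3L,
                      denominator = c("sum_lengths", "twice_min_length"),
                      log_transform = FALSE,
                      reduction = c("trim", "coverage"),
                      evalue_filter = FALSE,
                      evalue_threshold = 1e-2) {
  family <- as.integer(family)
  stopifnot(family %in% 1:3)
  denominator <- match.arg(denominator)
  reduction <- match.arg(reduction)
  if (family == 2L) denominator <- "sum_lengths"  # unused; normalized form
  idx <- gbdp_index_of(family, denominator, log_transform)
  structure(
    list(family = family, denominator = denominator,
         log_transform = isTRUE(log_transform),
         reduction = reduction,
         evalue_filter = isTRUE(evalue_filter),
         evalue_threshold = evalue_threshold,
         gbdp_index = idx),
    class = "gbdp_spec")
}

gbdp_index_of <- function(family, denominator, log_transform) {
  two_min <- denominator == "twice_min_length"
  lg <- isTRUE(log_transform)
  if (family == 1L) {
    if (!lg) (if (two_min) 1L else 0L) else (if (two_min) 3L else 2L)
  } else if (family == 2L) {
    if (!lg) 4L else 5L
  } else {
    if (!lg) (if (two_min) 7L else 6L) else (if (two_min) 9L else 8L)
  }
}

#' Build a distance specification from its canonical 0-9 index
#' @param index integer 0-9.
#' @param ... further arguments (\code{reduction}, \code{evalue_filter},
#'   ...) passed to \code{\link{gbdp_spec}}.
#' @return a \code{"gbdp_spec"}.
#' @export
gbdp_spec_from_index <- function(index, ...) {
  index <- as.integer(index)
  stopifnot(index >= 0L, index <= 9L)
  family <- c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 3L)[index + 1L]
  denom <- if (index %in% c(1L, 3L, 7L, 9L)) "twice_min_length" else "sum_lengths"
  lg <- index %in% c(2L, 3L, 5L, 8L, 9L)
  gbdp_spec(family = family, denominator = denom, log_transform = lg, ...)
}

#' @export
print.gbdp_spec <- function(x, ...) {
  cat("GBDP distance function ", x$gbdp_index, ": formula (", x$family,
      "), lambda = ", if (x$family == 2L) "none" else x$denominator,
      if (x$log_transform) ", log-transformed" else "",
      ", reduction = ", x$reduction,
      if (x$evalue_filter) paste0(", e-value filter <= ", x$evalue_threshold) else "",
      "\n", sep = "")
  invisible(x)
}

#' Distance components from a pair of reduced match sets
#'
#' Collects the quantities entering every distance formula: total match
#' length and total identical base pairs per direction, plus the two genome
#' lengths.
#'
#' @param reduced_xy,reduced_yx \code{"gbdp_reduced"} objects for the two
#'   directions of the same genome pair (x queried against y, and y against
#'   x).
#' @param genome_x,genome_y the \code{gbdp_genome} objects.
#' @return a \code{"gbdp_components"} list with \code{h_xy, h_yx, i_xy,
#'   i_yx, len_x, len_y}.
#' @export
compute_components <- function(reduced_xy, reduced_yx, genome_x, genome_y) {
  stopifnot(inherits(reduced_xy, "gbdp_reduced"),
            inherits(reduced_yx, "gbdp_reduced"))
  if (reduced_xy$query_genome_id != genome_x$genome_id ||
      reduced_xy$subject_genome_id != genome_y$genome_id)
    stop("reduced_xy does not match the given genome pair (expected ",
         genome_x$genome_id, " -> ", genome_y$genome_id, ")")
  if (reduced_yx$query_genome_id != genome_y$genome_id ||
      reduced_yx$subject_genome_id != genome_x$genome_id)
    stop("reduced_yx does not match the given genome pair (expected ",
         genome_y$genome_id, " -> ", genome_x$genome_id, ")")
  gbdp_components(h_xy = reduced_xy$h_total, h_yx = reduced_yx$h_total,
                  i_xy = reduced_xy$i_total, i_yx = reduced_yx$i_total,
                  len_x = genome_x$total_length, len_y = genome_y$total_length)
}

#' Construct distance components directly
#' @param h_xy,h_yx total match length per direction (bp).
#' @param i_xy,i_yx total identical base pairs per direction (bp).
#' @param len_x,len_y genome lengths (bp).
#' @return a \code{"gbdp_components"} list.
#' @export
gbdp_components <- function(h_xy, h_yx, i_xy, i_yx, len_x, len_y) {
  stopifnot(len_x > 0, len_y > 0,
            h_xy >= 0, h_yx >= 0,
            i_xy >= 0, i_yx >= 0,
            i_xy <= h_xy, i_yx <= h_yx)
  structure(list(h_xy = h_xy, h_yx = h_yx, i_xy = i_xy, i_yx = i_yx,
                 len_x = len_x, len_y = len_y),
            class = "gbdp_components")
}

#' Genome-to-genome distance from components
#'
#' Evaluates one GBDP distance function on a set of components. Degenerate
#' input with no matches at all (\eqn{H_{xy} + H_{yx} = 0}) yields the
#' maximal distance 1 for every family (family 2's 0/0 is defined as
#' maximally distant). Similarity ratios above 1 (possible in raw coverage
#' mode with repeats) clamp the distance to 0 rather than going negative.
#' For the log transform the distance is first capped at \eqn{1 - 10^{-12}}
#' so the transform stays finite.
#'
#' @param components a \code{"gbdp_components"} object.
#' @param spec a \code{"gbdp_spec"}.
#' @return a \code{"gbdp_pair_result"} list with elements \code{distance},
#'   \code{spec} and \code{components}.
#' @examples
#' cmp <- gbdp_components(400, 500, 360, 450, 1000, 800)
#' ggd(cmp, gbdp_spec(family = 2))$distance  # 1 - 810/900 = 0.1
#' @export
ggd <- function(components, spec) {
  stopifnot(inherits(components, "gbdp_components"),
            inherits(spec, "gbdp_spec"))
  with(components, {
    hsum <- h_xy + h_yx
    isum <- i_xy + i_yx
    lambda <- if (spec$denominator == "twice_min_length")
      2 * min(len_x, len_y) else len_x + len_y
    if (hsum == 0) {
      d <- 1
    } else {
      if (spec$family == 2L && isum == hsum)
        warning("all matches are identity-only (MUM-like input); ",
                "family 2 distance is identically 0")
      s <- switch(as.character(spec$family),
                  "1" = hsum / lambda,
                  "2" = isum / hsum,
                  "3" = isum / lambda)
      d <- min(max(1 - s, 0), 1)
    }
    if (spec$log_transform)
      d <- -log(1 - min(d, 1 - 1e-12))
    structure(list(distance = d, spec = spec, components = components),
              class = "gbdp_pair_result")
  })
}

#' @export
print.gbdp_pair_result <- function(x, ...) {
  cat("GGD = ", format(x$distance), " (GBDP index ", x$spec$gbdp_index,
      ")\n", sep = "")
  invisible(x)
}

#' Evaluate all ten GBDP distance functions on one component set
#' @param components a \code{"gbdp_components"}.
#' @param reduction recorded in each returned spec (informational).
#' @return named numeric vector of length 10 (names \code{"d0"}..\code{"d9"}).
#' @export
ggd_all <- function(components, reduction = "trim") {
  v <- vapply(0:9, function(i)
    ggd(components, gbdp_spec_from_index(i, reduction = reduction))$distance,
    numeric(1L))
  names(v) <- paste0("d", 0:9)
  v
}

#' Pairwise GGD matrix over a collection of genomes
#'
#' Computes one symmetric distance matrix per requested GBDP index. The
#' match sets are obtained from \code{matchset_provider(x, y)}, a function
#' returning the directed \code{gbdp_matchset} for querying genome x
#' against genome y; both directions of each pair are requested once. The
#' provider defaults to the internal exact matcher. The e-value filter and
#' the reduction declared in \code{spec} are applied to every directed set.
#' A provider failure for a pair leaves that entry \code{NA} and is recorded
#' in the \code{"failures"} attribute; the run continues.
#'
#' @param genomes list of \code{gbdp_genome} objects.
#' @param spec a \code{"gbdp_spec"} (its reduction/filter settings apply to
#'   all indices).
#' @param matchset_provider function(genome_x, genome_y) ->
#'   \code{gbdp_matchset}; default uses \code{\link{find_exact_matches}}
#'   with \code{min_length}.
#' @param indices GBDP indices to compute (default all ten).
#' @param min_length minimum match length for the default internal matcher.
#' @return a list of symmetric matrices, one per index (names
#'   \code{"d<index>"}), with genome ids as dimnames, zero diagonal by
#'   construction of self-comparison, and attributes \code{"failures"}
#'   (data.frame of failed pairs and messages) and \code{"pair_stats"}
#'   (per directed set: matches parsed, matches removed by the e-value
#'   filter, total match bp before and after reduction).
#' @export
distance_matrix <- function(genomes, spec = gbdp_spec(),
                            matchset_provider = NULL,
                            indices = 0:9, min_length = 20L) {
  stopifnot(length(genomes) >= 2L)
  ids <- vapply(genomes, function(g) g$genome_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  names(genomes) <- ids
  if (is.null(matchset_provider))
    matchset_provider <- function(x, y) find_exact_matches(x, y, min_length)
  n <- length(genomes)
  mats <- lapply(indices, function(i)
    matrix(0, n, n, dimnames = list(ids, ids)))
  names(mats) <- paste0("d", indices)
  failures <- data.frame(genome_a = character(), genome_b = character(),
                         message = character(), stringsAsFactors = FALSE)
  stats_rows <- list()
  specs <- lapply(indices, function(i)
    gbdp_spec_from_index(i, reduction = spec$reduction,
                         evalue_filter = spec$evalue_filter,
                         evalue_threshold = spec$evalue_threshold))
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    res <- tryCatch({
      sxy <- matchset_provider(genomes[[a]], genomes[[b]])
      syx <- matchset_provider(genomes[[b]], genomes[[a]])
      n_parsed <- c(nrow(sxy$matches), nrow(syx$matches))
      if (spec$evalue_filter) {
        sxy <- suppressWarnings(filter_by_evalue(sxy, spec$evalue_threshold))
        syx <- suppressWarnings(filter_by_evalue(syx, spec$evalue_threshold))
      }
      rxy <- reduce_matches(sxy, spec$reduction)
      ryx <- reduce_matches(syx, spec$reduction)
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        query = c(ids[a], ids[b]), subject = c(ids[b], ids[a]),
        n_matches = n_parsed,
        n_removed_by_filter = n_parsed - c(nrow(sxy$matches), nrow(syx$matches)),
        bp_input = c(sum(sxy$matches$length), sum(syx$matches$length)),
        bp_reduced = c(rxy$h_total, ryx$h_total),
        stringsAsFactors = FALSE)
      cmp <- compute_components(rxy, ryx, genomes[[a]], genomes[[b]])
      vapply(specs, function(sp)
        suppressWarnings(ggd(cmp, sp)$distance), numeric(1L))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(genome_a = ids[a], genome_b = ids[b],
                                   message = conditionMessage(res),
                                   stringsAsFactors = FALSE))
      for (k in seq_along(mats)) mats[[k]][a, b] <- mats[[k]][b, a] <- NA_real_
    } else {
      for (k in seq_along(mats)) mats[[k]][a, b] <- mats[[k]][b, a] <- res[k]
    }
  }
  attr(mats, "failures") <- failures
  attr(mats, "pair_stats") <- if (length(stats_rows))
    do.call(rbind, stats_rows) else NULL
  mats
}

#' Write a distance matrix in PHYLIP square format
#' @param mat symmetric numeric matrix with dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_phylip <- function(mat, path) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(mat)), con)
  nm <- rownames(mat)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste0(formatC(substr(nm[i], 1L, 10L), width = -10L), "  ",
                      paste(formatC(mat[i, ], format = "f", digits = 6),
                            collapse = "  ")), con)
  }
  invisible(path)
}

#' Long-form TSV of pairwise distances
#' @param mats list of matrices as returned by \code{\link{distance_matrix}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_distance_tsv <- function(mats, path) {
  rows <- list()
  for (nm in names(mats)) {
    m <- mats[[nm]]
    idx <- which(upper.tri(m), arr.ind = TRUE)
    rows[[nm]] <- data.frame(
      genome_a = rownames(m)[idx[, 1L]],
      genome_b = colnames(m)[idx[, 2L]],
      gbdp_index = as.integer(sub("^d", "", nm)),
      distance = m[idx], stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
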