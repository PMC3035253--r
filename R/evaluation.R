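#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation, the headline statistic for comparing
#' distance functions against DDH: it uses ranks only, so it is invariant
#' under any strictly monotone transform (the log-transformed distance
#' variants correlate identically to their base variants), and it is robust
#' to the saturation of some distance formulas. DDH tables contain tied
#' values, hence tau-b.
#'
#' @param a,b equal-length numeric vectors, length >= 2, neither constant.
#' @return tau in [-1, 1].
#' @export
kendall_tau <- function(a, b) {
  check_paired(a, b)
  stats::cor(a, b, method = "kendall")
}

#' Pearson product-moment correlation
#' @param a,b equal-length numeric vectors, length >= 2, neither constant.
#' @return r in [-1, 1].
#' @export
pearson_r <- function(a, b) {
  check_paired(a, b)
  stats::cor(a, b, method = "pearson")
}

check_paired <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 2L) stop("need at least 2 paired observations")
  if (anyNA(a) || anyNA(b)) stop("missing values in paired vectors")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant vector")
  invisible(TRUE)
}

#' Euclidean distance between two distance vectors
#'
#' Used to quantify how far the distances inferred from incompletely
#' sequenced genomes drift from those computed on the complete genomes.
#' Unnormalized: \eqn{\sqrt{\sum_i (a_i - b_i)^2}}.
#'
#' @param a,b equal-length numeric vectors.
#' @return non-negative scalar.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  sqrt(sum((a - b)^2))
}

#' Uncorrected p-distance matrix from aligned sequences
#'
#' Computes pairwise uncorrected ("p") distances from a multiple alignment
#' (e.g. of 16S rRNA genes): for each pair, the proportion of differing
#' sites among the sites comparable in both sequences. Columns holding a
#' gap, \code{N} or any other ambiguity character in either sequence of the
#' pair are excluded (pairwise-deletion semantics); \code{U} is treated as
#' \code{T}. A pair with zero comparable sites gets \code{NA}.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences, or a path to an aligned FASTA file.
#' @return symmetric numeric matrix with zero diagonal.
#' @examples
#' p_distance_matrix(c(s1 = "ACGT", s2 = "ACGA", s3 = "AC-T"))
#' @export
p_distance_matrix <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) {
    set <- Biostrings::readBStringSet(alignment)
    alignment <- stats::setNames(as.character(set),
                                 sub("\\s.*$", "", names(set)))
  }
  seqs <- toupper(as.character(alignment))
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 aligned sequences")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("aligned sequences must have equal length")
  seqs <- chartr("U", "T", seqs)
  ids <- names(alignment) %||% paste0("seq", seq_len(n))
  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  valid <- lapply(chars, function(v) v %in% c("A", "C", "G", "T"))
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[[i]] & valid[[j]]
    nv <- sum(ok)
    p <- if (nv == 0L) NA_real_ else sum(chars[[i]][ok] != chars[[j]][ok]) / nv
    out[i, j] <- out[j, i] <- p
  }
  out
}

#' Correlation report for distance variants against a reference
#'
#' Computes Kendall tau-b and Pearson r of each distance column against a
#' reference vector (DDH percentages or 16S p-distances), one row per
#' distance variant.
#'
#' @param distances data.frame or named list of equal-length numeric
#'   vectors (e.g. one per GBDP index).
#' @param reference numeric reference vector.
#' @return data.frame with columns \code{variant}, \code{tau}, \code{r},
#'   \code{n}.
#' @export
correlation_report <- function(distances, reference) {
  distances <- as.data.frame(distances)
  do.call(rbind, lapply(names(distances), function(nm) {
    data.frame(variant = nm,
               tau = kendall_tau(distances[[nm]], reference),
               r = pearson_r(distances[[nm]], reference),
               n = length(reference),
               stringsAsFactors = FALSE)
  }))
}
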