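#' Construct a genome object
#'
#' A genome is an ordered named set of replicon sequences (chromosome plus
#' any plasmids or draft contigs). Sequences are stored uppercase over the
#' alphabet \{A, C, G, T, N\}; any other character (including IUPAC ambiguity
#' codes) is normalized to \code{N} with a warning, and \code{N} never
#' participates in exact matching downstream.
#'
#' All coordinates used in this package are 0-based, half-open
#' \code{[start, end)} on the forward strand of each replicon.
#'
#' @param genome_id short label for the genome.
#' @param sequences named character vector of replicon sequences; names are
#'   replicon ids and must be unique.
#' @return An object of class \code{"gbdp_genome"}: a list with elements
#'   \code{genome_id}, \code{replicons} (named character vector) and
#'   \code{total_length} (sum of replicon lengths in bp).
#' @examples
#' g <- genome("toy", c(chr = "ACGTACGT", pl = "GGGG"))
#' g$total_length
#' @export
genome <- function(genome_id, sequences) {
  if (length(sequences) == 0L)
    stop("genome must contain at least one replicon")
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every replicon needs a non-empty id")
  if (anyDuplicated(ids))
    stop("duplicate replicon id: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(sequences))
  if (any(!nzchar(seqs)))
    stop("replicon with empty sequence: ", ids[!nzchar(seqs)][1L])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    warning("characters outside {A,C,G,T,N} normalized to N in replicon(s): ",
            paste(ids[bad], collapse = ", "))
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  names(seqs) <- ids
  structure(
    list(genome_id = as.character(genome_id)[1L],
         replicons = seqs,
         total_length = sum(nchar(seqs))),
    class = "gbdp_genome")
}

#' @export
print.gbdp_genome <- function(x, ...) {
  cat("gbdp genome '", x$genome_id, "': ", length(x$replicons),
      " replicon(s), ", x$total_length, " bp total\n", sep = "")
  lens <- nchar(x$replicons)
  for (i in seq_along(lens))
    cat("  ", names(lens)[i], ": ", lens[i], " bp\n", sep = "")
  invisible(x)
}

#' Lengths of the replicons of a genome
#' @param g a \code{gbdp_genome}.
#' @return named integer vector of replicon lengths (bp).
#' @export
replicon_lengths <- function(g) {
  stopifnot(inherits(g, "gbdp_genome"))
  nchar(g$replicons)
}

#' Read a genome from a FASTA file
#'
#' Reads a (possibly multi-record) FASTA file into a \code{gbdp_genome}.
#' Replicons keep file order; lowercase is normalized to uppercase and
#' non-\code{ACGTN} characters to \code{N}. The record id is the first
#' whitespace-delimited token of the header line.
#'
#' @param path path to a FASTA file.
#' @param genome_id label for the genome; defaults to the file name without
#'   extension.
#' @return a \code{gbdp_genome}.
#' @export
read_fasta <- function(path, genome_id = NULL) {
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("no FASTA records in ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  genome(genome_id, seqs)
}

#' Write a genome to a FASTA file
#'
#' Round-trip guarantee: \code{read_fasta(write_fasta(g))} reproduces the
#' replicon ids, their order and their sequences exactly.
#'
#' @param g a \code{gbdp_genome}.
#' @param path output file path.
#' @param line_width sequence characters per line (default 60).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(g, path, line_width = 60L) {
  stopifnot(inherits(g, "gbdp_genome"), line_width >= 1L)
  if (length(g$replicons) == 0L)
    stop("refusing to write a genome with no replicons")
  set <- Biostrings::BStringSet(g$replicons)
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(line_width))
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' \code{N} maps to \code{N}; input must already be normalized to ACGTN.
#' @param s character scalar.
#' @return reverse-complemented string.
#' @export
revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(s, function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]),
                                     collapse = ""), character(1L),
                USE.NAMES = FALSE))
}

#' Read a calibration table of genome-pair distances and DDH values
#'
#' The table pairs an in-silico genome-to-genome distance (GGD) with the
#' wet-lab DNA-DNA hybridization percentage for the same genome pair; it is
#' the input to threshold optimization (\code{\link{ggd_threshold}}) and the
#' correlation analyses.
#'
#' @param path tab- or comma-separated text file with a header containing at
#'   least the columns \code{pair_id}, \code{ggd}, \code{ddh}.
#' @return data.frame with columns \code{pair_id} (character), \code{ggd}
#'   (numeric, finite, >= 0) and \code{ddh} (numeric, in [0, 100]).
#' @export
read_calibration_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty calibration table: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           colClasses = "character", fill = FALSE,
                           strip.white = TRUE)
  need <- c("pair_id", "ggd", "ddh")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("calibration table missing column(s): ", paste(miss, collapse = ", "))
  ggd <- suppressWarnings(as.numeric(tab$ggd))
  ddh <- suppressWarnings(as.numeric(tab$ddh))
  bad <- which(is.na(ggd) | is.na(ddh) | !is.finite(ggd))
  if (length(bad))
    stop("non-numeric ggd/ddh in calibration row ", bad[1L])
  bad <- which(ggd < 0)
  if (length(bad))
    stop("negative ggd in calibration row ", bad[1L])
  bad <- which(ddh < 0 | ddh > 100)
  if (length(bad))
    stop("ddh outside [0,100] in calibration row ", bad[1L])
  data.frame(pair_id = tab$pair_id, ggd = ggd, ddh = ddh,
             stringsAsFactors = FALSE)
}

#' Write a calibration table
#' @param records data.frame with columns \code{pair_id}, \code{ggd}, \code{ddh}.
#' @param path output path (tab-separated).
#' @return \code{path}, invisibly.
#' @export
write_calibration_table <- function(records, path) {
  stopifnot(all(c("pair_id", "ggd", "ddh") %in% names(records)))
  utils::write.table(records[, c("pair_id", "ggd", "ddh")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
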