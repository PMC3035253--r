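#' @importFrom stats setNames
NULL

match_columns <- c("q_replicon", "s_replicon", "q_start", "q_end",
                   "s_start", "s_end", "strand", "length", "identities",
                   "score", "evalue")

empty_matches <- function() {
  data.frame(q_replicon = character(), s_replicon = character(),
             q_start = numeric(), q_end = numeric(),
             s_start = numeric(), s_end = numeric(),
             strand = character(), length = numeric(),
             identities = numeric(), score = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

validate_matches <- function(m, query_lengths, subject_lengths, context = "match set") {
  if (nrow(m) == 0L) return(invisible(m))
  with(m, {
    if (any(q_start < 0 | s_start < 0 | q_start >= q_end | s_start >= s_end))
      stop(context, ": invalid interval (need 0 <= start < end)")
    if (any(identities > length))
      stop(context, ": identities exceed alignment length")
    if (any(length < 1 | identities < 0))
      stop(context, ": non-positive length or negative identities")
    if (any(score <= 0))
      stop(context, ": score must be > 0")
    if (any(!strand %in% c("+", "-")))
      stop(context, ": strand must be '+' or '-'")
  })
  uq <- setdiff(unique(m$q_replicon), names(query_lengths))
  if (length(uq))
    stop(context, ": query replicon not in genome: ", uq[1L])
  us <- setdiff(unique(m$s_replicon), names(subject_lengths))
  if (length(us))
    stop(context, ": subject replicon not in genome: ", us[1L])
  if (any(m$q_end > query_lengths[m$q_replicon]))
    stop(context, ": query interval beyond replicon end")
  if (any(m$s_end > subject_lengths[m$s_replicon]))
    stop(context, ": subject interval beyond replicon end")
  invisible(m)
}

#' Construct a directed match set
#'
#' The container for all HSPs or MUMs obtained by querying one genome
#' against another. Direction matters: the set of matches from querying x
#' against y and the one from querying y against x are distinct objects, and
#' both enter the distance components (\code{H_xy}/\code{I_xy} vs
#' \code{H_yx}/\code{I_yx}).
#'
#' Coordinates are 0-based half-open on the forward strand of the respective
#' replicon; \code{strand} is the orientation of the subject segment relative
#' to the query. \code{length} is the alignment-column length, \code{identities}
#' the number of identical aligned columns (\code{identities == length} for
#' exact matches), \code{score} the alignment score (the match length for
#' MUMs) and \code{evalue} is \code{NA} where the source provides none.
#'
#' @param query_genome,subject_genome \code{gbdp_genome} objects.
#' @param matches data.frame with columns \code{q_replicon, s_replicon,
#'   q_start, q_end, s_start, s_end, strand, length, identities, score,
#'   evalue}.
#' @return An object of class \code{"gbdp_matchset"}.
#' @export
match_set <- function(query_genome, subject_genome, matches = empty_matches()) {
  stopifnot(inherits(query_genome, "gbdp_genome"),
            inherits(subject_genome, "gbdp_genome"))
  if (nrow(matches)) {
    miss <- setdiff(match_columns, names(matches))
    if (length(miss))
      stop("matches missing column(s): ", paste(miss, collapse = ", "))
    matches <- matches[, match_columns]
  } else {
    matches <- empty_matches()
  }
  ql <- replicon_lengths(query_genome)
  sl <- replicon_lengths(subject_genome)
  validate_matches(matches, ql, sl)
  structure(
    list(query_genome_id = query_genome$genome_id,
         subject_genome_id = subject_genome$genome_id,
         matches = matches,
         query_lengths = ql, subject_lengths = sl,
         query_length = sum(ql), subject_length = sum(sl)),
    class = "gbdp_matchset")
}

#' @export
print.gbdp_matchset <- function(x, ...) {
  cat("gbdp match set ", x$query_genome_id, " -> ", x$subject_genome_id,
      ": ", nrow(x$matches), " match(es)\n", sep = "")
  if (nrow(x$matches))
    cat("  total length ", sum(x$matches$length), " bp, identities ",
        sum(x$matches$identities), " bp\n", sep = "")
  invisible(x)
}

sort_matches <- function(m) {
  if (nrow(m) == 0L) return(m)
  o <- order(m$q_replicon, m$q_start, m$q_end, m$s_replicon, m$s_start, m$strand)
  m2 <- m[o, , drop = FALSE]
  rownames(m2) <- NULL
  m2
}

#' Parse BLAST tabular output into a directed match set
#'
#' Accepts the standard 12-column tabular format (\code{-outfmt 6} or
#' \code{7}): qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore. Lines starting with \code{#} are skipped.
#' BLAST's 1-based inclusive coordinates are converted to 0-based half-open;
#' \code{sstart > send} marks a minus-strand HSP whose subject interval is
#' stored on the forward strand. Identity counts are reconstructed as
#' \code{round(pident * length / 100)} since the tabular format carries
#' percent identity only.
#'
#' @param path path to a BLAST tabular file.
#' @param query_genome,subject_genome \code{gbdp_genome} objects the
#'   coordinates refer to.
#' @return a \code{gbdp_matchset}.
#' @export
parse_blast_tabular <- function(path, query_genome, subject_genome) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(match_set(query_genome, subject_genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_ok <- lengths(fields) == 12L
  if (any(!ncol_ok))
    stop("BLAST tabular line ", which(!ncol_ok)[1L],
         ": expected 12 tab-separated columns, got ",
         lengths(fields)[!ncol_ok][1L])
  m <- do.call(rbind, fields)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop("BLAST tabular line ", which(is.na(v))[1L],
           ": non-numeric ", what)
    v
  }
  pident <- num(3L, "pident"); len <- num(4L, "length")
  qstart <- num(7L, "qstart"); qend <- num(8L, "qend")
  sstart <- num(9L, "sstart"); send <- num(10L, "send")
  evalue <- num(11L, "evalue"); bitscore <- num(12L, "bitscore")
  minus <- sstart > send
  res <- data.frame(
    q_replicon = m[, 1L], s_replicon = m[, 2L],
    q_start = qstart - 1, q_end = qend,
    s_start = ifelse(minus, send - 1, sstart - 1),
    s_end = ifelse(minus, sstart, send),
    strand = ifelse(minus, "-", "+"),
    length = len,
    identities = round(pident * len / 100),
    score = bitscore, evalue = evalue,
    stringsAsFactors = FALSE)
  match_set(query_genome, subject_genome, sort_matches(res))
}

#' Parse MUMmer match-list output into a directed match set
#'
#' Accepts the plain match list written by the classic \code{mummer}
#' program: one \code{"> id"} header per query sequence (with the suffix
#' \code{Reverse} opening the reverse-complement section), then one match
#' per line as \code{reference_position query_position length} (a 4-column
#' variant carrying the reference id first is also accepted). The first
#' positional column is the reference (= subject) position and the second
#' the query position, both 1-based. Reverse-section query positions refer
#' to the reversed query and are reflected to forward-strand half-open
#' intervals at parse time. MUMs are exact, so identities = length, the
#' match length stands in for the score, and there is no e-value.
#'
#' @param path path to a mummer match list.
#' @param query_genome,subject_genome \code{gbdp_genome} objects
#'   (\code{query_genome} is the mummer query, \code{subject_genome} the
#'   reference).
#' @return a \code{gbdp_matchset}.
#' @export
parse_mummer_mums <- function(path, query_genome, subject_genome) {
  lines <- readLines(path)
  ql <- replicon_lengths(query_genome)
  sl <- replicon_lengths(subject_genome)
  if (length(sl) != 1L && !any(grepl("^>", lines)))
    stop("multi-replicon subject requires the 4-column mummer format")
  cur_query <- if (length(ql) == 1L) names(ql) else NA_character_
  cur_rev <- FALSE
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      hdr <- trimws(sub("^>", "", ln))
      toks <- strsplit(hdr, "\\s+")[[1L]]
      cur_rev <- length(toks) >= 2L && tolower(toks[length(toks)]) == "reverse"
      if (cur_rev) toks <- toks[-length(toks)]
      cur_query <- toks[1L]
      next
    }
    toks <- strsplit(ln, "\\s+")[[1L]]
    if (length(toks) == 3L) {
      sref <- if (length(sl) == 1L) names(sl) else
        stop("mummer line ", i, ": 3-column row but subject has multiple replicons")
      v <- suppressWarnings(as.numeric(toks))
    } else if (length(toks) == 4L) {
      sref <- toks[1L]
      v <- suppressWarnings(as.numeric(toks[-1L]))
    } else {
      stop("mummer line ", i, ": expected 3 or 4 columns")
    }
    if (anyNA(v)) stop("mummer line ", i, ": non-numeric field")
    spos <- v[1L]; qpos <- v[2L]; len <- v[3L]
    if (len <= 0) stop("mummer line ", i, ": match length must be positive")
    if (is.na(cur_query))
      stop("mummer line ", i, ": no query header seen and query is multi-replicon")
    if (!cur_query %in% names(ql))
      stop("mummer line ", i, ": unknown query replicon '", cur_query, "'")
    if (cur_rev) {
      # position on the reversed query; reflect to forward strand:
      # reversed [qpos, qpos+len-1] -> forward [L-qpos-len+1, L-qpos] (1-based)
      L <- ql[[cur_query]]
      q_start <- L - (qpos - 1) - len
      q_end <- L - (qpos - 1)
      strand <- "-"
    } else {
      q_start <- qpos - 1
      q_end <- qpos - 1 + len
      strand <- "+"
    }
    out[[i]] <- data.frame(
      q_replicon = cur_query, s_replicon = sref,
      q_start = q_start, q_end = q_end,
      s_start = spos - 1, s_end = spos - 1 + len,
      strand = strand, length = len, identities = len,
      score = len, evalue = NA_real_, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L)
    return(match_set(query_genome, subject_genome))
  match_set(query_genome, subject_genome,
            sort_matches(do.call(rbind, out)))
}

#' Remove high e-value matches
#'
#' Drops every match whose e-value exceeds \code{threshold}. Matches that
#' carry no e-value (MUMs, internal exact matches) are kept unchanged; if
#' the set contains none with an e-value, a warning notes that the filter is
#' vacuous.
#'
#' @param set a \code{gbdp_matchset}.
#' @param threshold e-value cutoff, default \code{1e-2}.
#' @return the filtered \code{gbdp_matchset}.
#' @export
filter_by_evalue <- function(set, threshold = 1e-2) {
  stopifnot(inherits(set, "gbdp_matchset"), threshold > 0)
  m <- set$matches
  if (nrow(m) && all(is.na(m$evalue)))
    warning("no match carries an e-value; filter has no effect")
  keep <- is.na(m$evalue) | m$evalue <= threshold
  set$matches <- m[keep, , drop = FALSE]
  rownames(set$matches) <- NULL
  set
}

#' Write a match set as TSV
#'
#' One match per line, 0-based half-open coordinates, explicit strand
#' column; header carries the genome ids. Readable back with
#' \code{\link{read_match_tsv}}.
#'
#' @param set a \code{gbdp_matchset}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_match_tsv <- function(set, path) {
  stopifnot(inherits(set, "gbdp_matchset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# query_genome=", set$query_genome_id,
                    " subject_genome=", set$subject_genome_id), con)
  utils::write.table(set$matches, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a match-set TSV written by \code{\link{write_match_tsv}}
#' @param path input path.
#' @param query_genome,subject_genome the genomes the coordinates refer to.
#' @return a \code{gbdp_matchset}.
#' @export
read_match_tsv <- function(path, query_genome, subject_genome) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(tab) == 0L) return(match_set(query_genome, subject_genome))
  for (col in c("q_replicon", "s_replicon", "strand"))
    tab[[col]] <- as.character(tab[[col]])
  for (col in c("q_start", "q_end", "s_start", "s_end", "length",
                "identities", "score", "evalue"))
    tab[[col]] <- as.numeric(tab[[col]])  # an all-NA column reads as logical
  match_set(query_genome, subject_genome, tab[, match_columns])
}
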