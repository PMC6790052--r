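# Core sequence and interval model. Coordinates are 0-based half-open
# throughout the package; conversion to Biostrings' 1-based views happens
# only at call boundaries.

#' Validate and canonicalize a nucleotide sequence
#'
#' Accepts a character scalar or a `Biostrings::DNAString` and returns the
#' uppercase character form. Characters outside `A C G T N` are rejected
#' rather than coerced.
#'
#' @param x sequence (character scalar or DNAString); lowercase is accepted
#'   and uppercased.
#' @param arg name used in error messages.
#' @return uppercase character scalar.
#' @export
#' @examples
#' as_dna("acgtn")
as_dna <- function(x, arg = "x") {
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single character string", arg), call. = FALSE)
  }
  x <- toupper(x)
  if (nzchar(x) && grepl("[^ACGTN]", x)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", x), "")[[1L]])
    stop(sprintf("`%s` contains characters outside {A,C,G,T,N}: %s",
                 arg, paste(bad, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Reverse complement of a nucleotide sequence
#'
#' The complement of `N` is `N`; applying the function twice returns the
#' input (involution).
#'
#' @param seq sequence (character or DNAString).
#' @return character scalar.
#' @export
#' @examples
#' reverse_complement("GGAT")  # "ATCC"
reverse_complement <- function(seq) {
  seq <- as_dna(seq, "seq")
  if (!nzchar(seq)) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Construct a genomic interval (0-based, half-open)
#'
#' @param seq_id sequence identifier.
#' @param start 0-based start (inclusive).
#' @param end end (exclusive); must satisfy `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @return a one-row data frame with columns `seq_id`, `start`, `end`,
#'   `strand`; interval length is `end - start`.
#' @export
genomic_interval <- function(seq_id, start, end, strand = ".") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("invalid interval: need 0 <= start < end", call. = FALSE)
  }
  if (!strand %in% c("+", "-", ".")) {
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  }
  data.frame(seq_id = as.character(seq_id), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Map a pair of upstream construct coordinates to an interval
#'
#' Reporter constructs are conventionally named by distances upstream of the
#' annotated start codon, e.g. a \emph{-576/-421} construct. Offsets are
#' negative integers with the ATG at offset 0. The pair maps to the
#' half-open interval `[ATG - |a|, ATG - |b|)`, whose length is exactly
#' `|a| - |b|` (so -576/-421 has length 155 and -547/-401 has length 146).
#'
#' @param a,b negative integer offsets with `|a| > |b|`.
#' @param seq_id identifier for the returned interval.
#' @param atg coordinate of the start codon in the target coordinate
#'   system. The default (`abs(a)`) places the interval at the origin of a
#'   region that begins at the `-|a|` position.
#' @return interval data frame as from [genomic_interval()].
#' @export
#' @examples
#' upstream_interval(-576, -421)  # length 155
upstream_interval <- function(a, b, seq_id = "upstream", atg = abs(a)) {
  a <- as.integer(a); b <- as.integer(b)
  if (is.na(a) || is.na(b) || a >= 0L || b >= 0L) {
    stop("upstream offsets must be negative integers (ATG at 0)", call. = FALSE)
  }
  if (abs(a) <= abs(b)) {
    stop("need |a| > |b|: `a` is the more distal (more negative) offset",
         call. = FALSE)
  }
  genomic_interval(seq_id, atg - abs(a), atg - abs(b), "+")
}

#' Read a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` that uppercases
#' sequences and validates the alphabet. A file whose first non-empty line
#' is not a header is reported with its line number.
#'
#' @param path FASTA file (wrapped or unwrapped records).
#' @return named character vector of sequences (possibly empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) return(setNames(character(0), character(0)))
  first <- nonempty[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA at %s line %d: expected '>' header",
                 path, first), call. = FALSE)
  }
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  for (i in seq_along(seqs)) as_dna(seqs[[i]], sprintf("record '%s'", ids[i]))
  setNames(unname(seqs), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named", call. = FALSE)
  }
  set <- Biostrings::DNAStringSet(vapply(seqs, as_dna, character(1)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write intervals as BED6
#'
#' Coordinates are written as stored (0-based, half-open), matching the BED
#' convention natively.
#'
#' @param intervals data frame with columns `seq_id`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  need <- c("seq_id", "start", "end")
  if (!all(need %in% names(intervals))) {
    stop("intervals must have columns seq_id, start, end", call. = FALSE)
  }
  n <- nrow(intervals)
  bed <- data.frame(
    chrom = intervals$seq_id,
    start = as.integer(intervals$start),
    end = as.integer(intervals$end),
    name = if ("name" %in% names(intervals)) intervals$name else rep(".", n),
    score = if ("score" %in% names(intervals)) intervals$score else rep(0, n),
    strand = if ("strand" %in% names(intervals)) intervals$strand else rep(".", n),
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data frame as TSV with a header row
#'
#' @param records data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
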