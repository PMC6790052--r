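# Degenerate (IUPAC) motif scanning and in-silico site-directed mutagenesis.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Validate a named set of IUPAC motif patterns
#'
#' @param motifs named character vector mapping a factor name (e.g.
#'   `"Ets1/2"`) to an IUPAC consensus pattern (e.g. `"GGAW"`).
#' @return the validated vector (uppercased).
#' @export
motif_set <- function(motifs) {
  if (length(motifs) == 0L) stop("motif set is empty", call. = FALSE)
  if (is.null(names(motifs)) || any(!nzchar(names(motifs)))) {
    stop("every motif pattern must be named", call. = FALSE)
  }
  motifs <- toupper(motifs)
  for (i in seq_along(motifs)) {
    pat <- motifs[[i]]
    if (!nzchar(pat)) stop("motif pattern must be non-empty", call. = FALSE)
    letters_ok <- strsplit(pat, "")[[1L]] %in% names(IUPAC_SETS)
    if (!all(letters_ok)) {
      stop(sprintf("motif '%s' has non-IUPAC letters in pattern '%s'",
                   names(motifs)[i], pat), call. = FALSE)
    }
  }
  motifs
}

#' Default transcription-factor motif library
#'
#' Consensus patterns for the factors operating in tunicate cardiopharyngeal
#' enhancers: Ets1/2 (`GGAW`), TBX6 (`GGNG`), the homeodomain core `ATTA`
#' (its reverse-strand reading `TAAT` arises automatically from two-strand
#' scanning), and the Forkhead core `TGTT`. There is no default LHX3 entry:
#' no consensus is bundled, so an LHX3 pattern must be supplied explicitly
#' when needed.
#'
#' @return named character vector of IUPAC patterns.
#' @export
default_motifs <- function() {
  c("Ets1/2" = "GGAW", TBX6 = "GGNG", ATTA = "ATTA", FOX_core = "TGTT")
}

#' Expand an IUPAC pattern into its concrete words
#'
#' @param pattern IUPAC consensus string.
#' @return character vector of all concrete words matching the pattern
#'   (sorted); length equals the product of per-position degeneracies.
#' @export
#' @examples
#' expand_iupac("GGAW")  # GGAA GGAT
expand_iupac <- function(pattern) {
  pattern <- motif_set(c(pattern = pattern))[[1L]]
  sets <- IUPAC_SETS[strsplit(pattern, "")[[1L]]]
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste0,
             collapse = ""))
}

empty_hits <- function() {
  data.frame(motif = character(0), start = integer(0), end = integer(0),
             strand = character(0), match = character(0),
             stringsAsFactors = FALSE)
}

sort_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$start, match(hits$strand, c("+", "-")), hits$motif,
               hits$end)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a sequence for degenerate motifs on one or both strands
#'
#' Matching follows the IUPAC degeneracy sets exactly; an `N` in the
#' scanned sequence matches no motif letter (degenerate or literal).
#' Overlapping and nested hits are all reported; a site matching on both
#' strands yields two hits.
#'
#' @param seq sequence (character or DNAString).
#' @param motifs named IUPAC patterns, as in [motif_set()].
#' @param strands subset of `c("+", "-")`.
#' @return data frame with columns `motif`, `start`, `end` (0-based,
#'   half-open), `strand`, and `match` (the concrete word on the reference
#'   strand; for a `-` hit its reverse complement matches the pattern),
#'   sorted by start then strand.
#' @export
#' @examples
#' scan_motifs("AAGGATAA", c("Ets1/2" = "GGAW"))
scan_motifs <- function(seq, motifs, strands = c("+", "-")) {
  seq <- as_dna(seq, "seq")
  motifs <- motif_set(motifs)
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  L <- nchar(seq)
  if (L == 0L) return(empty_hits())
  subj <- Biostrings::DNAString(seq)
  out <- list()
  for (i in seq_along(motifs)) {
    name <- names(motifs)[i]
    pat <- motifs[[i]]
    k <- nchar(pat)
    if (k > L) next
    if ("+" %in% strands) {
      m <- Biostrings::matchPattern(pat, subj,
                                    fixed = c(pattern = FALSE, subject = TRUE))
      if (length(m) > 0L) {
        st <- IRanges::start(m) - 1L
        word <- substring(seq, st + 1L, st + k)
        out[[length(out) + 1L]] <- data.frame(
          motif = name, start = st, end = st + k, strand = "+",
          match = word, stringsAsFactors = FALSE)
      }
    }
    if ("-" %in% strands) {
      rc <- Biostrings::reverseComplement(subj)
      m <- Biostrings::matchPattern(pat, rc,
                                    fixed = c(pattern = FALSE, subject = TRUE))
      if (length(m) > 0L) {
        # position on the rc maps back to [L - end, L - start) forward
        st <- L - (IRanges::start(m) - 1L + k)
        word <- substring(seq, st + 1L, st + k)
        out[[length(out) + 1L]] <- data.frame(
          motif = name, start = st, end = st + k, strand = "-",
          match = word, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[!grepl("N", hits$match, fixed = TRUE), , drop = FALSE]
  sort_hits(hits)
}

hit_overlaps <- function(hits, start, end) {
  nrow(hits) > 0L & hits$start < end & hits$end > start
}

replace_span <- function(seq, start, end, replacement) {
  paste0(substring(seq, 1L, start), replacement,
         substring(seq, end + 1L, nchar(seq)))
}

#' Knock out a motif occurrence in place
#'
#' Replaces the matched word with a same-length word that no configured
#' motif matches (on either strand) anywhere overlapping the replaced span.
#' A fixed substitution table is consulted first (by default the classic
#' Ets1/2 site knockout `GGAT -> GCTT`); otherwise random same-length words
#' are drawn until the post-condition holds, up to `max_attempts`.
#'
#' @param seq sequence carrying the hit.
#' @param hit one-row hit data frame as returned by [scan_motifs()].
#' @param motifs motif set used to verify the knockout (defaults to the
#'   hit's own motif only is not enough: all configured motifs are checked
#'   so a knockout never creates a new site of another factor).
#' @param substitutions named character vector mapping a strand-word to its
#'   fixed replacement.
#' @param max_attempts bound on random resampling.
#' @return the edited sequence (same length as input).
#' @export
knockout_motif <- function(seq, hit, motifs,
                           substitutions = c(GGAT = "GCTT"),
                           max_attempts = 100L) {
  seq <- as_dna(seq, "seq")
  motifs <- motif_set(motifs)
  stopifnot(nrow(hit) == 1L)
  start <- hit$start; end <- hit$end
  if (start < 0L || end > nchar(seq)) {
    stop("hit interval lies outside the sequence", call. = FALSE)
  }
  k <- end - start
  word_fwd <- substring(seq, start + 1L, end)
  strand_word <- if (hit$strand == "-") reverse_complement(word_fwd) else word_fwd
  maxk <- max(nchar(motifs))
  ctx_start <- max(0L, start - (maxk - 1L))
  ctx_end <- min(nchar(seq), end + (maxk - 1L))

  ok <- function(candidate_strand_word) {
    repl_fwd <- if (hit$strand == "-") reverse_complement(candidate_strand_word)
                else candidate_strand_word
    new_seq <- replace_span(seq, start, end, repl_fwd)
    ctx <- substring(new_seq, ctx_start + 1L, ctx_end)
    h <- scan_motifs(ctx, motifs)
    if (nrow(h) == 0L) return(new_seq)
    h$start <- h$start + ctx_start
    h$end <- h$end + ctx_start
    if (any(hit_overlaps(h, start, end))) NULL else new_seq
  }

  if (strand_word %in% names(substitutions)) {
    res <- ok(unname(substitutions[[strand_word]]))
    if (!is.null(res)) return(res)
  }
  for (attempt in seq_len(max_attempts)) {
    cand <- paste0(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                   collapse = "")
    res <- ok(cand)
    if (!is.null(res)) return(res)
  }
  stop(sprintf("could not find a motif-free replacement in %d attempts",
               max_attempts), call. = FALSE)
}

#' Displace a motif occurrence by a fixed offset
#'
#' Knocks out the original site and writes the same matched word at
#' `start + delta`, emulating site-directed mutagenesis that moves a
#' binding site relative to an anchor site (e.g. moving an Ets1/2 site
#' 6 bp upstream turns a 10 bp gap to the neighboring ATTA site into a
#' 16 bp gap). Negative `delta` shifts toward the 5' end (upstream).
#'
#' @param seq sequence carrying the hit.
#' @param hit one-row hit data frame (the site to move).
#' @param delta signed shift in bp applied to the hit's start; `0` returns
#'   the input unchanged.
#' @param anchor_hit optional one-row hit the destination must not overlap.
#' @param motifs motif set used for verification and for the knockout.
#' @param hits optional pre-computed hit table used to detect collisions
#'   with other annotated sites (defaults to scanning `seq` with `motifs`).
#' @param max_attempts resampling bound forwarded to the knockout step.
#' @return the edited sequence; total hit count of the moved motif is
#'   unchanged.
#' @export
displace_motif <- function(seq, hit, delta, anchor_hit = NULL, motifs,
                           hits = NULL, max_attempts = 100L) {
  seq <- as_dna(seq, "seq")
  motifs <- motif_set(motifs)
  stopifnot(nrow(hit) == 1L)
  delta <- as.integer(delta)
  if (delta == 0L) return(seq)
  k <- hit$end - hit$start
  dest_start <- hit$start + delta
  dest_end <- dest_start + k
  if (dest_start < 0L || dest_end > nchar(seq)) {
    stop("destination span lies outside the sequence", call. = FALSE)
  }
  if (!is.null(anchor_hit) &&
      dest_start < anchor_hit$end && dest_end > anchor_hit$start) {
    stop("destination span overlaps the anchor site", call. = FALSE)
  }
  if (is.null(hits)) hits <- scan_motifs(seq, motifs)
  others <- hits[!(hits$start == hit$start & hits$end == hit$end &
                     hits$strand == hit$strand & hits$motif == hit$motif), ,
                 drop = FALSE]
  if (any(hit_overlaps(others, dest_start, dest_end))) {
    stop("destination span overlaps another annotated motif hit",
         call. = FALSE)
  }
  this_motif <- motifs[hit$motif]
  n_before <- nrow(scan_motifs(seq, this_motif))
  word_fwd <- substring(seq, hit$start + 1L, hit$end)
  for (attempt in seq_len(max_attempts)) {
    out <- knockout_motif(seq, hit, motifs, max_attempts = max_attempts)
    out <- replace_span(out, dest_start, dest_end, word_fwd)
    if (nrow(scan_motifs(out, this_motif)) != n_before) next
    # the move must not create cryptic sites of other configured motifs
    # at the destination junctions
    new_hits <- scan_motifs(out, motifs)
    at_dest <- new_hits[hit_overlaps(new_hits, dest_start, dest_end), ,
                        drop = FALSE]
    clean <- nrow(at_dest) == 1L && at_dest$motif == hit$motif &&
      at_dest$start == dest_start && at_dest$end == dest_end
    if (clean) return(out)
  }
  stop("displacement would change motif content: flanking bases create or ",
       "destroy sites at the destination", call. = FALSE)
}
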