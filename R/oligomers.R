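# Shared-oligomer detection and ordering distance: the raw material of the
# window score. "Oligomers" are operationalized as a greedy left-to-right
# tiling of the window by maximal substrings (length >= min_oligo) that
# occur somewhere in the reference enhancer on either strand.

#' Index all substrings of a reference sequence
#'
#' Builds a hash of every substring of `reference` (and of its reverse
#' complement) with length at least `min_oligo`, used for O(1) membership
#' queries during window tiling. Substrings containing `N` are excluded:
#' an N participates in no oligomer match.
#'
#' @param reference reference enhancer sequence.
#' @param min_oligo minimum oligomer length (>= 1).
#' @return an opaque index object for [shared_oligomers()].
#' @export
oligomer_index <- function(reference, min_oligo = 4L) {
  reference <- as_dna(reference, "reference")
  min_oligo <- as.integer(min_oligo)
  if (is.na(min_oligo) || min_oligo < 1L) {
    stop("min_oligo must be a positive integer", call. = FALSE)
  }
  n <- nchar(reference)
  by_len <- list()
  if (n >= min_oligo) {
    rc <- reverse_complement(reference)
    for (L in min_oligo:n) {
      starts <- 1:(n - L + 1L)
      words <- unique(c(substring(reference, starts, starts + L - 1L),
                        substring(rc, starts, starts + L - 1L)))
      by_len[[L]] <- words[!grepl("N", words, fixed = TRUE)]
    }
  }
  structure(list(by_len = by_len, reference = reference,
                 min_oligo = min_oligo,
                 occ_cache = new.env(parent = emptyenv())),
            class = "oligomer_index")
}

index_has <- function(index, word) {
  L <- nchar(word)
  L <= length(index$by_len) && !is.null(index$by_len[[L]]) &&
    word %in% index$by_len[[L]]
}

# maximal shared-substring length starting at every window position
# (0 where even the min_oligo-mer is absent); computed level by level with
# vectorized substring extraction and hash matching. Words containing N can
# never be in the index, so no separate N handling is needed.
max_match_lengths <- function(window, index) {
  n <- nchar(window)
  k <- index$min_oligo
  maxL <- length(index$by_len)
  if (n < k || maxL == 0L) return(integer(0))
  starts <- 1:(n - k + 1L)
  words <- substring(window, starts, starts + k - 1L)
  alive <- words %in% index$by_len[[k]]
  M <- ifelse(alive, k, 0L)
  L <- k
  while (any(alive) && L < maxL) {
    L <- L + 1L
    ii <- which(alive & (starts + L - 1L) <= n)
    alive[alive] <- FALSE
    if (length(ii) > 0L && !is.null(index$by_len[[L]])) {
      w <- substring(window, starts[ii], starts[ii] + L - 1L)
      ok <- w %in% index$by_len[[L]]
      M[ii[ok]] <- L
      alive[ii[ok]] <- TRUE
    }
  }
  as.integer(M)
}

#' Greedy tiling of a window by oligomers shared with a reference
#'
#' Walks the window left to right; at each position takes the longest
#' substring (length >= `min_oligo`) present in the reference on either
#' strand, records it, and resumes after it. The resulting tiles give both
#' the shared-oligomer count (feature 1 of the window score) and an
#' unambiguous left-to-right ordering (input to feature 2). Each tile is
#' assigned a reference offset by greedy first-occurrence matching:
#' duplicate words consume reference occurrences left to right.
#'
#' @param window window sequence.
#' @param reference reference enhancer sequence (ignored when `index` is
#'   supplied).
#' @param min_oligo minimum oligomer length.
#' @param index optional pre-built [oligomer_index()] (reused across the
#'   windows of one scan).
#' @return data frame with columns `word`, `window_offset`, `length`,
#'   `ref_offset`, `strand_in_ref`, in window order. Zero rows when nothing
#'   is shared.
#' @export
#' @examples
#' shared_oligomers("ACGTACGT", "TTACGTTT")  # two ACGT tiles
shared_oligomers <- function(window, reference = NULL, min_oligo = 4L,
                             index = NULL) {
  window <- as_dna(window, "window")
  if (is.null(index)) {
    if (is.null(reference)) stop("supply `reference` or `index`", call. = FALSE)
    index <- oligomer_index(reference, min_oligo)
  }
  min_oligo <- index$min_oligo
  if (!nzchar(window) || !nzchar(index$reference)) {
    stop("window and reference must be non-empty", call. = FALSE)
  }
  n <- nchar(window)
  M <- max_match_lengths(window, index)
  words <- character(0); offs <- integer(0)
  i <- 1L
  while (i <= length(M)) {
    if (M[i] == 0L) {
      i <- i + 1L
      next
    }
    words <- c(words, substring(window, i, i + M[i] - 1L))
    offs <- c(offs, i - 1L)
    i <- i + M[i]
  }
  tiles <- data.frame(word = words, window_offset = offs,
                      length = nchar(words), stringsAsFactors = FALSE)
  if (nrow(tiles) == 0L) {
    tiles$ref_offset <- integer(0)
    tiles$strand_in_ref <- character(0)
    return(tiles)
  }
  occ <- match_reference_occurrences(tiles$word, index$reference,
                                     cache = index$occ_cache)
  tiles$ref_offset <- occ$offset
  tiles$strand_in_ref <- occ$strand
  tiles
}

# number of distinct words of each length >= min_oligo shared between the
# window and the reference, derived from the maximal-match profile: the
# word of length L starting at window position i is shared iff M[i] >= L
# (substring closure), so each level enumerates unique words at the still-
# alive positions.
count_distinct_shared <- function(window, index, M = NULL) {
  if (is.null(M)) M <- max_match_lengths(window, index)
  if (length(M) == 0L || max(M) == 0L) return(0L)
  k <- index$min_oligo
  total <- 0L
  for (L in k:max(M)) {
    pos <- which(M >= L)
    total <- total + length(unique(substring(window, pos, pos + L - 1L)))
  }
  total
}

# maximum total tile length over subsequences of tiles whose reference
# offsets are strictly increasing (length-weighted longest increasing
# subsequence); the complement, total - result, is the amount of shared
# material that must be moved to restore reference order.
weighted_in_order <- function(ref_offset, lengths) {
  n <- length(ref_offset)
  if (n == 0L) return(0)
  best <- as.numeric(lengths)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (ref_offset[j] < ref_offset[i] && best[j] + lengths[i] > best[i]) {
        best[i] <- best[j] + lengths[i]
      }
    }
  }
  max(best)
}

# fast internal reverse complement for short words (avoids DNAString
# construction overhead in the per-window hot path)
rc_chr <- function(s) {
  if (!nzchar(s)) return(s)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
}

# Greedy first-occurrence matching of tile words to reference positions.
# Occurrences of a word pool forward matches of the word and forward
# positions of its reverse complement; identical intervals found on both
# strands (palindromes) count once, as '+'.
match_reference_occurrences <- function(words, reference, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  occurrences <- function(word) {
    if (!exists(word, envir = cache, inherits = FALSE)) {
      fwd <- find_all(reference, word)
      rev <- find_all(reference, rc_chr(word))
      rev <- setdiff(rev, fwd)
      df <- data.frame(
        offset = c(fwd, rev),
        strand = c(rep("+", length(fwd)), rep("-", length(rev))),
        stringsAsFactors = FALSE)
      df <- df[order(df$offset), , drop = FALSE]
      assign(word, df, envir = cache)
    }
    get(word, envir = cache, inherits = FALSE)
  }
  used <- new.env(parent = emptyenv())
  offset <- integer(length(words)); strand <- character(length(words))
  for (i in seq_along(words)) {
    w <- words[i]
    k <- if (exists(w, envir = used, inherits = FALSE))
      get(w, envir = used, inherits = FALSE) else 0L
    occ <- occurrences(w)
    j <- min(k + 1L, nrow(occ))  # duplicates beyond supply reuse the last
    offset[i] <- occ$offset[j]
    strand[i] <- occ$strand[j]
    assign(w, k + 1L, envir = used)
  }
  list(offset = offset, strand = strand)
}

# all 0-based start offsets of fixed word in seq (forward strand)
find_all <- function(seq, word) {
  hits <- gregexpr(word, seq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Minimum adjacent transpositions between two orderings
#'
#' The number of steps needed to transform one ordering of a multiset into
#' the other, where a step swaps two adjacent elements (the Kendall
#' distance of the induced permutation, i.e. its inversion count).
#' Duplicate labels are matched greedily by first occurrence.
#'
#' @param order_a,order_b vectors containing the same multiset of labels.
#' @return non-negative integer; symmetric in its arguments.
#' @export
#' @examples
#' ordering_steps(c("A", "B", "C"), c("C", "A", "B"))  # 2
ordering_steps <- function(order_a, order_b) {
  a <- as.character(order_a); b <- as.character(order_b)
  if (length(a) != length(b) ||
      !identical(sort(a), sort(b))) {
    stop("orderings must contain the same multiset of labels", call. = FALSE)
  }
  if (length(a) <= 1L) return(0L)
  taken <- logical(length(b))
  p <- integer(length(a))
  for (i in seq_along(a)) {
    j <- which(!taken & b == a[i])[1L]
    taken[j] <- TRUE
    p[i] <- j
  }
  count_inversions(p)
}

count_inversions <- function(p) {
  n <- length(p)
  if (n <= 1L) return(0L)
  inv <- 0L
  for (i in 1:(n - 1L)) {
    inv <- inv + sum(p[i] > p[(i + 1L):n])
  }
  as.integer(inv)
}
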