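# Enhancer architecture ("grammar") extraction and comparison: number,
# order, orientation, inter-site spacing, and helical phase of binding
# motifs. Enhanceosome-like elements conserve all of these axes; loosely
# organized elements do not.

#' Extract the binding-motif architecture of an enhancer
#'
#' @param seq enhancer sequence.
#' @param motifs named IUPAC patterns ([motif_set()]).
#' @return object of class `enhancer_architecture`: a list with `hits`
#'   (the [scan_motifs()] table, sorted by start), `types` (motif name per
#'   hit), `strands`, and `gaps` (end-to-start distance between consecutive
#'   hits, bp; length `n_hits - 1`; negative when hits overlap).
#' @export
architecture_of <- function(seq, motifs) {
  seq <- as_dna(seq, "seq")
  if (!nzchar(seq)) stop("sequence must be non-empty", call. = FALSE)
  motifs <- motif_set(motifs)
  hits <- scan_motifs(seq, motifs)
  n <- nrow(hits)
  gaps <- if (n >= 2L) hits$start[-1L] - hits$end[-n] else integer(0)
  structure(list(hits = hits, types = hits$motif, strands = hits$strand,
                 gaps = as.integer(gaps), motifs = motifs,
                 seq_length = nchar(seq)),
            class = "enhancer_architecture")
}

#' @export
print.enhancer_architecture <- function(x, ...) {
  cat(sprintf("Enhancer architecture: %d motif hit(s) over %d bp\n",
              nrow(x$hits), x$seq_length))
  if (nrow(x$hits) > 0L) {
    cat(paste0(" ", x$types, "(", x$strands, ")", collapse = ""), "\n")
    if (length(x$gaps)) cat(" gaps:", paste(x$gaps, collapse = ", "), "\n")
  }
  invisible(x)
}

# longest common subsequence of two character vectors; returns matched
# index pairs (ia, ib) in increasing order
lcs_pairs <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) {
    return(list(ia = integer(0), ib = integer(0)))
  }
  d <- matrix(0L, na + 1L, nb + 1L)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d[i + 1L, j + 1L] <- if (a[i] == b[j]) d[i, j] + 1L
        else max(d[i, j + 1L], d[i + 1L, j])
    }
  }
  ia <- integer(0); ib <- integer(0)
  i <- na; j <- nb
  while (i > 0L && j > 0L) {
    if (a[i] == b[j] && d[i + 1L, j + 1L] == d[i, j] + 1L) {
      ia <- c(i, ia); ib <- c(j, ib)
      i <- i - 1L; j <- j - 1L
    } else if (d[i, j + 1L] >= d[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(ia = ia, ib = ib)
}

#' Helical phase offset between two inter-site spacings
#'
#' Two binding-site gaps differing by a multiple of the helical period
#' (~10 bp, one turn of the double helix) place the flanking factors on
#' the same helical face; the phase offset is the residue of the gap
#' difference modulo the period (0 = in phase).
#'
#' @param gap_a,gap_b non-negative inter-site gaps in bp.
#' @param period helical period in bp (default 10; 10.5 is also customary).
#' @return value in `[0, period)`: the absolute gap difference modulo the
#'   period.
#' @export
#' @examples
#' spacing_phase(10, 20)  # 0, one full turn
#' spacing_phase(10, 16)  # 6
spacing_phase <- function(gap_a, gap_b, period = 10) {
  if (period <= 0) stop("period must be positive", call. = FALSE)
  if (any(c(gap_a, gap_b) < 0)) stop("gaps must be >= 0", call. = FALSE)
  abs(gap_a - gap_b) %% period
}

#' Compare two enhancer architectures
#'
#' Aligns the two motif-type sequences by longest common subsequence and
#' quantifies conservation of each grammar axis:
#'
#' * `count_deltas`: per-motif-type hit-count differences (a minus b);
#' * `order_conservation`: LCS length / max(n_a, n_b), in `[0,1]`;
#' * `orientation_agreement`: fraction of LCS-matched hit pairs on the same
#'   strand;
#' * `spacing_deltas`: absolute gap differences (bp) between consecutive
#'   LCS-matched hits;
#' * `helical_phase_deltas`: the same gap differences modulo
#'   `helical_period`;
#' * `rigidity`: scalar summary in `[0,1]`, the mean of order conservation,
#'   orientation agreement, and `exp(-mean(spacing_deltas)/10)`; 1 exactly
#'   when number, order, orientation, and spacing all agree
#'   (enhanceosome-like conservation).
#'
#' @param a,b `enhancer_architecture` objects scanned with the same motif
#'   set.
#' @param helical_period period for the phase metric (bp).
#' @return object of class `architecture_comparison`.
#' @export
compare_architectures <- function(a, b, helical_period = 10) {
  stopifnot(inherits(a, "enhancer_architecture"),
            inherits(b, "enhancer_architecture"))
  ma <- a$motifs[order(names(a$motifs))]
  mb <- b$motifs[order(names(b$motifs))]
  if (!identical(ma, mb)) {
    stop("architectures were scanned with different motif sets",
         call. = FALSE)
  }
  if (helical_period <= 0) stop("helical period must be positive",
                                call. = FALSE)
  types <- sort(unique(names(ma)))
  count_deltas <- vapply(types, function(t) {
    sum(a$types == t) - sum(b$types == t)
  }, numeric(1))

  na <- length(a$types); nb <- length(b$types)
  m <- lcs_pairs(a$types, b$types)
  lcs_len <- length(m$ia)
  order_conservation <- if (max(na, nb) == 0L) 1 else lcs_len / max(na, nb)
  orientation_agreement <- if (lcs_len == 0L) {
    if (na == 0L && nb == 0L) 1 else 0
  } else {
    mean(a$strands[m$ia] == b$strands[m$ib])
  }

  spacing_deltas <- numeric(0); phase_deltas <- numeric(0)
  if (lcs_len >= 2L) {
    gap_a <- a$hits$start[m$ia[-1L]] - a$hits$end[m$ia[-lcs_len]]
    gap_b <- b$hits$start[m$ib[-1L]] - b$hits$end[m$ib[-lcs_len]]
    spacing_deltas <- abs(gap_a - gap_b)
    phase_deltas <- spacing_deltas %% helical_period
  }
  spacing_term <- if (length(spacing_deltas) == 0L) 1 else
    exp(-mean(spacing_deltas) / 10)
  rigidity <- mean(c(order_conservation, orientation_agreement, spacing_term))

  structure(list(
    count_deltas = count_deltas,
    order_conservation = order_conservation,
    orientation_agreement = orientation_agreement,
    spacing_deltas = spacing_deltas,
    helical_phase_deltas = phase_deltas,
    helical_period = helical_period,
    lcs_length = lcs_len,
    n_hits = c(a = na, b = nb),
    rigidity = rigidity
  ), class = "architecture_comparison")
}

#' @export
print.architecture_comparison <- function(x, ...) {
  cat("Architecture comparison\n")
  cat(sprintf("  hits: %d vs %d (LCS %d)\n", x$n_hits[["a"]],
              x$n_hits[["b"]], x$lcs_length))
  cat(sprintf("  order conservation:    %.3f\n", x$order_conservation))
  cat(sprintf("  orientation agreement: %.3f\n", x$orientation_agreement))
  if (length(x$spacing_deltas)) {
    cat("  spacing deltas (bp):  ", paste(x$spacing_deltas, collapse = ", "),
        "\n")
    cat("  helical phase deltas: ",
        paste(x$helical_phase_deltas, collapse = ", "), "\n")
  }
  cat(sprintf("  rigidity:              %.3f\n", x$rigidity))
  invisible(x)
}
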