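# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths: naive string
# operations only.

random_dna <- function(n, gc = 0.5) {
  paste0(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
         collapse = "")
}

oracle_rc <- function(s) {
  if (!nzchar(s)) return(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_expand <- function(pattern) {
  words <- ""
  for (ch in strsplit(pattern, "")[[1]]) {
    words <- as.vector(outer(words, oracle_iupac[[ch]], paste0))
  }
  sort(words)
}

# naive per-position scan over expanded words, both strands
oracle_scan <- function(seq, motifs, strands = c("+", "-")) {
  n <- nchar(seq)
  rows <- list()
  for (m in seq_along(motifs)) {
    words <- oracle_expand(motifs[[m]])
    k <- nchar(motifs[[m]])
    if (k > n) next
    for (i in 0:(n - k)) {
      sub <- substring(seq, i + 1, i + k)
      if ("+" %in% strands && sub %in% words) {
        rows[[length(rows) + 1]] <- data.frame(
          motif = names(motifs)[m], start = i, end = i + k, strand = "+",
          match = sub, stringsAsFactors = FALSE)
      }
      if ("-" %in% strands && oracle_rc(sub) %in% words) {
        rows[[length(rows) + 1]] <- data.frame(
          motif = names(motifs)[m], start = i, end = i + k, strand = "-",
          match = sub, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      match = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, match(out$strand, c("+", "-")), out$motif,
                   out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# greedy maximal tiling using naive substring membership (grepl against the
# reference and its reverse complement)
oracle_tiling <- function(window, reference, k = 4) {
  in_ref <- function(w) {
    grepl(w, reference, fixed = TRUE) ||
      grepl(w, oracle_rc(reference), fixed = TRUE)
  }
  n <- nchar(window)
  words <- character(0)
  i <- 1
  while (i + k - 1 <= n) {
    w <- substring(window, i, i + k - 1)
    if (grepl("N", w, fixed = TRUE) || !in_ref(w)) {
      i <- i + 1
      next
    }
    while (i + nchar(w) <= n) {
      w2 <- substring(window, i, i + nchar(w))
      if (grepl("N", w2, fixed = TRUE) || !in_ref(w2)) break
      w <- w2
    }
    words <- c(words, w)
    i <- i + nchar(w)
  }
  words
}

# breadth-first search over adjacent transpositions: minimum swaps to turn
# ordering a into ordering b
oracle_bfs_steps <- function(a, b) {
  key <- function(x) paste(x, collapse = "\r")
  if (key(a) == key(b)) return(0L)
  frontier <- list(a)
  seen <- new.env(parent = emptyenv())
  assign(key(a), TRUE, envir = seen)
  depth <- 0L
  n <- length(a)
  repeat {
    depth <- depth + 1L
    nxt <- list()
    for (x in frontier) {
      for (i in seq_len(n - 1L)) {
        y <- x
        y[c(i, i + 1L)] <- y[c(i + 1L, i)]
        ky <- key(y)
        if (ky == key(b)) return(depth)
        if (!exists(ky, envir = seen, inherits = FALSE)) {
          assign(ky, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- y
        }
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) stop("BFS exhausted without reaching target")
  }
}

# interval overlap helper used throughout the predictor tests
overlaps <- function(start_a, end_a, start_b, end_b) {
  start_a < end_b && end_a > start_b
}
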