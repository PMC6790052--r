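# Sliding-window enhancer predictor: score every window of a target region
# against a reference enhancer with a linear combination of four structural
# features, then call candidate elements.
#
#  F1  shared-oligomer count: distinct words >= min_oligo present in both
#      window and reference on either strand (default), or the greedy
#      maximal-tile count (config)
#  F2  ordering similarity of the shared oligomers. The window is tiled
#      greedily by maximal shared substrings; each tile is matched to a
#      reference occurrence. Default "weighted_moves" model: F2 is the
#      fraction of shared oligomer material already in reference order
#      (1 - moved_length/total_length, element-move edit model weighted by
#      tile length). "adjacent_swaps" model: 1 - inversions/count, clamped.
#  F3  positional similarity: 1 - |d_window/L_target - d_ref/L_ref|, with d
#      the distance from the window start to the start codon; a neutral
#      constant 1 when the reference position is unknown
#  F4  count of required conserved motifs (both strands)
#
# Features are normalized to [0,1] and combined as a weighted mean.
# Rationale for the F1/F2 defaults: at min_oligo = 4 a window shares tens
# of chance 4-mers with any ~200 bp reference, so tile COUNTS carry almost
# no signal (an exact copy of the reference is a single tile) and unweighted
# inversion counts saturate. Distinct-word counts and length-weighted order
# conservation keep both features informative; see the methods vignette.

#' Predictor configuration
#'
#' @param window_size window width in bp.
#' @param step slide increment in bp.
#' @param min_oligo minimum shared-oligomer length in bp.
#' @param weights non-negative weights for the four normalized features
#'   (oligomer count, ordering, position, motifs); they need not sum to 1.
#' @param required_motifs named IUPAC patterns of the gene-specific
#'   conserved motifs counted by feature 4 (e.g. `c("Ets1/2" = "GGAW")`);
#'   may be `NULL`, in which case F4 is 0 everywhere.
#' @param f4_cap motif count at which the normalized F4 saturates.
#' @param f1_cap shared-oligomer count at which the normalized F1
#'   saturates; default `2 * (window_size - min_oligo + 1)` (one anchored
#'   word per window position per strand).
#' @param f1_mode `"distinct_oligomers"` (default: distinct shared words of
#'   any length >= `min_oligo`) or `"tile_count"` (greedy maximal tiles).
#' @param order_model `"weighted_moves"` (default) or `"adjacent_swaps"`;
#'   see the package overview for definitions.
#' @param top_n number of candidates to call.
#' @param score_quantile windows at or above this score quantile are
#'   candidate material.
#' @param merge if `TRUE`, overlapping above-threshold windows are merged
#'   into union intervals.
#' @return a list of class `predictor_config`.
#' @export
predictor_config <- function(window_size = 150L, step = 25L, min_oligo = 4L,
                             weights = c(oligomers = 0.25, ordering = 0.25,
                                         position = 0.25, motifs = 0.25),
                             required_motifs = c("Ets1/2" = "GGAW"),
                             f4_cap = 3L, f1_cap = NULL,
                             f1_mode = c("distinct_oligomers", "tile_count"),
                             order_model = c("weighted_moves",
                                             "adjacent_swaps"),
                             top_n = 3L, score_quantile = 0.95,
                             merge = FALSE) {
  window_size <- as.integer(window_size)
  step <- as.integer(step)
  min_oligo <- as.integer(min_oligo)
  top_n <- as.integer(top_n)
  if (min_oligo < 1L) stop("min_oligo must be >= 1", call. = FALSE)
  if (window_size < min_oligo) {
    stop("window_size must be >= min_oligo", call. = FALSE)
  }
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  if (length(weights) != 4L || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be four non-negative numbers with positive sum",
         call. = FALSE)
  }
  if (top_n < 1L) stop("top_n must be >= 1", call. = FALSE)
  if (!is.null(required_motifs)) required_motifs <- motif_set(required_motifs)
  f1_mode <- match.arg(f1_mode)
  if (is.null(f1_cap)) {
    f1_cap <- if (f1_mode == "distinct_oligomers")
      2L * (window_size - min_oligo + 1L) else window_size - min_oligo + 1L
  }
  structure(list(
    window_size = window_size, step = step, min_oligo = min_oligo,
    weights = unname(weights), required_motifs = required_motifs,
    f4_cap = as.numeric(f4_cap), f1_cap = as.numeric(f1_cap),
    f1_mode = f1_mode, order_model = match.arg(order_model),
    top_n = top_n, score_quantile = score_quantile, merge = isTRUE(merge)
  ), class = "predictor_config")
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Combine normalized features into the window score
#'
#' Weighted mean of the four normalized features; monotone non-decreasing
#' in each feature because weights are non-negative.
#'
#' @param f_norm numeric vector of four normalized features in `[0,1]`.
#' @param weights non-negative weights.
#' @return scalar score in `[0,1]`.
#' @export
combine_features <- function(f_norm, weights) {
  sum(weights * f_norm) / sum(weights)
}

#' Score one window against the reference enhancer
#'
#' @param window window sequence (length `config$window_size` unless scoring
#'   a free-standing fragment).
#' @param reference reference enhancer sequence (ignored when `index` is
#'   given).
#' @param window_start 0-based start of the window in the target region.
#' @param target_region_length length of the target 5' region; the region
#'   is taken to end at the start codon, so the window's distance to the
#'   ATG is `target_region_length - window_start`.
#' @param ref_distance_to_atg distance (bp) from the reference enhancer's
#'   start to its gene's start codon; `NULL` makes F3 a neutral constant 1.
#' @param ref_region_length length of the reference 5' region.
#' @param config [predictor_config()].
#' @param index optional pre-built [oligomer_index()].
#' @return one-row data frame: `window_start`, raw `f1_oligomers`,
#'   `f2_ordering`, `f3_position`, `f4_motifs`, normalized `f1_norm` ..
#'   `f4_norm`, and `score`.
#' @export
feature_vector <- function(window, reference = NULL, window_start = 0L,
                           target_region_length = nchar(window),
                           ref_distance_to_atg = NULL,
                           ref_region_length = NULL,
                           config = predictor_config(), index = NULL) {
  window <- as_dna(window, "window")
  if (target_region_length <= 0L) {
    stop("target region length must be positive", call. = FALSE)
  }
  if (is.null(index)) {
    if (is.null(reference)) stop("supply `reference` or `index`", call. = FALSE)
    index <- oligomer_index(reference, config$min_oligo)
  }

  tiles <- shared_oligomers(window, index = index)
  n_tiles <- nrow(tiles)
  f1 <- if (config$f1_mode == "distinct_oligomers")
    count_distinct_shared(window, index) else n_tiles
  if (n_tiles == 0L) {
    f2 <- 0
  } else if (config$order_model == "weighted_moves") {
    total_len <- sum(tiles$length)
    f2 <- weighted_in_order(tiles$ref_offset, tiles$length) / total_len
  } else {
    steps <- if (n_tiles > 1L)
      count_inversions(rank(tiles$ref_offset, ties.method = "first")) else 0L
    f2 <- clamp01(1 - steps / max(1L, n_tiles))
  }

  if (is.null(ref_distance_to_atg) || is.null(ref_region_length)) {
    f3 <- 1
  } else {
    d_window <- target_region_length - window_start
    f3 <- clamp01(1 - abs(d_window / target_region_length -
                            ref_distance_to_atg / ref_region_length))
  }

  f4 <- if (is.null(config$required_motifs)) 0L else
    nrow(scan_motifs(window, config$required_motifs))

  f_norm <- c(
    clamp01(f1 / config$f1_cap),
    f2,
    f3,
    min(f4 / config$f4_cap, 1)
  )
  data.frame(
    window_start = as.integer(window_start),
    f1_oligomers = as.integer(f1), f2_ordering = f2,
    f3_position = f3, f4_motifs = as.integer(f4),
    f1_norm = f_norm[1L], f2_norm = f_norm[2L],
    f3_norm = f_norm[3L], f4_norm = f_norm[4L],
    score = combine_features(f_norm, config$weights)
  )
}

#' Score all sliding windows of a target region
#'
#' Windows start at 0, `step`, `2*step`, ...; the number of windows is
#' `floor((L - window_size)/step) + 1`.
#'
#' @inheritParams feature_vector
#' @param target target region sequence (e.g. a 5' intergenic region).
#' @return data frame of per-window feature vectors (one row per window).
#' @export
score_windows <- function(target, reference, config = predictor_config(),
                          ref_distance_to_atg = NULL,
                          ref_region_length = NULL) {
  target <- as_dna(target, "target")
  L <- nchar(target)
  w <- config$window_size
  if (L < w) {
    stop(sprintf("region shorter than window (%d bp < %d bp)", L, w),
         call. = FALSE)
  }
  index <- oligomer_index(as_dna(reference, "reference"), config$min_oligo)
  starts <- seq.int(0L, L - w, by = config$step)
  rows <- lapply(starts, function(s) {
    feature_vector(substring(target, s + 1L, s + w),
                   window_start = s, target_region_length = L,
                   ref_distance_to_atg = ref_distance_to_atg,
                   ref_region_length = ref_region_length,
                   config = config, index = index)
  })
  do.call(rbind, rows)
}

#' Call candidate enhancer elements from window scores
#'
#' Windows scoring at or above the configured score quantile are candidate
#' material. By default the `top_n` best non-overlapping windows are
#' reported as fixed-width candidates; with `config$merge = TRUE`,
#' overlapping above-threshold windows are merged into union intervals
#' scored by their best member. Ties are broken toward the smaller start.
#'
#' @param scores data frame from [score_windows()].
#' @param config [predictor_config()].
#' @param seq_id identifier for the candidate intervals.
#' @return data frame with columns `seq_id`, `start`, `end`, `score`,
#'   `rank` (rank 1 = highest score), sorted by rank.
#' @export
call_candidates <- function(scores, config = predictor_config(),
                            seq_id = "target") {
  if (is.null(scores) || nrow(scores) == 0L) {
    stop("empty score list", call. = FALSE)
  }
  thr <- stats::quantile(scores$score, config$score_quantile, names = FALSE)
  keep <- scores[scores$score >= thr, , drop = FALSE]
  w <- config$window_size
  if (config$merge) {
    ir <- IRanges::IRanges(start = keep$window_start + 1L, width = w)
    red <- IRanges::reduce(ir)
    cand <- data.frame(
      start = IRanges::start(red) - 1L,
      end = IRanges::end(red),
      score = vapply(seq_along(red), function(i) {
        inside <- keep$window_start >= IRanges::start(red)[i] - 1L &
          keep$window_start + w <= IRanges::end(red)[i]
        max(keep$score[inside])
      }, numeric(1))
    )
    cand <- cand[order(-cand$score, cand$start), , drop = FALSE]
    cand <- utils::head(cand, config$top_n)
  } else {
    keep <- keep[order(-keep$score, keep$window_start), , drop = FALSE]
    sel_start <- integer(0); sel_score <- numeric(0)
    for (i in seq_len(nrow(keep))) {
      s <- keep$window_start[i]
      if (length(sel_start) >= config$top_n) break
      if (all(abs(sel_start - s) >= w)) {
        sel_start <- c(sel_start, s)
        sel_score <- c(sel_score, keep$score[i])
      }
    }
    cand <- data.frame(start = sel_start, end = sel_start + w,
                       score = sel_score)
  }
  if (nrow(cand) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(seq_id = seq_id, start = as.integer(cand$start),
             end = as.integer(cand$end), score = cand$score,
             rank = seq_len(nrow(cand)), stringsAsFactors = FALSE)
}

#' Predict candidate enhancers in a target region
#'
#' Convenience wrapper: [score_windows()] then [call_candidates()].
#'
#' @inheritParams score_windows
#' @param seq_id identifier used for candidate intervals.
#' @return list of class `crm_prediction` with elements `scores` and
#'   `candidates`.
#' @export
predict_enhancers <- function(target, reference, config = predictor_config(),
                              ref_distance_to_atg = NULL,
                              ref_region_length = NULL, seq_id = "target") {
  scores <- score_windows(target, reference, config,
                          ref_distance_to_atg, ref_region_length)
  candidates <- call_candidates(scores, config, seq_id)
  structure(list(scores = scores, candidates = candidates, config = config),
            class = "crm_prediction")
}

#' @export
print.crm_prediction <- function(x, ...) {
  cat(sprintf("CRM prediction: %d windows scored, %d candidate(s)\n",
              nrow(x$scores), nrow(x$candidates)))
  print(x$candidates)
  invisible(x)
}
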