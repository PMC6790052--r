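# Seeded generator of planted-truth synthetic loci: a reference enhancer
# built from a binding-site grammar, a diverged ortholog (rigid or
# rearranged regime), and a random intergenic background with a recorded
# truth interval. Used to benchmark the predictor when real genomes are
# unavailable.

#' Default reference enhancer grammar
#'
#' A FoxF-style trunk-ventral-cell enhancer grammar: three Ets1/2 sites and
#' two homeodomain (ATTA) sites, with the first Ets site 10 bp upstream of
#' the first ATTA site (one helical turn) and 15 bp between the remaining
#' sites. The `gap` column is the spacer length preceding each site (`NA`
#' for the first site, which is placed by the flanking padding).
#'
#' @return data frame with columns `motif`, `word`, `strand`, `gap`.
#' @export
foxf_grammar <- function() {
  data.frame(
    motif = c("Ets1/2", "ATTA", "Ets1/2", "Ets1/2", "ATTA"),
    word = c("GGAT", "ATTA", "GGAA", "GGAT", "ATTA"),
    strand = c("+", "+", "+", "+", "+"),
    gap = c(NA, 10L, 15L, 15L, 15L),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic locus
#'
#' @param grammar binding-site grammar as in [foxf_grammar()].
#' @param enhancer_length total enhancer length in bp (grammar plus
#'   flanking spacer padding).
#' @param background_length length of the intergenic background region the
#'   diverged enhancer is planted into.
#' @param gc_content background/spacer GC fraction.
#' @param plant_position 0-based plant position, or `"random"`.
#' @param divergence_regime `"rigid"` (spacer substitutions only; sites,
#'   order, orientation, and spacing preserved) or `"rearranged"` (site
#'   gain/loss, strand flips, gap jitter).
#' @param spacer_substitution_rate per-base substitution probability in
#'   spacers (rigid regime).
#' @param p_gain,p_loss,p_flip per-site probabilities of duplication,
#'   deletion, and strand flip (rearranged regime).
#' @param gap_jitter maximum absolute gap perturbation in bp (rearranged
#'   regime; gaps are kept >= 2).
#' @param motifs motif set defining the planted grammar (used for
#'   spurious-hit rejection and architecture read-back).
#' @param ref_distance_to_atg,ref_region_length optional position metadata
#'   of the reference enhancer in its locus, consumed by the predictor's
#'   positional feature. Default `NULL`: a locus planted at a random
#'   position has no meaningful ATG-relative position, so the positional
#'   feature stays neutral; supply values when `plant_position` is fixed to
#'   emulate position-conserved orthologs.
#' @return a list of class `locus_spec`.
#' @export
locus_spec <- function(grammar = foxf_grammar(), enhancer_length = 183L,
                       background_length = 866L, gc_content = 0.4,
                       plant_position = "random",
                       divergence_regime = c("rigid", "rearranged"),
                       spacer_substitution_rate = 0.3,
                       p_gain = 0.15, p_loss = 0.15, p_flip = 0.15,
                       gap_jitter = 8L,
                       motifs = c("Ets1/2" = "GGAW", ATTA = "ATTA"),
                       ref_distance_to_atg = NULL,
                       ref_region_length = NULL) {
  divergence_regime <- match.arg(divergence_regime)
  stopifnot(is.data.frame(grammar),
            all(c("motif", "word", "strand", "gap") %in% names(grammar)))
  rates <- c(gc_content, spacer_substitution_rate, p_gain, p_loss, p_flip)
  if (any(rates < 0 | rates > 1)) {
    stop("rates and fractions must lie in [0, 1]", call. = FALSE)
  }
  motifs <- motif_set(motifs)
  for (i in seq_len(nrow(grammar))) {
    pat <- motifs[[grammar$motif[i]]]
    if (is.null(pat) || is.na(pat)) {
      stop(sprintf("grammar motif '%s' is not in the motif set",
                   grammar$motif[i]), call. = FALSE)
    }
    if (!grammar$word[i] %in% expand_iupac(pat)) {
      stop(sprintf("grammar word '%s' does not match pattern '%s'",
                   grammar$word[i], pat), call. = FALSE)
    }
  }
  structure(list(
    grammar = grammar, enhancer_length = as.integer(enhancer_length),
    background_length = as.integer(background_length),
    gc_content = gc_content, plant_position = plant_position,
    divergence_regime = divergence_regime,
    spacer_substitution_rate = spacer_substitution_rate,
    p_gain = p_gain, p_loss = p_loss, p_flip = p_flip,
    gap_jitter = as.integer(gap_jitter), motifs = motifs,
    ref_distance_to_atg = ref_distance_to_atg,
    ref_region_length = ref_region_length
  ), class = "locus_spec")
}

# Per-operation seed substreams: seed * 101 + offset keeps the substreams
# of consecutive replicate seeds disjoint (101 > number of operations).
sub_seed <- function(seed, op) {
  offsets <- c(reference = 1L, diverge = 2L, plant = 3L)
  as.integer(seed) * 101L + offsets[[op]]
}

random_bases <- function(n, gc) {
  if (n == 0L) return(character(0))
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# grammar -> (sequence chars, planted hit table) given total length;
# left padding centers the grammar span.
assemble_enhancer <- function(grammar, enhancer_length, gc) {
  words_fwd <- ifelse(grammar$strand == "-",
                      vapply(grammar$word, reverse_complement, character(1)),
                      grammar$word)
  gaps <- grammar$gap
  span <- sum(nchar(words_fwd)) + sum(gaps[-1L], na.rm = TRUE)
  if (span > enhancer_length) {
    stop(sprintf("grammar span (%d bp) exceeds enhancer length (%d bp)",
                 span, enhancer_length), call. = FALSE)
  }
  left <- (enhancer_length - span) %/% 2L
  chars <- random_bases(enhancer_length, gc)
  pos <- left
  planted <- vector("list", nrow(grammar))
  for (i in seq_len(nrow(grammar))) {
    if (i > 1L) pos <- pos + gaps[i]
    w <- strsplit(words_fwd[i], "")[[1L]]
    chars[(pos + 1L):(pos + length(w))] <- w
    planted[[i]] <- data.frame(motif = grammar$motif[i], start = pos,
                               end = pos + length(w),
                               strand = grammar$strand[i],
                               stringsAsFactors = FALSE)
    pos <- pos + length(w)
  }
  list(chars = chars, planted = do.call(rbind, planted))
}

# Redraw spacer bases under spurious motif hits until the scan recovers
# exactly the planted sites. Bases inside planted intervals are never
# touched.
scrub_spurious <- function(chars, planted, motifs, gc, max_iter = 100L) {
  protected <- rep(FALSE, length(chars))
  for (i in seq_len(nrow(planted))) {
    protected[(planted$start[i] + 1L):planted$end[i]] <- TRUE
  }
  key <- paste(planted$motif, planted$start, planted$end, planted$strand)
  for (iter in seq_len(max_iter)) {
    hits <- scan_motifs(paste0(chars, collapse = ""), motifs)
    hkey <- paste(hits$motif, hits$start, hits$end, hits$strand)
    spurious <- hits[!hkey %in% key, , drop = FALSE]
    if (nrow(spurious) == 0L) {
      missing <- setdiff(key, hkey)
      if (length(missing) > 0L) {
        stop("planted motif sites were destroyed during assembly",
             call. = FALSE)
      }
      return(chars)
    }
    for (i in seq_len(nrow(spurious))) {
      idx <- (spurious$start[i] + 1L):spurious$end[i]
      idx <- idx[!protected[idx]]
      if (length(idx) == 0L) {
        stop("spurious motif hit lies entirely within planted sites",
             call. = FALSE)
      }
      chars[idx] <- random_bases(length(idx), gc)
    }
  }
  stop(sprintf("could not scrub spurious motif hits in %d iterations",
               max_iter), call. = FALSE)
}

#' Generate the reference enhancer of a synthetic locus
#'
#' Deterministic for a fixed seed. Spacer bases are rejection-sampled so
#' that scanning the assembled enhancer with the spec's motif set recovers
#' exactly the planted sites (no spurious hits in spacers or across
#' site/spacer junctions).
#'
#' @param spec a [locus_spec()].
#' @param seed integer seed.
#' @return list with `sequence`, `architecture`
#'   ([architecture_of()] read-back), and `planted` (the truth hit table).
#' @export
make_reference_enhancer <- function(spec, seed) {
  stopifnot(inherits(spec, "locus_spec"))
  set.seed(sub_seed(seed, "reference"))
  asm <- assemble_enhancer(spec$grammar, spec$enhancer_length,
                           spec$gc_content)
  chars <- scrub_spurious(asm$chars, asm$planted, spec$motifs,
                          spec$gc_content)
  sequence <- paste0(chars, collapse = "")
  list(sequence = sequence,
       architecture = architecture_of(sequence, spec$motifs),
       planted = asm$planted)
}

#' Diverge a reference enhancer under a rigid or rearranged regime
#'
#' Rigid regime: motif words, order, orientations, and gaps are preserved
#' exactly; spacer bases are substituted independently at
#' `spec$spacer_substitution_rate` (substitutions that would create a
#' spurious motif site are redrawn). Rearranged regime: the grammar itself
#' is perturbed (site loss, duplication, strand flips, gap jitter) and the
#' enhancer is rebuilt with fresh spacers; at least one realized change is
#' guaranteed when any perturbation rate is positive.
#'
#' @param reference output of [make_reference_enhancer()].
#' @param spec the [locus_spec()].
#' @param seed integer seed.
#' @return list with `sequence`, `architecture`, `planted` for the
#'   ortholog enhancer.
#' @export
diverge <- function(reference, spec, seed) {
  stopifnot(inherits(spec, "locus_spec"))
  set.seed(sub_seed(seed, "diverge"))
  if (spec$divergence_regime == "rigid") {
    chars <- strsplit(reference$sequence, "")[[1L]]
    planted <- reference$planted
    protected <- rep(FALSE, length(chars))
    for (i in seq_len(nrow(planted))) {
      protected[(planted$start[i] + 1L):planted$end[i]] <- TRUE
    }
    spacer_idx <- which(!protected)
    hit <- spacer_idx[stats::runif(length(spacer_idx)) <
                        spec$spacer_substitution_rate]
    for (j in hit) {
      chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1L)
    }
    chars <- scrub_spurious(chars, planted, spec$motifs, spec$gc_content)
    sequence <- paste0(chars, collapse = "")
    return(list(sequence = sequence,
                architecture = architecture_of(sequence, spec$motifs),
                planted = planted))
  }

  # rearranged: perturb the grammar table, then rebuild
  base <- spec$grammar
  for (attempt in 1:100) {
    g <- base
    keep <- stats::runif(nrow(g)) >= spec$p_loss
    g <- g[keep, , drop = FALSE]
    if (nrow(g) > 0L) {
      dup <- which(stats::runif(nrow(g)) < spec$p_gain)
      if (length(dup) > 0L) {
        extra <- g[dup, , drop = FALSE]
        extra$gap <- pmax(2L, extra$gap, na.rm = FALSE)
        extra$gap[is.na(extra$gap)] <- 10L
        at <- sample(seq_len(nrow(g) + 1L), length(dup), replace = TRUE)
        for (k in seq_along(dup)) {
          pos <- min(at[k], nrow(g) + 1L)
          g <- rbind(utils::head(g, pos - 1L), extra[k, , drop = FALSE],
                     utils::tail(g, nrow(g) - pos + 1L))
        }
      }
      flip <- stats::runif(nrow(g)) < spec$p_flip
      g$strand[flip] <- ifelse(g$strand[flip] == "+", "-", "+")
      # rows moved away from the front need a concrete preceding gap
      if (nrow(g) > 1L) {
        inner <- g$gap[-1L]
        inner[is.na(inner)] <- 10L
        g$gap[-1L] <- inner
      }
      if (spec$gap_jitter > 0L && nrow(g) > 1L) {
        jit <- sample(seq(-spec$gap_jitter, spec$gap_jitter),
                      nrow(g) - 1L, replace = TRUE)
        g$gap[-1L] <- pmax(2L, g$gap[-1L] + jit)
      }
      g$gap[1L] <- NA
    }
    changed <- !isTRUE(all.equal(g, base, check.attributes = FALSE))
    any_rate <- spec$p_loss > 0 || spec$p_gain > 0 || spec$p_flip > 0 ||
      spec$gap_jitter > 0L
    if (changed || !any_rate) break
  }
  span <- sum(nchar(g$word)) + sum(g$gap[-1L], na.rm = TRUE)
  enh_len <- max(spec$enhancer_length, span + 20L)
  if (nrow(g) == 0L) {
    chars <- random_bases(enh_len, spec$gc_content)
    planted <- empty_hits()[, c("motif", "start", "end", "strand")]
    chars <- scrub_spurious(chars, planted, spec$motifs, spec$gc_content)
  } else {
    asm <- assemble_enhancer(g, enh_len, spec$gc_content)
    chars <- scrub_spurious(asm$chars, asm$planted, spec$motifs,
                            spec$gc_content)
    planted <- asm$planted
  }
  sequence <- paste0(chars, collapse = "")
  list(sequence = sequence,
       architecture = architecture_of(sequence, spec$motifs),
       planted = planted)
}

#' Plant an enhancer in a random intergenic background
#'
#' The background is i.i.d. per-base sequence at the spec's GC content; the
#' enhancer replaces a slice at the plant position, and the exact planted
#' span is recorded as the truth interval. The background is redrawn if it
#' happens to contain a second full copy of the enhancer.
#'
#' @param spec the [locus_spec()].
#' @param enhancer enhancer sequence to plant.
#' @param seed integer seed.
#' @return list with `region` (the background with the planted enhancer),
#'   `truth` (interval data frame), and `plant_position`.
#' @export
plant_in_background <- function(spec, enhancer, seed) {
  stopifnot(inherits(spec, "locus_spec"))
  set.seed(sub_seed(seed, "plant"))
  enhancer <- as_dna(enhancer, "enhancer")
  len <- nchar(enhancer)
  bg_len <- spec$background_length
  if (len > bg_len) {
    stop("background_length is smaller than the enhancer", call. = FALSE)
  }
  pos <- spec$plant_position
  if (identical(pos, "random")) {
    pos <- sample.int(bg_len - len + 1L, 1L) - 1L
  }
  pos <- as.integer(pos)
  if (pos < 0L || pos + len > bg_len) {
    stop("plant_position does not fit in the background", call. = FALSE)
  }
  for (attempt in 1:50) {
    chars <- random_bases(bg_len, spec$gc_content)
    chars[(pos + 1L):(pos + len)] <- strsplit(enhancer, "")[[1L]]
    region <- paste0(chars, collapse = "")
    copies <- find_all(region, enhancer)
    if (identical(copies, pos)) {
      return(list(region = region,
                  truth = genomic_interval("synthetic_region", pos,
                                           pos + len, "+"),
                  plant_position = pos))
    }
  }
  stop("background repeatedly contained a second enhancer copy",
       call. = FALSE)
}

#' Simulate a full synthetic locus pair
#'
#' Chains [make_reference_enhancer()], [diverge()], and
#' [plant_in_background()] under per-operation seed substreams, so each
#' stage is independently reproducible from the same global seed.
#'
#' @param spec a [locus_spec()].
#' @param seed integer global seed.
#' @return object of class `synthetic_pair`: `reference_enhancer`,
#'   `ortholog_enhancer`, `ortholog_region`, `truth` (interval of the
#'   planted ortholog enhancer in the region), `ref_architecture`,
#'   `ortholog_architecture`, and the `spec`.
#' @export
simulate_locus <- function(spec = locus_spec(), seed = 1L) {
  ref <- make_reference_enhancer(spec, seed)
  ort <- diverge(ref, spec, seed)
  planted <- plant_in_background(spec, ort$sequence, seed)
  structure(list(
    reference_enhancer = ref$sequence,
    ortholog_enhancer = ort$sequence,
    ortholog_region = planted$region,
    truth = planted$truth,
    ref_architecture = ref$architecture,
    ortholog_architecture = ort$architecture,
    spec = spec, seed = as.integer(seed)
  ), class = "synthetic_pair")
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf(
    "Synthetic locus (seed %d, %s regime): %d bp reference, %d bp region,\n",
    x$seed, x$spec$divergence_regime, nchar(x$reference_enhancer),
    nchar(x$ortholog_region)))
  cat(sprintf("  truth interval [%d, %d)\n", x$truth$start, x$truth$end))
  invisible(x)
}
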