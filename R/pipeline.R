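# Pipeline layer: stage functions that read/write standard formats
# (FASTA / BED6 / TSV / JSON) plus a single dispatching entry point.
# A thin command-line wrapper over these functions ships in
# inst/cli/crmtools.R.

cg_error <- function(class, msg) {
  stop(structure(class = c(class, "cg_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Read a motif library from a YAML file
#'
#' The file is a flat mapping of factor name to IUPAC pattern, e.g.
#' `Ets1/2: GGAW`.
#'
#' @param path YAML file.
#' @return validated named character vector ([motif_set()]).
#' @export
read_motifs <- function(path) {
  if (!file.exists(path)) {
    cg_error("cg_input_error", sprintf("motif file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw))) {
    cg_error("cg_config_error",
             sprintf("motif file %s is not a name: pattern mapping", path))
  }
  motif_set(vapply(raw, as.character, character(1)))
}

write_manifest <- function(out_dir, params, inputs = character(0)) {
  manifest <- list(
    package = "cisgrammar",
    version = as.character(utils::packageVersion("cisgrammar")),
    params = params,
    input_md5 = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list()
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

require_inputs <- function(...) {
  paths <- c(...)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    cg_error("cg_input_error",
             paste("missing input file(s):", paste(missing, collapse = ", ")))
  }
  paths
}

first_seq <- function(fasta_path) {
  seqs <- read_fasta(fasta_path)
  if (length(seqs) == 0L) {
    cg_error("cg_input_error", sprintf("no records in %s", fasta_path))
  }
  seqs[[1L]]
}

#' Simulate stage: write a synthetic locus to disk
#'
#' Writes `reference.fa`, `ortholog_region.fa`, `truth.bed`,
#' `architectures.json`, and `manifest.json` to `out_dir`.
#'
#' @param spec a [locus_spec()].
#' @param seed integer seed (required; outputs are byte-identical for a
#'   fixed spec and seed).
#' @param out_dir output directory (created if needed).
#' @return named character vector of output paths, invisibly.
#' @export
pipeline_simulate <- function(spec = locus_spec(), seed, out_dir) {
  if (missing(seed)) cg_error("cg_config_error", "simulate requires a seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pair <- simulate_locus(spec, seed)
  paths <- c(
    reference = file.path(out_dir, "reference.fa"),
    ortholog_region = file.path(out_dir, "ortholog_region.fa"),
    truth = file.path(out_dir, "truth.bed"),
    architectures = file.path(out_dir, "architectures.json")
  )
  write_fasta(c(reference_enhancer = pair$reference_enhancer),
              paths[["reference"]])
  write_fasta(c(synthetic_region = pair$ortholog_region),
              paths[["ortholog_region"]])
  truth <- pair$truth
  truth$name <- "truth"
  write_bed(truth, paths[["truth"]])
  arch_json <- lapply(
    list(reference = pair$ref_architecture,
         ortholog = pair$ortholog_architecture),
    function(a) list(hits = a$hits, gaps = a$gaps))
  jsonlite::write_json(arch_json, paths[["architectures"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- write_manifest(out_dir, params = list(
    subcommand = "simulate", seed = as.integer(seed),
    regime = spec$divergence_regime,
    enhancer_length = spec$enhancer_length,
    background_length = spec$background_length,
    gc_content = spec$gc_content,
    spacer_substitution_rate = spec$spacer_substitution_rate
  ), inputs = character(0))
  invisible(c(paths, manifest = manifest))
}

#' Predict stage: run the sliding-window predictor on FASTA inputs
#'
#' Writes `candidates.bed`, `scores.tsv`, and `manifest.json`.
#'
#' @param target_fa FASTA with the target region (first record used).
#' @param reference_fa FASTA with the reference enhancer.
#' @param config a [predictor_config()].
#' @param ref_distance_to_atg,ref_region_length reference position
#'   metadata for the positional feature (optional).
#' @param out_dir output directory.
#' @return named character vector of output paths, invisibly.
#' @export
pipeline_predict <- function(target_fa, reference_fa,
                             config = predictor_config(),
                             ref_distance_to_atg = NULL,
                             ref_region_length = NULL, out_dir) {
  require_inputs(target_fa, reference_fa)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  target <- first_seq(target_fa)
  reference <- first_seq(reference_fa)
  pred <- tryCatch(
    predict_enhancers(target, reference, config,
                      ref_distance_to_atg, ref_region_length,
                      seq_id = names(read_fasta(target_fa))[1L]),
    error = function(e) cg_error("cg_stage_error", conditionMessage(e)))
  paths <- c(candidates = file.path(out_dir, "candidates.bed"),
             scores = file.path(out_dir, "scores.tsv"))
  cand <- pred$candidates
  cand$name <- if (nrow(cand)) paste0("candidate_", cand$rank) else character(0)
  write_bed(cand, paths[["candidates"]])
  write_tsv(pred$scores, paths[["scores"]])
  manifest <- write_manifest(out_dir, params = list(
    subcommand = "predict", window_size = config$window_size,
    step = config$step, min_oligo = config$min_oligo,
    weights = config$weights, top_n = config$top_n,
    f1_mode = config$f1_mode, order_model = config$order_model
  ), inputs = c(target_fa, reference_fa))
  invisible(c(paths, manifest = manifest))
}

#' Scan stage: motif hits of a FASTA sequence as TSV
#'
#' @param input_fa FASTA (first record used).
#' @param motifs motif set or path to a YAML motif file.
#' @param out_dir output directory.
#' @return named character vector of output paths, invisibly.
#' @export
pipeline_scan <- function(input_fa, motifs = default_motifs(), out_dir) {
  require_inputs(input_fa)
  if (is.character(motifs) && length(motifs) == 1L && file.exists(motifs)) {
    motifs <- read_motifs(motifs)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hits <- scan_motifs(first_seq(input_fa), motifs)
  path <- file.path(out_dir, "hits.tsv")
  write_tsv(hits, path)
  manifest <- write_manifest(out_dir, params = list(
    subcommand = "scan", motifs = as.list(motifs)), inputs = input_fa)
  invisible(c(hits = path, manifest = manifest))
}

#' Compare stage: architecture comparison of two FASTA sequences
#'
#' Writes `comparison.json` with every field of the comparison.
#'
#' @param seq_a_fa,seq_b_fa FASTA inputs (first records used).
#' @param motifs motif set or YAML path.
#' @param helical_period helical period in bp.
#' @param out_dir output directory.
#' @return named character vector of output paths, invisibly.
#' @export
pipeline_compare <- function(seq_a_fa, seq_b_fa, motifs = default_motifs(),
                             helical_period = 10, out_dir) {
  require_inputs(seq_a_fa, seq_b_fa)
  if (is.character(motifs) && length(motifs) == 1L && file.exists(motifs)) {
    motifs <- read_motifs(motifs)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cmp <- compare_architectures(
    architecture_of(first_seq(seq_a_fa), motifs),
    architecture_of(first_seq(seq_b_fa), motifs),
    helical_period = helical_period)
  path <- file.path(out_dir, "comparison.json")
  jsonlite::write_json(unclass(cmp), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest <- write_manifest(out_dir, params = list(
    subcommand = "compare", helical_period = helical_period,
    motifs = as.list(motifs)), inputs = c(seq_a_fa, seq_b_fa))
  invisible(c(comparison = path, manifest = manifest))
}

resolve_directive <- function(hits, motif, index = NULL) {
  matches <- hits[hits$motif == motif, , drop = FALSE]
  if (nrow(matches) == 0L) {
    cg_error("cg_stage_error", sprintf("no hit of motif '%s'", motif))
  }
  if (is.null(index)) {
    if (nrow(matches) > 1L) {
      where <- paste(sprintf("[%d,%d)%s", matches$start, matches$end,
                             matches$strand), collapse = " ")
      cg_error("cg_stage_error", sprintf(
        "directive for motif '%s' is ambiguous: %d hits (%s); give an index",
        motif, nrow(matches), where))
    }
    index <- 1L
  }
  if (index < 1L || index > nrow(matches)) {
    cg_error("cg_stage_error", sprintf(
      "motif '%s' has %d hit(s); index %d out of range",
      motif, nrow(matches), index))
  }
  matches[index, , drop = FALSE]
}

#' Apply a list of in-silico mutagenesis directives to a sequence
#'
#' Directives are applied left to right in the order given. Each directive
#' is a list with `op` (`"knockout"` or `"displace"`), `motif`, an optional
#' `index` (1-based, hits ordered by start; required when the motif has
#' several hits), and for displacement a signed `delta` in bp (negative =
#' upstream) plus an optional `anchor_motif`/`anchor_index`.
#'
#' @param seq input sequence.
#' @param edits list of directives (possibly empty: the sequence is
#'   returned unchanged).
#' @param motifs motif set used for hit resolution and verification.
#' @return list with `sequence` (edited) and `report` (one row per edit:
#'   op, motif, span, before/after words, and the motif's hit count after
#'   the edit).
#' @export
apply_edits <- function(seq, edits, motifs = default_motifs()) {
  seq <- as_dna(seq, "seq")
  motifs <- motif_set(motifs)
  report <- list()
  for (e in edits) {
    hits <- scan_motifs(seq, motifs)
    hit <- resolve_directive(hits, e$motif, e$index)
    before <- hit$match
    if (identical(e$op, "knockout")) {
      seq2 <- knockout_motif(seq, hit, motifs)
      after <- substring(seq2, hit$start + 1L, hit$end)
      span <- c(hit$start, hit$end)
    } else if (identical(e$op, "displace")) {
      anchor <- if (!is.null(e$anchor_motif)) {
        resolve_directive(hits, e$anchor_motif, e$anchor_index)
      } else NULL
      seq2 <- displace_motif(seq, hit, e$delta, anchor_hit = anchor,
                             motifs = motifs, hits = hits)
      after <- substring(seq2, hit$start + e$delta + 1L,
                         hit$end + e$delta)
      span <- c(hit$start + e$delta, hit$end + e$delta)
    } else {
      cg_error("cg_config_error",
               sprintf("unknown edit op '%s'", as.character(e$op)))
    }
    n_after <- sum(scan_motifs(seq2, motifs)$motif == e$motif)
    report[[length(report) + 1L]] <- data.frame(
      op = e$op, motif = e$motif, start = span[1L], end = span[2L],
      before = before, after = after, hits_after = n_after,
      stringsAsFactors = FALSE)
    seq <- seq2
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(op = character(0), motif = character(0), start = integer(0),
               end = integer(0), before = character(0), after = character(0),
               hits_after = integer(0), stringsAsFactors = FALSE)
  list(sequence = seq, report = report)
}

#' Mutate stage: apply mutagenesis directives to a FASTA sequence
#'
#' Writes `mutated.fa`, `edits.tsv`, and `manifest.json`.
#'
#' @param input_fa FASTA input (first record used).
#' @param edits directive list, as for [apply_edits()].
#' @param motifs motif set or YAML path.
#' @param out_dir output directory.
#' @param seed seed for randomized knockout replacements.
#' @return named character vector of output paths, invisibly.
#' @export
pipeline_mutate <- function(input_fa, edits, motifs = default_motifs(),
                            out_dir, seed = 1L) {
  require_inputs(input_fa)
  if (is.character(motifs) && length(motifs) == 1L && file.exists(motifs)) {
    motifs <- read_motifs(motifs)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))
  res <- apply_edits(first_seq(input_fa), edits, motifs)
  paths <- c(mutated = file.path(out_dir, "mutated.fa"),
             edits = file.path(out_dir, "edits.tsv"))
  write_fasta(setNames(res$sequence, "mutated"), paths[["mutated"]])
  write_tsv(res$report, paths[["edits"]])
  manifest <- write_manifest(out_dir, params = list(
    subcommand = "mutate", seed = as.integer(seed),
    n_edits = length(edits)), inputs = input_fa)
  invisible(c(paths, manifest = manifest))
}

#' Run one pipeline stage from a configuration list
#'
#' Single entry point dispatching on `config$subcommand`
#' (`"simulate"`, `"scan"`, `"predict"`, `"compare"`, `"mutate"`); the
#' remaining elements of `config` are passed to the stage function. Every
#' stage writes a `manifest.json` (parameters, seed, input checksums)
#' alongside its outputs, and identical config + seed produce identical
#' outputs.
#'
#' @param config named list; must contain `subcommand` and the stage's
#'   arguments (see `pipeline_simulate()` and friends).
#' @return named character vector of output paths, invisibly.
#' @export
run_pipeline <- function(config) {
  sub <- config$subcommand
  if (is.null(sub)) cg_error("cg_config_error", "config lacks a subcommand")
  config$subcommand <- NULL
  fn <- switch(sub,
               simulate = pipeline_simulate,
               scan = pipeline_scan,
               predict = pipeline_predict,
               compare = pipeline_compare,
               mutate = pipeline_mutate,
               cg_error("cg_config_error",
                        sprintf("unknown subcommand '%s'", sub)))
  do.call(fn, config)
}
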