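tvc_motifs <- c("Ets1/2" = "GGAW", ATTA = "ATTA")

test_that("a planted grammar is read back in order with its gaps", {
  # E,E,E,A,A grammar assembled by hand with known gaps
  # spacers chosen so no Ets/ATTA word (either strand) spans a junction
  seq <- paste0("CAGCC", "GGAT", "GCGCCGCGCG", "GGAA", "CGCCC", "GGAT",
                "GCGCCGCGC", "ATTA", "GCCGCAG", "ATTA", "GCCGC")
  arch <- architecture_of(seq, tvc_motifs)
  expect_identical(arch$types, c("Ets1/2", "Ets1/2", "Ets1/2", "ATTA", "ATTA"))
  expect_identical(arch$strands, rep("+", 5))
  expect_equal(arch$gaps, c(10, 5, 9, 7))

  # zero configured motifs present -> empty architecture
  empty <- architecture_of("CCGCCGCCGC", tvc_motifs)
  expect_equal(nrow(empty$hits), 0)
  expect_length(empty$gaps, 0)
})

test_that("the default synthetic reference carries the FoxF-style grammar", {
  ref <- make_reference_enhancer(locus_spec(), 99)
  expect_identical(ref$architecture$types,
                   c("Ets1/2", "ATTA", "Ets1/2", "Ets1/2", "ATTA"))
  expect_equal(ref$architecture$gaps[1], 10)  # E1-A1, one helical turn
})

test_that("self-comparison is perfectly conserved for arbitrary grammars", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    words <- sample(c("GGAT", "GGAA", "ATTA"), n, replace = TRUE)
    motif <- ifelse(words == "ATTA", "ATTA", "Ets1/2")
    strand <- sample(c("+", "-"), n, replace = TRUE)
    g <- data.frame(motif = motif, word = words, strand = strand,
                    gap = c(NA, sample(8:20, n - 1, replace = TRUE)))
    spec <- locus_spec(grammar = g, enhancer_length = 200,
                       motifs = tvc_motifs)
    ref <- make_reference_enhancer(spec, 400 + i)
    cmp <- compare_architectures(ref$architecture, ref$architecture)
    expect_equal(cmp$rigidity, 1)
    expect_equal(cmp$order_conservation, 1)
    expect_equal(cmp$orientation_agreement, 1)
    expect_true(all(cmp$spacing_deltas == 0))
    expect_true(all(cmp$count_deltas == 0))
  }
})

test_that("a single strand flip lowers orientation agreement only", {
  spec <- locus_spec()
  ref <- make_reference_enhancer(spec, 7)
  a <- ref$architecture
  b <- ref$architecture
  b$strands[2] <- "-"
  b$hits$strand[2] <- "-"
  cmp <- compare_architectures(a, b)
  expect_lt(cmp$orientation_agreement, 1)
  expect_equal(cmp$order_conservation, 1)
  expect_lt(cmp$rigidity, 1)
})

test_that("helical phase arithmetic wraps at the period", {
  expect_equal(spacing_phase(10, 20), 0)  # one full turn: in phase
  expect_equal(spacing_phase(10, 16), 6)
  expect_equal(spacing_phase(10, 24), 4)
  expect_equal(spacing_phase(12, 12), 0)
  expect_error(spacing_phase(10, 16, period = 0), "period")
  expect_error(spacing_phase(-1, 5), "gaps")
})

test_that("each elementary perturbation strictly lowers rigidity", {
  spec <- locus_spec()
  set.seed(66)
  for (seed in c(11, 12, 13)) {
    ref <- make_reference_enhancer(spec, seed)
    a <- ref$architecture

    flip <- a
    k <- sample(length(flip$strands), 1)
    flip$strands[k] <- ifelse(flip$strands[k] == "+", "-", "+")
    flip$hits$strand[k] <- flip$strands[k]
    expect_lt(compare_architectures(a, flip)$rigidity, 1)

    respace <- a
    shift <- 7L
    respace$hits$start[-1] <- respace$hits$start[-1] + shift
    respace$hits$end[-1] <- respace$hits$end[-1] + shift
    respace$gaps <- respace$hits$start[-1] -
      respace$hits$end[-nrow(respace$hits)]
    expect_lt(compare_architectures(a, respace)$rigidity, 1)

    dropped <- a
    keep <- setdiff(seq_len(nrow(a$hits)), sample(nrow(a$hits), 1))
    dropped$hits <- dropped$hits[keep, , drop = FALSE]
    dropped$types <- dropped$types[keep]
    dropped$strands <- dropped$strands[keep]
    n <- nrow(dropped$hits)
    dropped$gaps <- if (n >= 2) dropped$hits$start[-1] -
      dropped$hits$end[-n] else integer(0)
    expect_lt(compare_architectures(a, dropped)$rigidity, 1)
  }
})

test_that("order conservation is 1 exactly for identical type strings of equal length", {
  spec <- locus_spec()
  ref <- make_reference_enhancer(spec, 21)
  a <- ref$architecture
  expect_equal(compare_architectures(a, a)$order_conservation, 1)
  b <- a
  b$types <- rev(b$types)
  b$hits$motif <- rev(b$hits$motif)
  expect_lt(compare_architectures(a, b)$order_conservation, 1)
})

test_that("comparing architectures from different motif sets is refused", {
  seq <- "CCGGATCCATTACC"
  a <- architecture_of(seq, tvc_motifs)
  b <- architecture_of(seq, c("Ets1/2" = "GGAW"))
  expect_error(compare_architectures(a, b), "different motif sets")
})
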