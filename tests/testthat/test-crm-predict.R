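test_that("shared oligomer tiling matches the brute-force oracle", {
  # identity: the whole window is one maximal tile
  set.seed(3)
  ref <- random_dna(20)
  t <- shared_oligomers(ref, ref)
  expect_equal(nrow(t), 1)
  expect_identical(t$word, ref)
  expect_equal(t$window_offset, 0)

  # the greedy longest match may come from the reverse strand:
  # rc("TTACGTTT") = "AAACGTAA" contains the 5-mer ACGTA
  t <- shared_oligomers("ACGTACGT", "TTACGTTT")
  expect_identical(t$word, oracle_tiling("ACGTACGT", "TTACGTTT"))
  expect_identical(t$word, "ACGTA")

  # nothing shared
  expect_equal(nrow(shared_oligomers("AAAAAAAA", "CCCCCCCC")), 0)

  set.seed(17)
  for (i in 1:60) {
    w <- random_dna(sample(4:40, 1))
    r <- random_dna(sample(4:40, 1))
    expect_identical(shared_oligomers(w, r)$word, oracle_tiling(w, r),
                     info = paste(w, r))
  }
})

test_that("tiles never overlap, appear left to right, and exist in the reference", {
  set.seed(23)
  for (i in 1:20) {
    w <- random_dna(60)
    r <- random_dna(60)
    t <- shared_oligomers(w, r)
    if (nrow(t) < 1) next
    expect_true(all(t$length >= 4))
    expect_true(all(diff(t$window_offset) >= t$length[-nrow(t)]))
    for (j in seq_len(nrow(t))) {
      expect_true(grepl(t$word[j], r, fixed = TRUE) ||
                    grepl(t$word[j], oracle_rc(r), fixed = TRUE))
      expect_identical(substring(w, t$window_offset[j] + 1,
                                 t$window_offset[j] + t$length[j]), t$word[j])
    }
  }
})

test_that("ordering distance is the adjacent-transposition minimum", {
  expect_equal(ordering_steps(c("A", "B"), c("A", "B")), 0L)
  expect_equal(ordering_steps(c("A", "B"), c("B", "A")), 1L)
  expect_equal(ordering_steps(c("A", "B", "C"), c("C", "A", "B")), 2L)
  expect_error(ordering_steps(c("A", "B"), c("A", "A")), "multiset")

  set.seed(31)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    labels <- sample(LETTERS[1:4], n, replace = TRUE)
    a <- sample(labels)
    b <- sample(labels)
    got <- ordering_steps(a, b)
    expect_equal(got, oracle_bfs_steps(a, b), info = paste(i))
    # metric axioms
    expect_equal(ordering_steps(a, a), 0L)
    expect_equal(got, ordering_steps(b, a))
    cc <- sample(labels)
    expect_lte(got, ordering_steps(a, cc) + ordering_steps(cc, b))
  }
})

test_that("feature vector is perfect for a self-comparison", {
  set.seed(8)
  ref <- random_dna(30)
  fv <- feature_vector(ref, ref, window_start = 0,
                       target_region_length = 100,
                       ref_distance_to_atg = 100, ref_region_length = 100,
                       config = predictor_config(window_size = 30))
  expect_equal(fv$f2_ordering, 1)
  expect_equal(fv$f3_position, 1)
})

test_that("a window without required motifs scores F4 = 0", {
  fv <- feature_vector("ACACACACACACACAC", reference = "ACACACACACACACAC",
                       config = predictor_config(window_size = 16))
  expect_equal(fv$f4_motifs, 0)
  expect_equal(fv$f4_norm, 0)
})

test_that("the combined score is monotone in each feature under non-negative weights", {
  set.seed(12)
  for (i in 1:50) {
    w <- runif(4)
    f <- runif(4)
    base <- combine_features(f, w)
    j <- sample(4, 1)
    f2 <- f
    f2[j] <- min(1, f[j] + runif(1, 0, 1 - f[j]))
    expect_gte(combine_features(f2, w), base - 1e-12)
    expect_true(base >= 0 && base <= 1)
  }
})

test_that("window enumeration follows floor((L - w)/step) + 1", {
  set.seed(44)
  ref <- random_dna(183)
  sc <- score_windows(random_dna(866), ref)
  expect_equal(nrow(sc), 29)  # floor((866-150)/25)+1
  expect_equal(sc$window_start, seq(0, 700, by = 25))

  expect_equal(nrow(score_windows(random_dna(150), ref)), 1)
  expect_error(score_windows(random_dna(149), ref),
               "region shorter than window")
})

test_that("candidate calling ranks, breaks ties leftward, and can merge", {
  cfg <- predictor_config(top_n = 3)
  one <- data.frame(window_start = 0L, score = 0.7)
  cand <- call_candidates(one, cfg)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$end - cand$start, 150)
  expect_equal(cand$rank, 1)

  # two equal non-adjacent peaks: tie broken toward the smaller start
  sc <- data.frame(window_start = c(0L, 200L, 400L),
                   score = c(0.9, 0.1, 0.9))
  cand <- call_candidates(sc, predictor_config(top_n = 2, score_quantile = 0))
  expect_equal(cand$start[1], 0)
  expect_equal(cand$start[2], 400)

  # overlapping above-threshold windows merge into their union
  sc <- data.frame(window_start = c(0L, 25L, 50L), score = c(0.8, 0.9, 0.85))
  merged <- call_candidates(sc, predictor_config(top_n = 3,
                                                 score_quantile = 0,
                                                 merge = TRUE))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, 0)
  expect_equal(merged$end, 200)
  expect_equal(merged$score, 0.9)

  expect_error(call_candidates(sc[0, ], cfg), "empty")
  expect_error(predictor_config(top_n = 0), "top_n")
  expect_error(predictor_config(weights = c(-1, 1, 1, 1)), "non-negative")
  expect_error(predictor_config(min_oligo = 0), "min_oligo")
})

test_that("shared-oligomer features ignore reference orientation", {
  set.seed(77)
  for (i in 1:10) {
    w <- random_dna(40)
    r <- random_dna(60)
    cfg <- predictor_config(window_size = 40)
    f_fwd <- feature_vector(w, r, config = cfg)
    f_rev <- feature_vector(w, reverse_complement(r), config = cfg)
    expect_equal(f_fwd$f1_oligomers, f_rev$f1_oligomers)
  }
})

test_that("an exactly planted reference copy attains the maximal F1", {
  spec <- locus_spec(divergence_regime = "rigid",
                     spacer_substitution_rate = 0)
  for (seed in c(301, 302, 303)) {
    pair <- simulate_locus(spec, seed)
    expect_identical(pair$ortholog_enhancer, pair$reference_enhancer)
    sc <- score_windows(pair$ortholog_region, pair$reference_enhancer)
    best <- sc$window_start[sc$f1_oligomers == max(sc$f1_oligomers)]
    expect_true(any(best < pair$truth$end & best + 150 > pair$truth$start))
  }
})
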