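ets <- c("Ets1/2" = "GGAW")

test_that("IUPAC expansion enumerates exactly the degenerate words", {
  expect_identical(expand_iupac("GGAW"), c("GGAA", "GGAT"))
  expect_identical(expand_iupac("GGNG"), c("GGAG", "GGCG", "GGGG", "GGTG"))
  expect_identical(expand_iupac("ATTA"), "ATTA")
  expect_error(expand_iupac("GGAX"), "non-IUPAC")
  expect_error(expand_iupac(""), "non-empty")

  set.seed(11)
  letters15 <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")
  for (i in 1:10) {
    pat <- paste0(sample(letters15, sample(2:5, 1), replace = TRUE),
                  collapse = "")
    got <- expand_iupac(pat)
    expect_identical(got, oracle_expand(pat))
    degeneracy <- prod(lengths(oracle_iupac[strsplit(pat, "")[[1]]]))
    expect_length(got, degeneracy)
  }
})

test_that("motif scanning finds degenerate sites on both strands", {
  hits <- scan_motifs("AAGGATAA", ets)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 2)
  expect_equal(hits$end, 6)
  expect_identical(hits$strand, "+")
  expect_identical(hits$match, "GGAT")

  # reverse-strand site: forward text reads ATCC = rc(GGAT)
  hits <- scan_motifs("AAATCCAA", ets)
  expect_equal(nrow(hits), 1)
  expect_identical(hits$strand, "-")
  expect_equal(hits$start, 2)
  expect_identical(hits$match, "ATCC")

  # the knocked-out word GCTT is not an Ets site on either strand
  expect_equal(nrow(scan_motifs("AAGCTTAA", ets)), 0)

  # a reverse-complement palindromic site is reported once per strand
  hits <- scan_motifs("TACGTA", c(pal = "ACGT"))
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(unique(hits$start), 1)

  expect_error(scan_motifs("ACGT", character(0)), "empty")
})

test_that("N matches no motif letter, degenerate or literal", {
  expect_equal(nrow(scan_motifs("AAGGNTAA", ets)), 0)
  expect_equal(nrow(scan_motifs("AAGGNGAA", c(TBX6 = "GGNG"))), 0)
})

test_that("scanning agrees with the naive expanded-word oracle", {
  motifs <- default_motifs()
  set.seed(101)
  for (i in 1:40) {
    s <- random_dna(sample(4:60, 1), gc = runif(1, 0.3, 0.7))
    expect_identical(scan_motifs(s, motifs), oracle_scan(s, motifs))
  }
})

test_that("hits on a sequence and its reverse complement mirror each other", {
  motifs <- default_motifs()
  set.seed(202)
  for (i in 1:15) {
    s <- random_dna(60)
    h_fwd <- scan_motifs(s, motifs)
    h_rev <- scan_motifs(reverse_complement(s), motifs)
    # reflect h_rev back onto the forward coordinates
    L <- nchar(s)
    reflected <- data.frame(
      motif = h_rev$motif,
      start = L - h_rev$end,
      end = L - h_rev$start,
      strand = ifelse(h_rev$strand == "+", "-", "+"),
      stringsAsFactors = FALSE)
    key <- function(d) sort(paste(d$motif, d$start, d$end, d$strand))
    expect_identical(key(reflected), key(h_fwd[, names(reflected)]))
  }
})

test_that("knockout removes the targeted site without creating new ones", {
  motifs <- default_motifs()
  seq <- "AAAAGGATAAAA"
  hit <- scan_motifs(seq, ets)
  out <- knockout_motif(seq, hit, motifs)
  # the classic fixed substitution applies
  expect_identical(out, "AAAAGCTTAAAA")
  expect_equal(nchar(out), nchar(seq))
  expect_equal(nrow(scan_motifs(out, ets)), 0)
  # bases outside the span untouched
  expect_identical(substring(out, 1, 4), "AAAA")
  expect_identical(substring(out, 9, 12), "AAAA")

  # in a context where the fixed word would itself create a site on the
  # other strand (GCTT + CC -> TTCC = rc(GGAA)), the policy falls back to
  # resampling and still satisfies the contract
  set.seed(1)
  seq2 <- "CCCCGGATCCCC"
  hit2 <- scan_motifs(seq2, ets)[1, ]
  out2 <- knockout_motif(seq2, hit2, motifs)
  rescanned <- scan_motifs(out2, motifs)
  expect_false(any(rescanned$start < hit2$end & rescanned$end > hit2$start))
})

test_that("knockout of an ATTA site leaves neither ATTA nor TAAT", {
  motifs <- c(ATTA = "ATTA")
  set.seed(5)
  seq <- "GGCGATTAGCGG"
  hit <- scan_motifs(seq, motifs)
  expect_equal(nrow(hit), 1)
  out <- knockout_motif(seq, hit, motifs)
  expect_equal(nchar(out), nchar(seq))
  rescanned <- scan_motifs(out, motifs)
  expect_false(any(rescanned$start < hit$end & rescanned$end > hit$start))
  # nothing to remove afterwards: the site is gone for good
  expect_equal(sum(grepl("ATTA|TAAT", substring(out, hit$start + 1, hit$end))), 0)
})

test_that("knockout never increases any configured motif's hit count", {
  motifs <- default_motifs()
  set.seed(33)
  for (i in 1:10) {
    s <- random_dna(80)
    hits <- scan_motifs(s, motifs)
    if (nrow(hits) == 0) next
    target <- hits[sample(nrow(hits), 1), , drop = FALSE]
    out <- knockout_motif(s, target, motifs)
    before <- table(factor(scan_motifs(s, motifs)$motif, names(motifs)))
    after <- table(factor(scan_motifs(out, motifs)$motif, names(motifs)))
    expect_true(all(after <= before))
    expect_lt(after[[target$motif]], before[[target$motif]])
  }
})

test_that("displacement changes the gap to the anchor but not the hit count", {
  motifs <- c("Ets1/2" = "GGAW", ATTA = "ATTA")
  # E1 at [4,8), A1 at [18,22): gap 10 bp
  set.seed(9)
  seq <- paste0("CCGC", "GGAT", "CGCCGCCGCG", "ATTA", "GCCGCGCC")
  hits <- scan_motifs(seq, motifs)
  e1 <- hits[hits$motif == "Ets1/2", ][1, ]
  a1 <- hits[hits$motif == "ATTA", ][1, ]
  expect_equal(a1$start - e1$end, 10)

  moved <- displace_motif(seq, e1, delta = -4L, anchor_hit = a1,
                          motifs = motifs)
  expect_equal(nchar(moved), nchar(seq))
  new_hits <- scan_motifs(moved, motifs)
  new_e <- new_hits[new_hits$motif == "Ets1/2", ]
  new_a <- new_hits[new_hits$motif == "ATTA", ]
  expect_equal(nrow(new_e), 1)  # count preserved
  expect_equal(nrow(new_a), 1)
  expect_equal(new_a$start - new_e$end, 14)

  # identity displacement
  expect_identical(displace_motif(seq, e1, 0L, motifs = motifs), seq)

  # destination overlapping the anchor is refused
  expect_error(displace_motif(seq, e1, 12L, anchor_hit = a1, motifs = motifs),
               "anchor")
})
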