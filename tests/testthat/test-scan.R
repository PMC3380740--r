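test_that("scoring matrices match closed-form log-ratios", {
  # strict column, uniform background, zero pseudocount (floored)
  sm <- make_scoring_matrix(consensus_motif("t", "A"), pseudocount = 0)
  expect_equal(unname(sm$llr[1, "A"]), 2)          # log2(1 / 0.25)
  expect_true(all(is.finite(sm$llr)))

  # uniform column scores 0 everywhere
  smu <- make_scoring_matrix(motif_matrix("u", matrix(0.25, 1, 4)))
  expect_equal(unname(smu$llr[1, ]), rep(0, 4), tolerance = 1e-12)

  # JASPAR-style counts (8,2,0,0) with pseudocount 0.1: hand-computed
  m <- motif_matrix("j", matrix(c(8, 2, 0, 0), 1, 4))
  smj <- make_scoring_matrix(m, pseudocount = 0.1)
  hand <- log2(((c(8, 2, 0, 0) + 0.1 * 0.25) / 10.1) / 0.25)
  expect_equal(unname(smj$llr[1, ]), hand, tolerance = 1e-12)

  expect_error(make_scoring_matrix(consensus_motif("t", "A"),
                                   background = c(0.5, 0.5, 0.2, -0.2)),
               "background")
})

test_that("DP p-values hit exact corner cases", {
  sm <- make_scoring_matrix(consensus_motif("t4", "ACGT"), pseudocount = 0)
  pmap <- score_pvalue_function(sm)
  expect_equal(pmap(attr(pmap, "max_score")), 4^-4)   # unique best word
  expect_equal(pmap(attr(pmap, "min_score")), 1)
  expect_equal(pmap(attr(pmap, "min_score") - 10), 1)
  expect_error(score_pvalue_function(sm, granularity = 10), "granularity")

  # monotone non-increasing over a fine grid
  grid <- seq(attr(pmap, "min_score") - 1, attr(pmap, "max_score") + 1,
              length.out = 200)
  expect_true(all(diff(pmap(grid)) <= 1e-15))
})

test_that("DP p-values agree with exhaustive enumeration on random matrices", {
  withr_seed(99, {
    for (rep in 1:10) {
      w <- sample(2:6, 1)
      m <- motif_matrix(paste0("r", rep),
                        matrix(stats::runif(4 * w, 0.05, 1), w, 4))
      sm <- make_scoring_matrix(m)
      pmap <- score_pvalue_function(sm)
      oracle <- enum_pvalue_oracle(sm$llr, sm$background)
      u <- attr(pmap, "unit")
      ths <- stats::runif(20, attr(pmap, "min_score"), attr(pmap, "max_score"))
      for (s in ths) {
        lo <- oracle(s + w * u + 1e-12)
        hi <- oracle(s - w * u - 1e-12)
        expect_gte(pmap(s), lo - 1e-12)
        expect_lte(pmap(s), hi + 1e-12)
      }
    }
  })
})

test_that("scanning enumerates hits on both strands", {
  # palindromic strict motif ACGT on ACGTA: window 0 matches on + and, as
  # its own reverse complement, on - as well; window 1 (CGTA) matches neither
  sm <- make_scoring_matrix(consensus_motif("m", "ACGT"), pseudocount = 0)
  hits <- scan_regions(sm, c(r1 = "ACGTA"), p_threshold = 1 / 256)
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(unique(hits$offset), 0)

  # non-palindromic motif AACC in AGGTT: only rc(window 1) = AACC matches
  sm2 <- make_scoring_matrix(consensus_motif("m2", "AACC"), pseudocount = 0)
  hits2 <- scan_regions(sm2, c(r1 = "AGGTT"), p_threshold = 1 / 256)
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$offset, 1)
  expect_equal(hits2$strand, "-")

  # ambiguous bases never match
  expect_equal(nrow(scan_regions(sm, c(r1 = "NNNNNN"), p_threshold = 1)), 0)
  expect_equal(nrow(scan_regions(sm, c(r1 = "ACNTA"), p_threshold = 1 / 256)), 0)

  expect_error(scan_regions(sm, c(r1 = "ACGT"), p_threshold = 0), "p_threshold")
  expect_error(scan_regions(sm, c(r1 = "ACGT"), p_threshold = 1.5), "p_threshold")
})

test_that("hit counts are monotone in the p-value threshold", {
  seqs <- random_dna(30, 300, seed = 7)
  m <- consensus_motif("m", "ACGTAC", degeneracy = 0.2)
  sm <- make_scoring_matrix(m)
  ths <- c(1e-4, 1e-3, 1e-2, 0.1, 0.5)
  counts <- vapply(ths, function(th)
    nrow(scan_regions(sm, seqs, p_threshold = th)), numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[length(counts)], 0)
})

test_that("strand symmetry: scanning the reverse complement reflects hits", {
  withr_seed(21, {
    seqs <- random_dna(5, 120)
    m <- motif_matrix("r", matrix(stats::runif(20, 0.05, 1), 5, 4))
    sm <- make_scoring_matrix(m)
    rc <- function(s) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    fwd <- scan_regions(sm, seqs, p_threshold = 0.01)
    rev_ <- scan_regions(sm, vapply(seqs, rc, character(1)),
                         p_threshold = 0.01)
    expect_equal(nrow(fwd), nrow(rev_))
    key <- function(h, L) sort(paste(h$region_id,
                                     L - 5 - h$offset,
                                     ifelse(h$strand == "+", "-", "+"),
                                     round(h$score, 6)))
    expect_equal(sort(paste(fwd$region_id, fwd$offset, fwd$strand,
                            round(fwd$score, 6))),
                 key(rev_, 120))
  })
})

test_that("Benjamini-Hochberg q-values follow the hand formula", {
  h1 <- data.frame(motif = "m", region_id = "r", offset = 0, strand = "+",
                   score = 1, p_value = 0.01, q_value = NA_real_)
  expect_equal(attach_qvalues(h1, 1)$q_value, 0.01)

  h2 <- data.frame(motif = "m", region_id = c("a", "b"), offset = 0,
                   strand = "+", score = 1, p_value = c(0.001, 0.002),
                   q_value = NA_real_)
  expect_equal(attach_qvalues(h2, 2)$q_value, c(0.002, 0.002))

  # against the BH definition computed independently, with n_tests > hits
  withr_seed(5, {
    p <- sort(stats::runif(10, 0, 0.01))
    hs <- data.frame(motif = "m", region_id = letters[1:10], offset = 0,
                     strand = "+", score = 1, p_value = p,
                     q_value = NA_real_)
    n <- 1000
    manual <- rev(cummin(rev(p * n / seq_along(p))))
    expect_equal(attach_qvalues(hs, n)$q_value, pmin(manual, 1))
  })
  expect_error(attach_qvalues(h2, 1), "n_tests")
})

test_that("region hit counting separates hits from hit-bearing regions", {
  regions <- region_set(rep("c", 10), (0:9) * 100, (0:9) * 100 + 50,
                        id = paste0("r", 1:10))
  hits <- data.frame(motif = "m", region_id = rep("r1", 3),
                     offset = c(0, 5, 9), strand = "+", score = 1,
                     p_value = 1e-6, q_value = NA_real_)
  got <- count_region_hits(hits, regions)
  expect_equal(got$total_hits, 3)
  expect_equal(got$regions_with_hit, 1)
  expect_equal(got$regions_without_hit, 9)

  none <- hits[0, ]
  expect_equal(count_region_hits(none, regions)$regions_with_hit, 0)
  expect_equal(count_region_hits(none, regions)$total_hits, 0)

  bad <- hits; bad$region_id <- "nope"
  expect_error(count_region_hits(bad, regions), "unknown region")
})

test_that("hit tables round-trip through TSV", {
  sm <- make_scoring_matrix(consensus_motif("m", "ACGT"), pseudocount = 0)
  hits <- scan_regions(sm, c(r1 = "ACGTACGT"), p_threshold = 1 / 256)
  hits <- attach_qvalues(hits, n_scanned_positions(c(r1 = "ACGTACGT"), 4))
  f <- tempfile(fileext = ".tsv")
  write_hits(hits, f, comments = "demo")
  back <- read_hits(f)
  expect_equal(back$offset, hits$offset)
  expect_equal(back$p_value, hits$p_value, tolerance = 1e-12)
  expect_true(all(back$q_value >= back$p_value - 1e-12))
})
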