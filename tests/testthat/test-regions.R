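test_that("BED reading maps fields, assigns ids and validates bounds", {
  gt <- c(chr1 = 1000, chr2 = 500)
  bed <- tempfile(fileext = ".bed")

  writeLines("chr1\t100\t200", bed)
  rs <- read_bed(bed, genome = gt)
  expect_equal(nrow(rs), 1)
  expect_equal(rs$chrom, "chr1")
  expect_equal(rs$start, 100)
  expect_equal(rs$end, 200)
  expect_equal(region_lengths(rs), 100)
  expect_equal(rs$id, "chr1:100-200")

  writeLines(c("chr1\t0\t10\tpeak_a", "chr2\t5\t500\tpeak_b"), bed)
  rs <- read_bed(bed, genome = gt)
  expect_equal(rs$id, c("peak_a", "peak_b"))

  writeLines(character(0), bed)
  expect_equal(nrow(read_bed(bed, genome = gt)), 0)

  writeLines(c("chr1\t1\t2", "chr1\tfoo\t2"), bed)
  expect_error(read_bed(bed, genome = gt), "line 2")
  writeLines(c("chr1\t1\t2", "chr1\t3"), bed)
  expect_error(read_bed(bed, genome = gt), "line 2")
  writeLines("chr1\t900\t1100", bed)
  expect_error(read_bed(bed, genome = gt), "beyond chromosome")
  writeLines("chrX\t1\t2", bed)
  expect_error(read_bed(bed, genome = gt), "chrX")
})

test_that("BED round-trips through write_bed and counts/means are bookkept", {
  gt <- c(chr1 = 1e6)
  n <- 40
  starts <- seq(0, by = 2000, length.out = n)
  rs <- region_set(rep("chr1", n), starts, starts + 1500, genome = gt)
  bed <- tempfile(fileext = ".bed")
  write_bed(rs, bed)
  back <- read_bed(bed, genome = gt)
  expect_equal(as.data.frame(back), as.data.frame(rs))
  expect_equal(mean(region_lengths(back)), 1500)
})

test_that("region_set enforces its invariants", {
  expect_error(region_set("chr1", 10, 10), "start < end")
  expect_error(region_set("chr1", -1, 5), "start < end")
  expect_error(region_set(c("chr1", "chr1"), c(0, 5), c(10, 15),
                          id = c("x", "x")), "unique")
  expect_error(region_set(c("chr1", "chr1"), c(0, 5), c(10, 15),
                          role = "coldspot"), "non-overlapping")
})

test_that("sequence extraction slices, uppercases and masks to N", {
  genome <- c(chr1 = "ACGTACGT")
  rs <- region_set(c("chr1", "chr1"), c(0, 4), c(4, 8), id = c("r1", "r2"))
  seqs <- extract_sequences(rs, genome)
  expect_equal(unname(seqs), c("ACGT", "ACGT"))
  expect_equal(names(seqs), c("r1", "r2"))

  # masked/ambiguous region, cross-checked against a raw slice of the FASTA
  fasta <- tempfile(fileext = ".fa")
  raw_seq <- "ttacgnnACGTRyacg"
  writeLines(c(">chr9", raw_seq), fasta)
  rs2 <- region_set("chr9", 2, 7, id = "m")
  got <- extract_sequences(rs2, fasta)
  manual <- toupper(substr(raw_seq, 3, 7))
  manual <- gsub("[^ACGT]", "N", manual)
  expect_equal(unname(got), manual)
  expect_equal(unname(got), "ACGNN")

  expect_error(extract_sequences(region_set("chrZ", 0, 2), genome), "chrZ")
})

test_that("coldspot sampling respects the exclusion zone and is deterministic", {
  gt <- c(chr1 = 1e6)
  hs <- region_set("chr1", 400000, 403000, id = "h1", genome = gt)
  cs <- sample_coldspots(hs, gt, min_distance = 50000, seed = 3)
  expect_equal(nrow(cs), 1)
  expect_equal(region_lengths(cs), 3000)
  # span must avoid [350000, 453000)
  expect_true(cs$end <= 350000 || cs$start >= 453000)

  cs2 <- sample_coldspots(hs, gt, min_distance = 50000, seed = 3)
  expect_identical(as.data.frame(cs), as.data.frame(cs2))
})

test_that("repeated coldspot draws are valid and lengths are conserved", {
  gt <- c(chr1 = 2e6, chr2 = 2e6)
  hs <- region_set(rep(c("chr1", "chr2"), each = 8),
                   start = rep((0:7) * 2.4e5, 2),
                   end = rep((0:7) * 2.4e5, 2) + rep(c(2000, 3500), 8),
                   role = "hotspot", genome = gt)
  placements <- list()
  for (seed in 1:20) {
    cs <- sample_coldspots(hs, gt, min_distance = 50000, seed = seed)
    v <- validate_coldspots(cs, hs, min_distance = 50000)
    expect_true(v$pass)
    for (ch in c("chr1", "chr2")) {
      expect_equal(sum(region_lengths(cs[cs$chrom == ch, ])),
                   sum(region_lengths(hs[hs$chrom == ch, ])))
    }
    placements[[seed]] <- cs$start
  }
  # different seeds should give different placements (smoke check)
  expect_gt(length(unique(vapply(placements, paste, character(1),
                                 collapse = ","))), 15)
})

test_that("coldspot validation reports distance and overlap violations", {
  gt <- c(chr1 = 1e6)
  hs <- region_set("chr1", 400000, 403000, id = "h1", genome = gt)
  near <- region_set("chr1", 403010, 406010, id = "c1", role = "coldspot",
                     genome = gt)
  v <- validate_coldspots(near, hs, min_distance = 50000)
  expect_false(v$pass)
  expect_match(v$first_violation, "within 50000")

  # overlapping controls (constructed as plain data.frame to bypass the
  # constructor's own overlap check)
  over <- region_set(rep("chr1", 2), c(100000, 101000), c(103000, 104000),
                     id = c("c1", "c2"), genome = gt)
  attr(over, "role") <- "coldspot"
  v2 <- validate_coldspots(over, hs, min_distance = 50000)
  expect_false(v2$pass)
  expect_true(any(grepl("overlap", v2$violations)))

  good <- sample_coldspots(hs, gt, min_distance = 50000, seed = 1)
  expect_true(validate_coldspots(good, hs, 50000)$pass)
})

test_that("placement failure names the chromosome", {
  # no slot fits: the exclusion zone plus interval length exceed both flanks
  gt <- c(tiny = 105000)
  hs <- region_set("tiny", 50000, 53000, genome = gt)
  expect_error(sample_coldspots(hs, gt, min_distance = 50000, seed = 1,
                                max_attempts = 50), "tiny")
})

test_that("N-fraction filter rejects gap-saturated placements", {
  # left half of the chromosome is all N: controls must land on the right
  gt <- c(chr1 = 4e5)
  genome <- c(chr1 = paste0(strrep("N", 2e5),
                            paste(sample(c("A", "C", "G", "T"), 2e5,
                                         replace = TRUE), collapse = "")))
  hs <- region_set("chr1", 240000, 243000, genome = gt)
  cs <- sample_coldspots(hs, gt, min_distance = 20000, seed = 2,
                         genome_seq = genome, max_n_fraction = 0.1)
  sq <- extract_sequences(cs, genome)
  expect_lt(mean(strsplit(sq, "")[[1]] == "N"), 0.1)
})
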