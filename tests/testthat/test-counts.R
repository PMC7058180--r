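test_that("allele counting reproduces constructed tallies", {
  loc <- toy_locus()
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_fixture(sam, loc, n_ref = 8, n_var = 4)
  counts <- count_alleles(sam, loc)
  expect_equal(counts$n_ref, 8L)
  expect_equal(counts$n_var, 4L)
  expect_equal(counts$n_other, 0L)
})

test_that("mapping-quality and base-quality filters remove reads", {
  loc <- toy_locus()
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_fixture(sam, loc, n_ref = 8, n_var = 4, mapq_var = 5)
  counts <- count_alleles(sam, loc,
                          read_filter_config(min_mapping_quality = 20))
  expect_equal(c(counts$n_ref, counts$n_var), c(8L, 0L))
  # same fixture, permissive MQ: everything back
  counts <- count_alleles(sam, loc,
                          read_filter_config(min_mapping_quality = 0))
  expect_equal(c(counts$n_ref, counts$n_var), c(8L, 4L))

  write_sam_fixture(sam, loc, n_ref = 6, n_var = 3, base_quality = 10)
  counts <- count_alleles(sam, loc,
                          read_filter_config(min_base_quality = 20))
  expect_equal(c(counts$n_ref, counts$n_var), c(0L, 0L))
})

test_that("read-length, gap, and duplicate filters apply", {
  loc <- toy_locus()
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_fixture(sam, loc, n_ref = 5, n_var = 2, read_length = 25)
  counts <- count_alleles(sam, loc,
                          read_filter_config(min_read_length = 30))
  expect_equal(counts$n_ref + counts$n_var, 0L)
  counts <- count_alleles(sam, loc,
                          read_filter_config(min_read_length = 20))
  expect_equal(c(counts$n_ref, counts$n_var), c(5L, 2L))

  # a read with two indel events vs a max_gap_events=1 filter
  reads <- data.frame(
    qname = c("gappy", "clean"), flag = 0L, chrom = "chr1",
    pos = c(80L, 90L), mapq = 60L,
    cigar = c("10M2I10M2D20M", "40M"), rnext = "*", pnext = 0L, tlen = 0L,
    seq = c(paste(rep("A", 42), collapse = ""),
            paste(rep("A", 40), collapse = "")),
    qual = c(strrep("I", 42), strrep("I", 40)), stringsAsFactors = FALSE)
  write_sam(sam, reads, c(chr1 = 2000L))
  counts <- count_alleles(sam, loc,
                          read_filter_config(max_gap_events = 1,
                                             min_read_length = 30))
  expect_equal(counts$n_ref, 1L)

  # duplicate-flagged read (0x400) is excluded by default
  reads <- data.frame(
    qname = c("r1", "r2"), flag = c(0L, 1024L), chrom = "chr1",
    pos = 61L, mapq = 60L, cigar = "50M", rnext = "*", pnext = 0L,
    tlen = 0L, seq = paste(rep("A", 50), collapse = ""),
    qual = strrep("I", 50), stringsAsFactors = FALSE)
  write_sam(sam, reads, c(chr1 = 2000L))
  expect_equal(count_alleles(sam, loc)$n_ref, 1L)
  permissive <- read_filter_config(exclude_duplicates = FALSE)
  expect_equal(count_alleles(sam, loc, permissive)$n_ref, 2L)
})

test_that("splice gaps and deletions at the locus are handled", {
  loc <- toy_locus()
  sam <- withr::local_tempfile(fileext = ".sam")
  reads <- data.frame(
    qname = c("spliced", "deleted", "plain"), flag = 0L, chrom = "chr1",
    pos = c(90L, 90L, 90L), mapq = 60L,
    cigar = c("5M20N45M", "5M10D40M", "50M"),
    rnext = "*", pnext = 0L, tlen = 0L,
    seq = c(paste(rep("A", 50), collapse = ""),
            paste(rep("A", 45), collapse = ""),
            paste(rep("A", 50), collapse = "")),
    qual = c(strrep("I", 50), strrep("I", 45), strrep("I", 50)),
    stringsAsFactors = FALSE)
  write_sam(sam, reads, c(chr1 = 2000L))
  counts <- count_alleles(sam, loc)
  # spliced read has no aligned base at 100; deleted read counts as other
  expect_equal(counts$n_ref, 1L)
  expect_equal(counts$n_other, 1L)
})

test_that("overlapping mates count once per fragment", {
  loc <- toy_locus()
  sam <- withr::local_tempfile(fileext = ".sam")
  seq50 <- paste(rep("A", 50), collapse = "")
  reads <- data.frame(
    qname = c("frag1", "frag1", "frag2"), flag = c(99L, 147L, 0L),
    chrom = "chr1", pos = c(70L, 95L, 90L), mapq = 60L, cigar = "50M",
    rnext = c("=", "=", "*"), pnext = c(95L, 70L, 0L),
    tlen = c(75L, -75L, 0L), seq = seq50, qual = strrep("I", 50),
    stringsAsFactors = FALSE)
  write_sam(sam, reads, c(chr1 = 2000L))
  counts <- count_alleles(sam, loc)
  expect_equal(counts$n_ref, 2L)
  no_dedup <- read_filter_config(dedup_overlapping_mates = FALSE)
  expect_equal(count_alleles(sam, loc, no_dedup)$n_ref, 3L)
})

test_that("tally total is bounded by covering reads, with equality when permissive", {
  loc <- toy_locus()
  sam <- withr::local_tempfile(fileext = ".sam")
  set.seed(3)
  for (rep in 1:3) {
    n_ref <- sample(0:10, 1); n_var <- sample(0:10, 1)
    write_sam_fixture(sam, loc, n_ref = n_ref, n_var = n_var, seed = rep)
    permissive <- read_filter_config(min_mapping_quality = 0,
                                     min_base_quality = 0,
                                     min_read_length = 0)
    counts <- count_alleles(sam, loc, permissive)
    expect_equal(counts$n_ref + counts$n_var + counts$n_other,
                 n_ref + n_var)
    strict <- count_alleles(sam, loc, read_filter_config())
    expect_lte(strict$n_ref + strict$n_var + strict$n_other,
               n_ref + n_var)
  }
})

test_that("absent chromosome warns and yields zero counts", {
  loc <- rbind(toy_locus(),
               toy_locus(chrom = "chrZ", pos = 40L, ref = "C", alt = "T"))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam_fixture(sam, loc[1, ], n_ref = 3, n_var = 3)
  expect_warning(counts <- count_alleles(sam, loc), "chrZ")
  expect_equal(counts$n_ref, c(3L, 0L))
})

test_that("VAF follows the count formula with the coverage rule", {
  v <- compute_vaf(c(15, 6, 20, 0), c(5, 3, 0, 0))
  expect_equal(v$value, c(0.25, NA, 0, NA))
  expect_equal(v$coverage, c(20, 9, 20, 0))
  # scale consistency: doubling counts leaves the value unchanged
  set.seed(4)
  n_ref <- sample(5:50, 20); n_var <- sample(5:50, 20)
  expect_equal(compute_vaf(n_ref, n_var, 1)$value,
               compute_vaf(2 * n_ref, 2 * n_var, 1)$value)
  # monotone missingness in the coverage threshold
  for (thr in c(1, 5, 10, 20, 50)) {
    lo <- is.na(compute_vaf(n_ref, n_var, thr)$value)
    hi <- is.na(compute_vaf(n_ref, n_var, thr + 10)$value)
    expect_true(all(!lo | hi))
  }
})

test_that("genotype fractions, allelic states, and concordance map exactly", {
  expect_equal(genotype_to_fraction(c(0, 1, 2, NA)), c(0, 0.5, 1, NA))
  g <- matrix(c(0, 3), 1, 2, dimnames = list("chr1:5_A>G", c("s1", "s2")))
  expect_error(genotype_to_fraction(g), "s2")

  expect_equal(classify_allelic_state(c(0, 0.5, 1, 0.01, NA)),
               c("monoallelic_ref", "biallelic", "monoallelic_var",
                 "biallelic", NA))
  # composition property: genotype -> fraction -> state
  expect_equal(classify_allelic_state(genotype_to_fraction(0:2)),
               c("monoallelic_ref", "biallelic", "monoallelic_var"))

  states <- c("monoallelic_ref", "biallelic", "monoallelic_var")
  grid <- expand.grid(g = 0:2, s = states, stringsAsFactors = FALSE)
  got <- concordance(grid$g, grid$s)
  expect_equal(got == "concordant",
               (grid$g == 0 & grid$s == "monoallelic_ref") |
                 (grid$g == 1 & grid$s == "biallelic") |
                 (grid$g == 2 & grid$s == "monoallelic_var"))
  expect_equal(concordance(c(NA, 2), c("biallelic", NA)),
               c("unevaluable", "unevaluable"))
})

test_that("count tables round-trip through the TSV dialect", {
  counts <- data.frame(locus_id = c("chr1:100_A>G", "chr1:200_C>T"),
                       n_ref = c(15L, 6L), n_var = c(5L, 3L),
                       n_other = c(0L, 1L), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts(counts, f)
  back <- read_counts(f)
  expect_equal(back$n_ref, counts$n_ref)
  expect_equal(back$vaf, c(0.25, NA))
})
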