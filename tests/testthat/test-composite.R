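# A 600 bp region with no masks unless stated; reads built by make_read()
# default to Phred 40 everywhere.

region600 <- random_seq(600, seed = 1)
nomask600 <- logical(600)

test_that("alignment filters apply in fixed order with the published thresholds", {
  long_read <- substr(region600, 1, 500)
  base <- make_read("r1", long_read, read_length = 600)
  # score threshold 220: 219 fails on score even if identity also low
  r <- filter_alignments(dplyr::mutate(base, score = 219, pct_identity = 50),
                         nomask600)
  expect_false(r$accept)
  expect_equal(r$reject_reason, "score")
  # macaque at exactly 88.0 identity passes; all other criteria satisfied
  r <- filter_alignments(
    dplyr::mutate(base, species = "macaque", pct_identity = 88.0, score = 300),
    nomask600)
  expect_true(r$accept)
  # human at 93.9 fails identity
  r <- filter_alignments(dplyr::mutate(base, pct_identity = 93.9), nomask600)
  expect_equal(r$reject_reason, "identity")
  # aligned length must exceed 300 bp
  short <- make_read("r2", substr(region600, 1, 300), read_length = 600)
  expect_equal(filter_alignments(short, nomask600)$reject_reason,
               "aligned_length")
  # aligned fraction must exceed 40% of the read
  frac <- make_read("r3", substr(region600, 1, 301), read_length = 1000)
  expect_equal(filter_alignments(frac, nomask600)$reject_reason,
               "aligned_fraction")
  # >200 high-quality bases required
  lowq <- make_read("r4", long_read, read_length = 600,
                    qual = paste0(qual_str(40, 200), qual_str(10, 300)))
  expect_equal(filter_alignments(lowq, nomask600)$reject_reason, "hq_bases")
  # >200 unmasked aligned bases required
  heavy_mask <- c(logical(200), rep(TRUE, 400))
  expect_equal(filter_alignments(base, heavy_mask)$reject_reason,
               "unmasked_bases")
  # unknown species is a configuration error
  expect_error(filter_alignments(dplyr::mutate(base, species = "mouse"),
                                 nomask600), "unknown species")
})

mutate_at_pos <- function(seq, pos, base) {
  substr(seq, pos + 1, pos + 1) <- base
  seq
}

test_that("composite requires two supporting reads and collapses alleles to a binary flag", {
  ref <- strsplit(region600, "")[[1]]
  p <- 50L
  alt1 <- setdiff(c("A", "C", "G", "T"), ref[p + 1])[1]
  alt2 <- setdiff(c("A", "C", "G", "T"), ref[p + 1])[2]
  read_with <- function(id, base, species = "human") {
    make_read(id, mutate_at_pos(substr(region600, 1, 400), p, base),
              species = species)
  }
  # no reads: all-false diff, zero coverage
  comp0 <- build_composite(make_read("x", "ACGT")[0, ], region600, nomask600)
  expect_false(any(comp0$diff))
  expect_true(all(comp0$coverage == 0))
  # a single high-quality mismatch is not enough
  comp1 <- build_composite(read_with("r1", alt1), region600, nomask600)
  expect_false(comp1$diff[p + 1])
  expect_equal(unname(comp1$support["human", p + 1]), 1L)
  # three reads with two distinct alternative bases: one binary change
  aln3 <- dplyr::bind_rows(read_with("r1", alt1), read_with("r2", alt1),
                           read_with("r3", alt2))
  comp3 <- build_composite(aln3, region600, nomask600)
  expect_true(comp3$diff[p + 1])
  expect_equal(sum(comp3$diff), 1L)
  expect_equal(unname(comp3$support["human", p + 1]), 3L)
  # strict same-allele mode still passes here (alt1 seen twice) but fails
  # with only one read per allele
  expect_true(build_composite(aln3, region600, nomask600,
                              same_allele = TRUE)$diff[p + 1])
  aln2 <- dplyr::bind_rows(read_with("r1", alt1), read_with("r3", alt2))
  expect_true(build_composite(aln2, region600, nomask600)$diff[p + 1])
  expect_false(build_composite(aln2, region600, nomask600,
                               same_allele = TRUE)$diff[p + 1])
  # pooled vs per-species support: one human + one macaque read
  cross <- dplyr::bind_rows(read_with("r1", alt1),
                            read_with("r2", alt1, species = "macaque"))
  expect_true(build_composite(cross, region600, nomask600)$diff[p + 1])
  expect_false(build_composite(cross, region600, nomask600,
                               pool_species = FALSE)$diff[p + 1])
})

test_that("low-quality and masked mismatches never become differences", {
  ref <- strsplit(region600, "")[[1]]
  p <- 50L
  alt <- setdiff(c("A", "C", "G", "T"), ref[p + 1])[1]
  seq <- mutate_at_pos(substr(region600, 1, 400), p, alt)
  # Phred 26 sits below the >= 27 threshold
  qual <- paste0(qual_str(26, 51), qual_str(40, 349))
  aln <- dplyr::bind_rows(make_read("r1", seq, qual = qual),
                          make_read("r2", seq, qual = qual))
  expect_false(build_composite(aln, region600, nomask600)$diff[p + 1])
  # the same reads at Phred 27 do support a difference
  qual27 <- paste0(qual_str(27, 51), qual_str(40, 349))
  aln27 <- dplyr::bind_rows(make_read("r1", seq, qual = qual27),
                            make_read("r2", seq, qual = qual27))
  expect_true(build_composite(aln27, region600, nomask600)$diff[p + 1])
  # a masked position can never carry a difference
  masked <- nomask600
  masked[p + 1] <- TRUE
  comp <- build_composite(aln27, region600, masked)
  expect_false(comp$diff[p + 1])
  expect_false(any(comp$diff & comp$masked))
})

test_that("composite is invariant to read order and monotone under added reads", {
  set.seed(11)
  reads <- purrr::map(1:8, function(i) {
    start <- sample(0:200, 1)
    seq <- substr(region600, start + 1, start + 360)
    for (k in sample(360, 5)) {
      seq <- mutate_at_pos(seq, k - 1,
                           sample(c("A", "C", "G", "T"), 1))
    }
    make_read(paste0("r", i), seq, region_start = start,
              species = sample(c("human", "macaque"), 1))
  })
  aln <- dplyr::bind_rows(reads)
  comp_a <- build_composite(aln, region600, nomask600)
  comp_b <- build_composite(aln[sample(nrow(aln)), ], region600, nomask600)
  expect_identical(comp_a$diff, comp_b$diff)
  expect_identical(comp_a$support, comp_b$support)
  expect_identical(comp_a$coverage, comp_b$coverage)
  expect_identical(comp_a$alt, comp_b$alt)
  # adding a read never unsets a diff or lowers coverage
  comp_sub <- build_composite(aln[1:7, ], region600, nomask600)
  expect_true(all(comp_a$diff[comp_sub$diff]))
  expect_true(all(comp_a$coverage >= comp_sub$coverage))
  # support never exceeds total coverage
  expect_true(all(colSums(comp_a$support) <= colSums(comp_a$coverage)))
})

test_that("reads outside the region are rejected with a log entry", {
  off <- make_read("runaway", substr(region600, 1, 400), region_start = 350L)
  comp <- build_composite(off, region600, nomask600)
  expect_equal(comp$rejected$read_id, "runaway")
  expect_true(all(comp$coverage == 0))
})

test_that("coverage_profile averages over unmasked positions only", {
  comp <- make_composite(substr(region600, 1, 8),
                         cov_hs = c(2L, 2L, 4L, 4L, 9L, 9L, 9L, 9L),
                         cov_mmu = rep(5L, 8),
                         masked = c(rep(FALSE, 4), rep(TRUE, 4)))
  prof <- coverage_profile(comp, 0, 4)
  expect_equal(prof$cov_human, 3)
  expect_equal(prof$cov_macaque, 5)
  # uniform coverage returns the constant
  expect_equal(coverage_profile(comp, 2, 4)$cov_human, 4)
  # fully masked interval: zero with a flag
  prof_masked <- coverage_profile(comp, 4, 8)
  expect_equal(prof_masked$cov_human, 0)
  expect_true(prof_masked$all_masked)
  expect_error(coverage_profile(comp, 4, 4), "empty")
})
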