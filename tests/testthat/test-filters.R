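test_that("macaque coverage comparability rule", {
  pair <- function(ex, it) tibble::tibble(cov_mmu_exon = ex, cov_mmu_intron = it)
  expect_false(coverage_filter(pair(2.5, 1.5)))
  expect_true(coverage_filter(pair(2.5, 2.5)))
  expect_true(coverage_filter(pair(1.0, 0.5)))
})

test_that("intronic rate floor is a strict cut at 0.01", {
  expect_false(di_floor_filter(tibble::tibble(D_i = 0.009)))
  expect_true(di_floor_filter(tibble::tibble(D_i = 0.01)))
  expect_true(di_floor_filter(tibble::tibble(D_i = 0.04)))
})

test_that("tandem-domain gene list rule", {
  expect_false(tandem_domain_filter("NPIP", c("NPIP", "GOLGA")))
  expect_true(tandem_domain_filter("CD58", c("NPIP", "GOLGA")))
  expect_true(tandem_domain_filter("CD58", character()))
})

# two-exon transcript on a 2000 bp region: exon1 [500, 700), exon2 [1200, 1400)
two_exon_region <- function(seed = 13) {
  t <- make_tx(ex_start = c(500L, 1200L), ex_end = c(700L, 1400L), flank = 500L)
  t$region_start <- 0L
  t$region_end <- 2000L
  list(t_local = to_region_local(t), region_seq = random_seq(2000, seed = seed))
}

test_that("junction-spanning reads are flagged as pseudogene evidence", {
  fx <- two_exon_region()
  junction <- make_read(
    "pg1",
    paste0(substr(fx$region_seq, 601, 700), substr(fx$region_seq, 1201, 1300)),
    region_start = 600L, cigar = "100M500N100M", species = "macaque")
  genomic <- make_read("gen1", substr(fx$region_seq, 601, 800),
                       region_start = 600L)
  inside <- make_read("in1", substr(fx$region_seq, 501, 680),
                      region_start = 500L)
  aln <- dplyr::bind_rows(junction, genomic, inside)
  expect_equal(detect_pseudogene_reads(aln, fx$t_local), "pg1")
  # a skip that does not line up with the exon boundaries is not flagged
  shifted <- make_read("pg2", paste0(substr(fx$region_seq, 601, 700),
                                     substr(fx$region_seq, 1301, 1400)),
                       region_start = 600L, cigar = "100M600N100M")
  expect_equal(detect_pseudogene_reads(shifted, fx$t_local), character(0))
  # single-exon transcripts can never be flagged
  single <- toy_region()
  expect_equal(detect_pseudogene_reads(aln, single$t_local), character(0))
})

# mutate a string at 0-based positions to fixed bases
mutate_str <- function(s, pos, base) {
  for (k in seq_along(pos)) substr(s, pos[k] + 1, pos[k] + 1) <- base[k]
  s
}

test_that("pseudogene recomputation discards exons whose excess is read-borne", {
  fx <- two_exon_region()
  nomask <- logical(2000)
  ref <- fx$region_seq
  # two junction reads sharing 4 planted exon-1 mismatches
  ex_pos <- c(620L, 640L, 660L, 680L)
  ref_at <- substring(ref, ex_pos + 1L, ex_pos + 1L)
  pg_seq <- mutate_str(
    paste0(substr(ref, 601, 700), substr(ref, 1201, 1300)),
    ex_pos - 600L, ifelse(ref_at == "A", "C", "A"))
  pg <- dplyr::bind_rows(
    make_read("pg1", pg_seq, region_start = 600L, cigar = "100M500N100M",
              species = "macaque"),
    make_read("pg2", pg_seq, region_start = 600L, cigar = "100M500N100M",
              species = "macaque"))
  # two intronic macaque reads sharing 6 mismatches left of the exon
  in_pos <- c(100L, 150L, 200L, 250L, 300L, 350L)
  in_seq <- substr(ref, 51, 450)
  in_seq <- mutate_str(in_seq, in_pos - 50L,
                       ifelse(strsplit(substr(ref, 51, 450), "")[[1]][in_pos - 50 + 1] == "G",
                              "T", "G"))
  intron_reads <- dplyr::bind_rows(
    make_read("i1", in_seq, region_start = 50L, species = "macaque"),
    make_read("i2", in_seq, region_start = 50L, species = "macaque"))
  aln <- dplyr::bind_rows(pg, intron_reads)
  comp <- build_composite(aln, ref, nomask)
  masks <- list(all = nomask)
  w <- select_intron_reference(fx$t_local, 1, masks)
  pair <- count_differences(comp, 500L, 700L, w, exon_id = "e1",
                            transcript_id = fx$t_local$transcript_id)
  expect_gt(pair$D_e, pair$D_i)
  flagged <- detect_pseudogene_reads(aln, fx$t_local)
  expect_setequal(flagged, c("pg1", "pg2"))
  rec <- pseudogene_recompute(pair, aln, flagged, comp)
  expect_false(rec$keep)
  expect_lt(rec$pair$D_e, rec$pair$D_i)
  # removing reads can never increase the exonic rate
  expect_lte(rec$pair$D_e, pair$D_e)
  # with nothing flagged the recomputation is the identity
  rec0 <- pseudogene_recompute(pair, aln, character(0), comp)
  expect_true(rec0$keep)
  expect_equal(rec0$pair$x_e, pair$x_e)
})

# Exon of TAC codons at [100, 200) on a 1000 bp region; third-codon C -> A
# creates TAA stops.
stop_fixture <- function() {
  region <- paste0(strrep("G", 100), strrep("TAC", 33), "T", strrep("G", 800))
  region <- substr(region, 1, 1000)
  t <- make_tx(ex_start = 100L, ex_end = 200L, flank = 100L)
  t$region_start <- 0L
  t$region_end <- 1000L
  list(t_local = to_region_local(t), region = region,
       third_pos = 100L + 3L * (0:32) + 2L)
}

test_that("stop-codon sensitivity distinguishes robust from fragile exons", {
  fx <- stop_fixture()
  nomask <- logical(1000)
  stop_sites <- fx$third_pos[1:20]
  shared <- stop_sites[1:15]
  exon_read <- function(id, sites, base, species = "human") {
    make_read(id, mutate_str(substr(fx$region, 51, 450), sites - 50L,
                             rep(base, length(sites))),
              region_start = 50L, species = species)
  }
  # intron support: 8 shared mismatches in [300, 700)
  in_pos <- seq(450L, 660L, by = 30L)
  intron_read <- function(id) {
    make_read(id, mutate_str(substr(fx$region, 251, 750), in_pos - 250L,
                             rep("C", length(in_pos))),
              region_start = 250L, species = "macaque")
  }
  windows <- tibble::tibble(start = c(0L, 300L), end = c(50L, 700L),
                            side = c("5prime", "3prime"))
  windows <- windows[2, ]
  base_reads <- dplyr::bind_rows(intron_read("i1"), intron_read("i2"))
  # robust: the 15 shared sites are also supported by two stop-free reads
  # carrying the synonymous alternative at the same sites
  aln_rob <- dplyr::bind_rows(
    exon_read("s1", stop_sites, "A"), exon_read("s2", stop_sites, "A"),
    exon_read("c1", shared, "T"), exon_read("c2", shared, "T"),
    base_reads)
  comp_rob <- build_composite(aln_rob, fx$region, nomask)
  pair_rob <- count_differences(comp_rob, 100L, 200L, windows,
                                transcript_id = fx$t_local$transcript_id)
  rep_rob <- stop_codon_sensitivity(pair_rob, comp_rob, aln_rob, fx$t_local)
  expect_equal(rep_rob$status, "robust")
  expect_equal(rep_rob$n_stop_reads, 2L)
  expect_equal(rep_rob$n_stop_diffs, 5L)
  # fragile: all exon differences ride on the stop-carrying reads
  aln_fra <- dplyr::bind_rows(
    exon_read("s1", stop_sites, "A"), exon_read("s2", stop_sites, "A"),
    base_reads)
  comp_fra <- build_composite(aln_fra, fx$region, nomask)
  pair_fra <- count_differences(comp_fra, 100L, 200L, windows,
                                transcript_id = fx$t_local$transcript_id)
  expect_gt(lrt_exon(pair_fra)$statistic, 3.84)
  rep_fra <- stop_codon_sensitivity(pair_fra, comp_fra, aln_fra, fx$t_local)
  expect_equal(rep_fra$status, "fragile")
  expect_equal(rep_fra$n_stop_diffs, 20L)
  # no stop reads at all: trivially robust
  rep_none <- stop_codon_sensitivity(pair_fra, comp_fra, base_reads, fx$t_local)
  expect_equal(rep_none$status, "robust")
  expect_equal(rep_none$n_stop_reads, 0L)
})

test_that("tiling path requires gap-free coverage over unmasked positions", {
  ref <- random_seq(500, seed = 3)
  cov <- rep(3L, 500)
  comp <- make_composite(ref, cov_hs = cov, cov_mmu = integer(500))
  w <- tibble::tibble(start = 300L, end = 400L, side = "3prime")
  expect_true(tiling_path_check(comp, 100L, 200L, w))
  # a single zero-coverage base mid-exon fails
  cov2 <- cov; cov2[150] <- 0L
  comp2 <- make_composite(ref, cov_hs = cov2, cov_mmu = integer(500))
  expect_false(tiling_path_check(comp2, 100L, 200L, w))
  # the same hole inside a masked segment is exempt
  masked <- logical(500); masked[150] <- TRUE
  comp3 <- make_composite(ref, cov_hs = cov2, cov_mmu = integer(500),
                          masked = masked)
  expect_true(tiling_path_check(comp3, 100L, 200L, w))
})

test_that("strict tiling additionally demands overlapping reads", {
  ref <- random_seq(500, seed = 4)
  # two abutting reads: positions covered but no read spans the junction
  abut <- dplyr::bind_rows(
    make_read("a", substr(ref, 1, 250)),
    make_read("b", substr(ref, 251, 500), region_start = 250L))
  comp <- build_composite(abut, ref, logical(500))
  w <- tibble::tibble(start = integer(), end = integer(), side = character())
  expect_true(tiling_path_check(comp, 200L, 300L, w))
  expect_false(tiling_path_check(comp, 200L, 300L, w, aln = abut, strict = TRUE))
  # an overlapping third read fixes it
  span <- make_read("c", substr(ref, 201, 301), region_start = 200L)
  aln3 <- dplyr::bind_rows(abut, span)
  comp3 <- build_composite(aln3, ref, logical(500))
  expect_true(tiling_path_check(comp3, 200L, 300L, w, aln = aln3, strict = TRUE))
})

test_that("transcript aggregation sums counts and dedupes shared windows", {
  w1 <- tibble::tibble(start = c(0L, 300L), end = c(100L, 700L),
                       side = c("5prime", "3prime"), x = c(3L, 5L),
                       n = c(100L, 400L))
  w2 <- tibble::tibble(start = c(300L, 900L), end = c(700L, 1300L),
                       side = c("5prime", "3prime"), x = c(5L, 4L),
                       n = c(400L, 400L))
  mk <- function(id, x_e, n_e, w) {
    tibble::tibble(exon_id = id, transcript_id = "tx1", exon_start = 0L,
                   exon_end = 1L, x_e = x_e, n_e = n_e,
                   x_i = sum(w$x), n_i = sum(w$n),
                   D_e = x_e / n_e, D_i = sum(w$x) / sum(w$n),
                   cov_hs_exon = 5, cov_mmu_exon = 5, cov_hs_intron = 5,
                   cov_mmu_intron = 5, testable = TRUE, windows = list(w))
  }
  # disjoint windows: plain additivity
  p1 <- mk("e1", 5L, 100L, w1[2, ])
  p2 <- mk("e2", 3L, 60L, tibble::tibble(start = 900L, end = 1300L,
                                         side = "3prime", x = 4L, n = 400L))
  agg <- aggregate_transcript(dplyr::bind_rows(p1, p2))
  expect_equal(agg$x_e, 8L)
  expect_equal(agg$n_e, 160L)
  expect_equal(agg$x_i, 9L)
  expect_equal(agg$n_i, 800L)
  # a single exon aggregates to itself
  agg1 <- aggregate_transcript(p1)
  expect_equal(agg1$x_i, p1$x_i)
  expect_equal(agg1$n_e, p1$n_e)
  # the [300, 700) window shared by both exons is counted once
  p1s <- mk("e1", 5L, 100L, w1)
  p2s <- mk("e2", 3L, 60L, w2)
  aggs <- aggregate_transcript(dplyr::bind_rows(p1s, p2s))
  expect_equal(aggs$x_i, 3L + 5L + 4L)
  expect_equal(aggs$n_i, 100L + 400L + 400L)
  expect_error(aggregate_transcript(p1[0, ]), "no pairs")
})
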