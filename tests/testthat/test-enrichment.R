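test_that("duplication status is overlap-based, half-open, order-invariant", {
  sd <- tibble::tibble(chrom = "chr1", start = c(150L, 1000L),
                       end = c(500L, 2000L))
  exons <- tibble::tibble(chrom = "chr1",
                          gstart = c(100L, 100L, 600L),
                          gend = c(200L, 150L, 700L))
  ann <- annotate_duplication(exons, sd)
  expect_equal(ann$duplication, c("duplicated", "single_copy", "single_copy"))
  # SD row order does not matter; annotation is idempotent
  ann2 <- annotate_duplication(exons, sd[2:1, ])
  expect_equal(ann$duplication, ann2$duplication)
  expect_equal(annotate_duplication(ann, sd)$duplication, ann$duplication)
  # empty SD set: everything single-copy
  empty <- sd[0, ]
  expect_true(all(annotate_duplication(exons, empty)$duplication ==
                    "single_copy"))
})

test_that("fisher_enrichment matches a log-factorial oracle and fisher.test", {
  set.seed(5)
  for (i in 1:25) {
    tot <- sample(20:200, 1)
    a <- sample(0:10, 1); b <- sample(0:10, 1)
    c <- sample(0:(tot %/% 2), 1); d <- max(0, tot - a - b - c)
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    got <- fisher_enrichment(a, b, c, d)
    oracle <- oracle_fisher(a, b, c, d)
    expect_equal(got$p_one_sided, oracle$one_sided, tolerance = 1e-10)
    expect_equal(got$p_two_sided, oracle$two_sided, tolerance = 1e-10)
    ft <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
    expect_equal(got$p_two_sided, ft$p.value, tolerance = 1e-7)
  }
  # no association: two-sided p = 1
  expect_equal(fisher_enrichment(5, 5, 5, 5)$p_two_sided, 1)
  expect_warning(p <- fisher_enrichment(0, 0, 5, 5), "degenerate")
  expect_equal(p$p_two_sided, 1)
})

test_that("delta comparison separates planted selective classes", {
  same <- tibble::tibble(delta = rep(c(0.1, 0.2, 0.3), 2),
                         class_label = rep(c("a", "b"), each = 3))
  r <- delta_compare(same, "a", "b")
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  set.seed(1)
  rec <- tibble::tibble(
    delta = c(rnorm(5, 0.1, 0.005), rnorm(5, -0.1, 0.005)),
    class_label = rep(c("pos", "neg"), each = 5))
  r2 <- delta_compare(rec, "pos", "neg")
  expect_gt(r2$t, 0)
  expect_lt(r2$p_value, 0.01)
  expect_error(delta_compare(rec[c(1, 6, 7, 8), ], "pos", "neg"),
               "at least 2")
  # planted classes at the proof-of-concept mean separations
  set.seed(2)
  poc <- tibble::tibble(
    delta = c(rnorm(60, 0.015, 0.02), rnorm(60, -0.031, 0.02),
              rnorm(60, -0.022, 0.02)),
    class_label = rep(c("positive", "purifying", "neutral"), each = 60))
  expect_lt(delta_compare(poc, "positive", "purifying")$p_value, 0.01)
  expect_lt(delta_compare(poc, "positive", "neutral")$p_value, 0.01)
})

test_that("NG86 handles the textbook cases and is symmetric", {
  same <- ng86_dnds("TTTAAG", "TTTAAG")
  expect_equal(same$Nd + same$Sd, 0)
  expect_true(is.na(same$ratio))
  # Phe -> Phe third-position change: one synonymous difference
  r <- ng86_dnds("TTT", "TTC")
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$dN, 0)
  # a single codon saturates the synonymous proportion (pS = 3 > 3/4), so the
  # Jukes-Cantor correction is undefined
  expect_true(is.na(r$dS))
  # symmetry in the two sequences
  set.seed(17)
  a <- random_seq(60)
  b <- random_seq(60)
  ra <- ng86_dnds(a, b)
  rb <- ng86_dnds(b, a)
  expect_equal(ra$N, rb$N, tolerance = 1e-12)
  expect_equal(ra$Sd, rb$Sd, tolerance = 1e-12)
  expect_equal(ra$ratio, rb$ratio, tolerance = 1e-12)
  expect_error(ng86_dnds("TTTA", "TTT"), "equal length")
  expect_error(ng86_dnds("TTTA", "TTCA"), "multiple of 3")
})

test_that("NG86 agrees with the pathway-enumeration oracle on random pairs", {
  set.seed(7)
  for (i in 1:20) {
    n <- 3 * sample(5:30, 1)
    a <- random_seq(n)
    b <- strsplit(a, "")[[1]]
    mut <- runif(n) < 0.1
    b[mut] <- vapply(b[mut],
                     function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                     "")
    b <- paste(b, collapse = "")
    got <- ng86_dnds(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$N, want$N, tolerance = 1e-10)
    expect_equal(got$S, want$S, tolerance = 1e-10)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-10)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-10)
  }
})

test_that("dN/dS permutation test is reproducible and calibrated under exchangeability", {
  set.seed(31)
  # pool of exons whose composite differs from the reference at random sites
  make_pool <- function(n) {
    purrr::map_dfr(seq_len(n), function(i) {
      len <- 3 * sample(10:20, 1)
      ref <- random_seq(len)
      alt <- strsplit(ref, "")[[1]]
      mut <- which(runif(len) < 0.04)
      alt[mut] <- vapply(alt[mut],
                         function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                         "")
      tibble::tibble(exon_id = paste0("e", i), ref = ref,
                     alt = paste(alt, collapse = ""))
    })
  }
  pool <- make_pool(60)
  pool <- pool[!accelexon:::has_internal_stop(pool$ref), ]
  targets <- pool$exon_id[1:8]
  r1 <- permutation_dnds(targets, pool, n_perm = 200, seed = 99)
  r2 <- permutation_dnds(targets, pool, n_perm = 200, seed = 99)
  expect_identical(r1$permuted, r2$permuted)
  expect_identical(r1$p_value, r2$p_value)
  # a target set drawn like the pool should not look extreme
  expect_gt(r1$p_value, 0.02)
  expect_error(permutation_dnds(targets, pool, n_perm = 0), "at least 1")
  expect_error(permutation_dnds("absent", pool), "no eligible target")
})

test_that("a nonsynonymous-only target set is detected by the permutation test", {
  set.seed(41)
  # neutral pool: random substitutions; target exons: engineered so every
  # difference is nonsynonymous (first-codon-position transversions)
  pool <- purrr::map_dfr(1:50, function(i) {
    len <- 60L
    ref <- paste(rep("CTG", 20), collapse = "")  # Leu codons
    alt <- strsplit(ref, "")[[1]]
    if (i <= 10) {
      # targets: C -> A at codon starts (Leu -> Met/Ile family: nonsynonymous)
      idx <- seq(1, len, by = 3)[1:6]
      alt[idx] <- "A"
    } else {
      # pool: G -> A at third positions (Leu -> Leu: synonymous)
      idx <- seq(3, len, by = 3)[sample(20, 6)]
      alt[idx] <- "A"
    }
    tibble::tibble(exon_id = paste0("x", i), ref = ref,
                   alt = paste(alt, collapse = ""))
  })
  r <- permutation_dnds(paste0("x", 1:10), pool, n_perm = 200, seed = 5)
  expect_lt(r$p_value, 0.01)
})
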