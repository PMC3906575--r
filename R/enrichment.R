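# Post-hoc statistics: segmental-duplication annotation and enrichment,
# group comparison of the per-exon acceleration measure delta = D_e - D_i,
# and a Nei-Gojobori (1986) dN/dS estimator with a permutation test over the
# composite coding sequences.

#' Annotate exons by segmental-duplication status
#'
#' An exon is `duplicated` when it overlaps any SD interval by at least 1 bp
#' (totally or partially included), otherwise `single_copy`.
#'
#' @param exons tibble with `chrom` and either `gstart`/`gend` or
#'   `start`/`end` columns (0-based half-open).
#' @param sd tibble of SD intervals (`chrom`, `start`, `end`) as read from a
#'   BED3+ file.
#' @return `exons` with a `duplication` column.
#' @export
annotate_duplication <- function(exons, sd) {
  s <- if ("gstart" %in% names(exons)) exons$gstart else exons$start
  e <- if ("gend" %in% names(exons)) exons$gend else exons$end
  dup <- rep(FALSE, nrow(exons))
  for (ch in unique(exons$chrom)) {
    rows <- exons$chrom == ch
    ivs <- sd[sd$chrom == ch, , drop = FALSE]
    dup[rows] <- iv_any_overlap(ivs, s[rows], e[rows])
  }
  dplyr::mutate(exons, duplication = ifelse(dup, "duplicated", "single_copy"))
}

#' Fisher's exact test on a 2x2 significant-by-duplicated table
#'
#' Exact hypergeometric computation in log space, suitable for tables with
#' totals up to ~10^6. Rows are significant / not significant, columns
#' duplicated / single-copy.
#'
#' @param a,b,c,d cell counts: `a` significant duplicated, `b` significant
#'   single-copy, `c` non-significant duplicated, `d` non-significant
#'   single-copy.
#' @return One-row tibble with `p_one_sided` (enrichment of duplicated among
#'   significant) and `p_two_sided`.
#' @export
fisher_enrichment <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    warning("degenerate margin; p = 1", call. = FALSE)
    return(tibble::tibble(p_one_sided = 1, p_two_sided = 1))
  }
  m <- a + c   # duplicated total
  n <- b + d   # single-copy total
  k <- a + b   # significant total
  p_one <- stats::phyper(a - 1, m, n, k, lower.tail = FALSE)
  supp <- max(0, k - n):min(k, m)
  logd <- stats::dhyper(supp, m, n, k, log = TRUE)
  obs <- stats::dhyper(a, m, n, k, log = TRUE)
  keep <- logd <= obs + 1e-7
  mx <- max(logd[keep])
  p_two <- min(1, exp(mx + log(sum(exp(logd[keep] - mx)))))
  tibble::tibble(p_one_sided = p_one, p_two_sided = p_two)
}

#' Compare the acceleration measure between two exon classes
#'
#' Two-sample t-test (Welch by default) on delta = D_e - D_i between two
#' labelled classes of exons.
#'
#' @param records tibble with `delta` and `class_label` columns.
#' @param class_a,class_b labels to compare.
#' @param pooled use the pooled-variance t-test instead of Welch.
#' @return One-row tibble with means, `t`, `df` and `p_value`.
#' @export
delta_compare <- function(records, class_a, class_b, pooled = FALSE) {
  da <- records$delta[records$class_label == class_a]
  db <- records$delta[records$class_label == class_b]
  if (length(da) < 2 || length(db) < 2) {
    stop("each class needs at least 2 records", call. = FALSE)
  }
  tt <- stats::t.test(da, db, var.equal = pooled)
  tibble::tibble(
    class_a = class_a, class_b = class_b,
    mean_a = mean(da), mean_b = mean(db),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value
  )
}

codon_split <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length not a multiple of 3", call. = FALSE)
  substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
}

# Expected synonymous sites of one codon: per position, the fraction of the
# three possible changes that preserve the amino acid (changes to stop codons
# count as nonsynonymous).
ng86_syn_sites <- function(codon) {
  aa <- translate_codon(codon)
  ch <- strsplit(codon, "", fixed = TRUE)[[1]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), ch[pos])) {
      mut <- ch
      mut[pos] <- b
      mcodon <- paste(mut, collapse = "")
      if (!(mcodon %in% STOP_CODONS) && identical(translate_codon(mcodon), aa)) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

# Pathway-averaged observed synonymous/nonsynonymous differences between two
# codons. All orders of introducing the differing positions are enumerated;
# pathways passing through a stop-codon intermediate are excluded (all
# pathways are used if every one is blocked).
ng86_codon_diffs <- function(ca, cb) {
  a <- strsplit(ca, "", fixed = TRUE)[[1]]
  b <- strsplit(cb, "", fixed = TRUE)[[1]]
  dpos <- which(a != b)
  k <- length(dpos)
  if (k == 0) return(c(sd = 0, nd = 0))
  orders <- perms(dpos)
  path_sd <- numeric(0); path_nd <- numeric(0)
  blocked_sd <- numeric(0); blocked_nd <- numeric(0)
  for (r in seq_len(nrow(orders))) {
    cur <- a
    sd <- 0; nd <- 0; blocked <- FALSE
    for (step in seq_len(k)) {
      pos <- orders[r, step]
      nxt <- cur
      nxt[pos] <- b[pos]
      nxt_codon <- paste(nxt, collapse = "")
      if (step < k && nxt_codon %in% STOP_CODONS) blocked <- TRUE
      if (identical(translate_codon(paste(cur, collapse = "")),
                    translate_codon(nxt_codon)) &&
          !(nxt_codon %in% STOP_CODONS)) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    if (blocked) {
      blocked_sd <- c(blocked_sd, sd); blocked_nd <- c(blocked_nd, nd)
    } else {
      path_sd <- c(path_sd, sd); path_nd <- c(path_nd, nd)
    }
  }
  if (length(path_sd) == 0) {
    path_sd <- blocked_sd; path_nd <- blocked_nd
  }
  c(sd = mean(path_sd), nd = mean(path_nd))
}

perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

#' Nei-Gojobori (1986) pairwise dN/dS
#'
#' Counts expected synonymous (S) and nonsynonymous (N) sites averaged over
#' the two sequences, pathway-averages the observed differences per codon,
#' applies the Jukes-Cantor multiple-hit correction, and returns the dN/dS
#' ratio (NA when dS = 0). Codon pairs in which either codon is a stop are
#' excluded from all counts.
#'
#' @param seq_a,seq_b coding sequences of equal length (multiple of 3).
#' @return One-row tibble: `N`, `S`, `Nd`, `Sd`, `pN`, `pS`, `dN`, `dS`,
#'   `ratio`.
#' @export
ng86_dnds <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  ca <- codon_split(seq_a)
  cb <- codon_split(seq_b)
  keep <- !(ca %in% STOP_CODONS) & !(cb %in% STOP_CODONS) &
    !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[keep]; cb <- cb[keep]
  S <- 0; Nd <- 0; Sd <- 0
  for (i in seq_along(ca)) {
    S <- S + (ng86_syn_sites(ca[i]) + ng86_syn_sites(cb[i])) / 2
    d <- ng86_codon_diffs(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  total <- 3 * length(ca)
  N <- total - S
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  dS <- jc(pS); dN <- jc(pN)
  ratio <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
  tibble::tibble(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
                 dN = dN, dS = dS, ratio = ratio)
}

#' Permutation test of the target set's dN/dS
#'
#' Compares the concatenated composite-vs-reference dN/dS of a target exon
#' set against sets of the same size drawn uniformly without replacement from
#' the eligible pool (coding sequence of at least `min_len` bp and no
#' annotation-induced stop codon in the reference frame). The empirical
#' p-value is the fraction of permutations whose dN/dS is at least the
#' target's (dN > 0 with dS = 0 counts as infinite).
#'
#' @param target_ids exon ids of the target set.
#' @param exon_seqs tibble with `exon_id`, `ref`, `alt` in-frame coding
#'   sequences (see [exon_coding_sequences()]).
#' @param n_perm number of permutations (default 1000).
#' @param min_len minimum coding length in bp (default 20).
#' @param seed RNG seed for reproducibility.
#' @return List of class `accel_perm`: observed ratio, permutation ratios,
#'   empirical `p_value`, set size and pool size.
#' @export
permutation_dnds <- function(target_ids, exon_seqs, n_perm = 1000,
                             min_len = 20, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  eligible <- exon_seqs[nchar(exon_seqs$ref) >= min_len &
                          !has_internal_stop(exon_seqs$ref), , drop = FALSE]
  targets <- eligible[eligible$exon_id %in% target_ids, , drop = FALSE]
  if (nrow(targets) < 1) stop("no eligible target exon", call. = FALSE)
  if (nrow(eligible) < nrow(targets)) {
    stop("fewer eligible exons than the target set size", call. = FALSE)
  }
  score <- function(rows) {
    r <- ng86_dnds(paste(rows$ref, collapse = ""), paste(rows$alt, collapse = ""))
    if (is.na(r$ratio)) {
      if (!is.na(r$dS) && r$dS == 0 && !is.na(r$dN) && r$dN > 0) Inf else NA_real_
    } else {
      r$ratio
    }
  }
  observed <- score(targets)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  perm <- vapply(seq_len(n_perm), function(i) {
    score(eligible[sample.int(nrow(eligible), nrow(targets)), , drop = FALSE])
  }, numeric(1))
  p <- mean(!is.na(perm) & perm >= observed)
  structure(
    list(observed = observed, permuted = perm, p_value = p,
         set_size = nrow(targets), pool_size = nrow(eligible),
         n_perm = n_perm),
    class = "accel_perm"
  )
}

has_internal_stop <- function(seqs) {
  vapply(seqs, function(s) {
    if (nchar(s) < 3) return(FALSE)
    any(codon_split(s) %in% STOP_CODONS)
  }, logical(1), USE.NAMES = FALSE)
}

#' @export
print.accel_perm <- function(x, ...) {
  cat(sprintf(
    "<accel_perm> observed dN/dS = %.4g over %d exon(s); empirical p = %.4g (%d permutations, pool %d)\n",
    x$observed, x$set_size, x$p_value, x$n_perm, x$pool_size))
  invisible(x)
}
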