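# False-positive filter cascade applied to significant exons, plus
# transcript-level aggregation. Each rule is an independent predicate; the
# cascade records every failing rule, so the verdict does not depend on
# evaluation order.

#' Macaque coverage comparability rule
#'
#' Rejects a pair whose exon is covered by macaque reads (mean > 2) while its
#' intronic reference is not (mean < 2): such exons look accelerated simply
#' because the intron lacks macaque information.
#'
#' @param pair one-row pair tibble with `cov_mmu_exon`, `cov_mmu_intron`.
#' @return TRUE to keep, FALSE to reject.
#' @export
coverage_filter <- function(pair) {
  !(pair$cov_mmu_exon > 2 & pair$cov_mmu_intron < 2)
}

#' Intronic-rate floor rule
#'
#' Rejects pairs whose intronic reference shows almost no differences
#' (`D_i < floor`): such introns are either under selection themselves or
#' poorly represented in the read data.
#'
#' @param pair one-row pair tibble with `D_i`.
#' @param floor minimum intronic rate (default 0.01, strict `<` rejects).
#' @return TRUE to keep, FALSE to reject.
#' @export
di_floor_filter <- function(pair, floor = 0.01) {
  !(pair$D_i < floor)
}

#' Detect reads from processed pseudogenes
#'
#' A read betrays a reverse-transcribed (intronless) template when its
#' alignment runs contiguously out of the last `window` bp of one coding exon
#' into the first `window` bp of the next while the intervening intron is
#' skipped (a reference-skip CIGAR junction whose endpoints sit within
#' `window` bp of the flanking exon boundaries).
#'
#' @param aln alignment tibble mapped to the transcript's region.
#' @param t one-row region-local transcript tibble.
#' @param window junction window in bp (default 10).
#' @return Character vector of flagged `read_id`s (empty for single-exon
#'   transcripts).
#' @export
detect_pseudogene_reads <- function(aln, t, window = 10L) {
  ce <- t$coding_exons[[1]]
  if (nrow(ce) < 2 || nrow(aln) == 0) return(character(0))
  flagged <- character(0)
  for (i in seq_len(nrow(aln))) {
    pr <- alignment_pairs(aln$region_start[i], aln$cigar[i])
    jn <- pr$junctions
    if (length(jn$left) == 0) next
    for (k in seq_len(nrow(ce) - 1L)) {
      hit <- jn$left >= ce$end[k] - window & jn$left <= ce$end[k] &
        jn$right >= ce$start[k + 1L] & jn$right <= ce$start[k + 1L] + window
      if (any(hit)) {
        flagged <- c(flagged, aln$read_id[i])
        break
      }
    }
  }
  unique(flagged)
}

#' Recompute a pair after removing suspected pseudogene reads
#'
#' Rebuilds the composite without the flagged reads, recounts the pair over
#' the same exon and windows, and rejects the exon when the recomputed exonic
#' rate falls below the recomputed intronic rate.
#'
#' @param pair one-row pair tibble (must carry `exon_start`, `exon_end`,
#'   `windows`).
#' @param aln accepted alignments of the region.
#' @param flagged read ids to remove.
#' @param comp original `composite` (supplies sequence, masks and build
#'   parameters).
#' @return List with `keep` (logical), `pair` (recomputed one-row tibble) and
#'   `untestable`.
#' @export
pseudogene_recompute <- function(pair, aln, flagged, comp) {
  clean <- rebuild_composite(comp, aln[!aln$read_id %in% flagged, , drop = FALSE])
  newpair <- count_differences(clean, pair$exon_start, pair$exon_end,
                               pair$windows[[1]][, c("start", "end", "side")],
                               exon_id = pair$exon_id,
                               transcript_id = pair$transcript_id)
  untestable <- !newpair$testable
  keep <- !untestable && !(newpair$D_e < newpair$D_i)
  list(keep = keep, pair = newpair, untestable = untestable)
}

rebuild_composite <- function(comp, aln) {
  build_composite(aln, comp$ref, comp$masked,
                  q_min = comp$params$q_min,
                  min_support = comp$params$min_support,
                  pool_species = comp$params$pool_species,
                  same_allele = comp$params$same_allele,
                  region_id = comp$region_id)
}

# Read ids carrying at least one high-quality unmasked mismatch in a coding
# exon of t that creates a stop codon.
stop_carrying_reads <- function(aln, comp, t, q_min = comp$params$q_min) {
  ce <- t$coding_exons[[1]]
  ref <- toupper(strsplit(comp$ref, "", fixed = TRUE)[[1]])
  bases <- c("A", "C", "G", "T")
  coding <- iv_mask_vector(ce, chrom = NA, region_start = 0L,
                           region_end = comp$length)
  classify <- substitution_classifier(comp$ref, t)
  out <- character(0)
  for (i in seq_len(nrow(aln))) {
    pr <- alignment_pairs(aln$region_start[i], aln$cigar[i])
    if (length(pr$ref) == 0) next
    inside <- pr$ref >= 0L & pr$ref < comp$length
    refp <- pr$ref[inside]; readp <- pr$read[inside]
    rb <- toupper(substring(aln$read_seq[i], readp + 1L, readp + 1L))
    quals <- utf8ToInt(aln$qual[i]) - 33L
    cand <- which(coding[refp + 1L] & quals[readp + 1L] >= q_min &
                    !comp$masked[refp + 1L] & rb != ref[refp + 1L] &
                    rb %in% bases & ref[refp + 1L] %in% bases)
    for (k in cand) {
      if (identical(classify(refp[k], rb[k]), "stop")) {
        out <- c(out, aln$read_id[i])
        break
      }
    }
  }
  unique(out)
}

#' Stop-codon sensitivity of a significant exon
#'
#' Removes every read carrying a high-quality difference that creates a stop
#' codon, rebuilds the composite, recomputes the pair and re-runs the LRT.
#' The exon is `robust` when it stays significant at `p_cut` and `fragile`
#' otherwise; the counts of removed reads and of exonic differences lost are
#' reported either way. This is a report, not a rejection rule.
#'
#' @param pair one-row pair tibble.
#' @param comp the region `composite`.
#' @param aln accepted alignments of the region.
#' @param t one-row region-local transcript tibble.
#' @param p_cut p-value level at which significance must be retained.
#' @return One-row tibble: `status`, `n_stop_reads`, `n_stop_diffs`,
#'   `p_recomputed`.
#' @export
stop_codon_sensitivity <- function(pair, comp, aln, t, p_cut = 0.05) {
  flagged <- stop_carrying_reads(aln, comp, t)
  if (length(flagged) == 0) {
    return(tibble::tibble(status = "robust", n_stop_reads = 0L,
                          n_stop_diffs = 0L, p_recomputed = NA_real_))
  }
  clean <- rebuild_composite(comp, aln[!aln$read_id %in% flagged, , drop = FALSE])
  newpair <- count_differences(clean, pair$exon_start, pair$exon_end,
                               pair$windows[[1]][, c("start", "end", "side")],
                               exon_id = pair$exon_id,
                               transcript_id = pair$transcript_id)
  res <- lrt_exon(newpair)
  ok <- res$testable && !is.na(res$p_value) && res$p_value <= p_cut &&
    res$D_e > res$D_i
  tibble::tibble(
    status = ifelse(ok, "robust", "fragile"),
    n_stop_reads = length(flagged),
    n_stop_diffs = as.integer(pair$x_e - newpair$x_e),
    p_recomputed = res$p_value
  )
}

#' Tiling-path coverage check
#'
#' Requires every unmasked position of the exon and of each intron window to
#' be covered by at least one accepted read. With `strict = TRUE` (and
#' alignments supplied) consecutive unmasked positions must additionally be
#' spanned together by at least one read, i.e. adjacent reads must overlap.
#'
#' @param comp the region `composite`.
#' @param exon_start,exon_end region-local exon interval.
#' @param windows intron window tibble.
#' @param aln alignments (only needed for `strict = TRUE`).
#' @param strict require overlapping reads across every junction.
#' @return TRUE (pass) or FALSE (fail).
#' @export
tiling_path_check <- function(comp, exon_start, exon_end, windows,
                              aln = NULL, strict = FALSE) {
  idx <- (exon_start + 1L):exon_end
  if (nrow(windows) > 0) {
    idx <- c(idx, unlist(purrr::map2(windows$start, windows$end, ~ (.x + 1L):.y)))
  }
  idx <- idx[!comp$masked[idx]]
  if (length(idx) == 0) return(TRUE)
  total_cov <- comp$coverage["human", ] + comp$coverage["macaque", ]
  if (any(total_cov[idx] < 1)) return(FALSE)
  if (!strict) return(TRUE)
  stopifnot(!is.null(aln))
  # junction j = between positions j and j+1 (1-based index into the region)
  jcov <- integer(comp$length)
  for (i in seq_len(nrow(aln))) {
    pr <- alignment_pairs(aln$region_start[i], aln$cigar[i])
    refp <- sort(pr$ref[pr$ref >= 0 & pr$ref < comp$length])
    spans <- refp[which(diff(refp) == 1L)]
    jcov[spans + 1L] <- jcov[spans + 1L] + 1L
  }
  idx <- sort(idx)
  adjacent <- idx[which(diff(idx) == 1L)]
  all(jcov[adjacent] >= 1)
}

#' Tandem protein-domain family rule
#'
#' Genes from families with tandem protein domains accumulate spurious
#' differences through misalignment; they are rejected via a caller-supplied
#' gene list.
#'
#' @param gene_id gene identifier(s).
#' @param tandem_genes character vector of tandem-domain gene ids/families.
#' @return Logical: TRUE to keep, FALSE to reject.
#' @export
tandem_domain_filter <- function(gene_id, tandem_genes = character()) {
  !(gene_id %in% tandem_genes)
}

#' Aggregate exon/intron pairs to the transcript level
#'
#' Sums the exonic counts over all testable exons of a transcript and the
#' intronic counts over the distinct intron windows (a window shared by two
#' adjacent exons is counted once). The summed pair feeds [lrt_exon()]
#' unchanged.
#'
#' @param pairs pair tibble, all rows from one transcript.
#' @return One-row pair tibble at the transcript level.
#' @export
aggregate_transcript <- function(pairs) {
  if (nrow(pairs) == 0) stop("no pairs to aggregate", call. = FALSE)
  if (length(unique(pairs$transcript_id)) != 1) {
    stop("pairs from more than one transcript", call. = FALSE)
  }
  wins <- dplyr::bind_rows(pairs$windows)
  wins <- dplyr::distinct(wins, .data$start, .data$end, .keep_all = TRUE)
  n_e <- sum(pairs$n_e)
  n_i <- sum(wins$n)
  tibble::tibble(
    exon_id = paste0(pairs$transcript_id[1], ":tx"),
    transcript_id = pairs$transcript_id[1],
    exon_start = min(pairs$exon_start), exon_end = max(pairs$exon_end),
    x_e = sum(pairs$x_e), n_e = n_e,
    x_i = sum(wins$x), n_i = n_i,
    D_e = ifelse(n_e > 0, sum(pairs$x_e) / n_e, NA_real_),
    D_i = ifelse(n_i > 0, sum(wins$x) / n_i, NA_real_),
    cov_hs_exon = stats::weighted.mean(pairs$cov_hs_exon, pmax(pairs$n_e, 1)),
    cov_mmu_exon = stats::weighted.mean(pairs$cov_mmu_exon, pmax(pairs$n_e, 1)),
    cov_hs_intron = stats::weighted.mean(pairs$cov_hs_intron, pmax(pairs$n_i, 1)),
    cov_mmu_intron = stats::weighted.mean(pairs$cov_mmu_intron, pmax(pairs$n_i, 1)),
    testable = n_e > 0 && n_i > 0,
    windows = list(wins)
  )
}

#' Run the full filter cascade over the significant exons
#'
#' Applies the coverage comparability rule, the intronic-rate floor, the
#' processed-pseudogene removal-and-recompute rule, the tandem-domain list
#' and the tiling-path check to every significant exon, recording all failing
#' rules. Stop-codon sensitivity is reported alongside (it does not reject
#' unless `strict_stop = TRUE`).
#'
#' @param sig significant results tibble (rows of the LRT results).
#' @param regions named list of per-region data, each with elements
#'   `t_local`, `comp`, `aln` (accepted alignments); names are transcript
#'   ids.
#' @param tandem_genes tandem-domain gene list.
#' @param di_floor intronic rate floor.
#' @param pg_window pseudogene junction window (bp).
#' @param p_cut significance level for the stop-codon sensitivity report.
#' @param strict_stop also reject exons fragile to stop-read removal.
#' @param strict_tiling strict (overlapping-reads) tiling mode.
#' @return Verdict tibble: `exon_id`, `passed`, `failed_rules` (list-column),
#'   stop-codon report columns and recomputed rates.
#' @export
filter_cascade <- function(sig, regions, tandem_genes = character(),
                           di_floor = 0.01, pg_window = 10L, p_cut = 0.05,
                           strict_stop = FALSE, strict_tiling = FALSE) {
  rows <- purrr::map(seq_len(nrow(sig)), function(i) {
    pair <- sig[i, ]
    reg <- regions[[pair$transcript_id]]
    failed <- character(0)
    if (!coverage_filter(pair)) failed <- c(failed, "coverage_rule")
    if (!di_floor_filter(pair, floor = di_floor)) failed <- c(failed, "di_floor")
    flagged <- detect_pseudogene_reads(reg$aln, reg$t_local, window = pg_window)
    rec <- pseudogene_recompute(pair, reg$aln, flagged, reg$comp)
    if (!rec$keep) failed <- c(failed, "pseudogene")
    if (!tandem_domain_filter(pair$gene_id %||% pair$transcript_id, tandem_genes)) {
      failed <- c(failed, "tandem_domain")
    }
    if (!tiling_path_check(reg$comp, pair$exon_start, pair$exon_end,
                           pair$windows[[1]], aln = reg$aln,
                           strict = strict_tiling)) {
      failed <- c(failed, "tiling_path")
    }
    stop_rep <- stop_codon_sensitivity(pair, reg$comp, reg$aln, reg$t_local,
                                       p_cut = p_cut)
    if (strict_stop && stop_rep$status == "fragile") {
      failed <- c(failed, "stop_codon_sensitivity")
    }
    tibble::tibble(
      exon_id = pair$exon_id,
      transcript_id = pair$transcript_id,
      passed = length(failed) == 0,
      failed_rules = list(failed),
      n_pseudogene_reads = length(flagged),
      D_e_recomputed = rec$pair$D_e,
      D_i_recomputed = rec$pair$D_i,
      stop_status = stop_rep$status,
      n_stop_reads = stop_rep$n_stop_reads,
      n_stop_diffs = stop_rep$n_stop_diffs
    )
  })
  if (length(rows) == 0) {
    return(tibble::tibble(
      exon_id = character(), transcript_id = character(), passed = logical(),
      failed_rules = list(), n_pseudogene_reads = integer(),
      D_e_recomputed = numeric(), D_i_recomputed = numeric(),
      stop_status = character(), n_stop_reads = integer(),
      n_stop_diffs = integer()
    ))
  }
  dplyr::bind_rows(rows)
}
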