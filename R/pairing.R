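# Exon/intron pairing: select the neutral intronic reference windows for each
# coding exon and count composite differences to form the LRT inputs
# (x_e, n_e, x_i, n_i). All coordinates here are region-local 0-based
# half-open; transcripts must first pass through to_region_local().

#' Select the intronic reference windows for a coding exon
#'
#' Walks outward from each side of the exon and accumulates qualifying
#' intronic positions until `window` bp are collected per side (fewer if the
#' region is exhausted). A position qualifies when it is not masked by any
#' track, does not overlap any exon of any supplied transcript, and is not
#' within `buffer` bp of any such exon. Windows may fragment around excluded
#' segments.
#'
#' @param t one-row region-local transcript tibble.
#' @param exon_index index into the transcript's coding exons.
#' @param masks_local list of logical mask vectors from [region_masks()].
#' @param all_exons optional tibble(start, end) of every exon interval
#'   (region-local) the buffer should respect; defaults to the transcript's
#'   own exons.
#' @param buffer bp adjacent to any exon excluded as splice-constrained
#'   (default 50).
#' @param window target qualifying bp per side (default 400).
#' @return Tibble of windows (`start`, `end`, `side`); zero rows when no
#'   qualifying position exists on either side (no-reference).
#' @export
select_intron_reference <- function(t, exon_index, masks_local,
                                    all_exons = NULL, buffer = 50L,
                                    window = 400L) {
  stopifnot(nrow(t) == 1)
  ce <- t$coding_exons[[1]]
  if (exon_index < 1 || exon_index > nrow(ce)) {
    stop("exon not in transcript", call. = FALSE)
  }
  exon <- ce[exon_index, ]
  L <- length(masks_local$all)
  exons <- all_exons %||% t$exons[[1]]
  excluded <- masks_local$all |
    iv_mask_vector(
      tibble::tibble(start = pmax(0L, exons$start - as.integer(buffer)),
                     end = exons$end + as.integer(buffer)),
      chrom = NA, region_start = 0L, region_end = L
    )
  take_side <- function(pos_seq) {
    if (length(pos_seq) == 0) return(integer(0))
    ok <- pos_seq[!excluded[pos_seq + 1L]]
    utils::head(ok, window)
  }
  left <- take_side(if (exon$start > 0) (exon$start - 1L):0L else integer(0))
  right <- take_side(if (exon$end < L) exon$end:(L - 1L) else integer(0))
  out <- dplyr::bind_rows(
    dplyr::mutate(positions_to_intervals(left), side = "5prime"),
    dplyr::mutate(positions_to_intervals(right), side = "3prime")
  )
  if (nrow(out) == 0) {
    return(tibble::tibble(start = integer(), end = integer(), side = character()))
  }
  dplyr::arrange(out, .data$start)
}

#' Count composite differences in an exon and its intron reference
#'
#' @param comp a `composite`.
#' @param exon_start,exon_end region-local exon interval.
#' @param windows intron window tibble from [select_intron_reference()].
#' @param exon_id,transcript_id identifiers carried into the output.
#' @return One-row pair tibble with counts, rates, per-species coverage
#'   summaries, a `testable` flag and the per-window counts as a list-column.
#' @export
count_differences <- function(comp, exon_start, exon_end, windows,
                              exon_id = "", transcript_id = "") {
  unm <- !comp$masked
  d <- comp$diff
  eidx <- (exon_start + 1L):exon_end
  x_e <- sum(d[eidx] & unm[eidx])
  n_e <- sum(unm[eidx])
  if (nrow(windows) > 0) {
    wx <- integer(nrow(windows)); wn <- integer(nrow(windows))
    for (k in seq_len(nrow(windows))) {
      widx <- (windows$start[k] + 1L):windows$end[k]
      wx[k] <- sum(d[widx] & unm[widx])
      wn[k] <- sum(unm[widx])
    }
    windows <- dplyr::mutate(windows, x = wx, n = wn)
    x_i <- sum(wx); n_i <- sum(wn)
  } else {
    windows <- tibble::tibble(start = integer(), end = integer(),
                              side = character(), x = integer(), n = integer())
    x_i <- 0L; n_i <- 0L
  }
  cov_e <- coverage_profile(comp, exon_start, exon_end)
  cov_i <- intron_coverage(comp, windows)
  tibble::tibble(
    exon_id = exon_id, transcript_id = transcript_id,
    exon_start = as.integer(exon_start), exon_end = as.integer(exon_end),
    x_e = x_e, n_e = n_e, x_i = x_i, n_i = n_i,
    D_e = ifelse(n_e > 0, x_e / n_e, NA_real_),
    D_i = ifelse(n_i > 0, x_i / n_i, NA_real_),
    cov_hs_exon = cov_e$cov_human, cov_mmu_exon = cov_e$cov_macaque,
    cov_hs_intron = cov_i$cov_human, cov_mmu_intron = cov_i$cov_macaque,
    testable = n_e > 0 && n_i > 0,
    windows = list(windows)
  )
}

intron_coverage <- function(comp, windows) {
  if (nrow(windows) == 0) {
    return(tibble::tibble(cov_human = 0, cov_macaque = 0))
  }
  idx <- unlist(purrr::map2(windows$start, windows$end, ~ (.x + 1L):.y))
  keep <- idx[!comp$masked[idx]]
  if (length(keep) == 0) {
    return(tibble::tibble(cov_human = 0, cov_macaque = 0))
  }
  tibble::tibble(cov_human = mean(comp$coverage["human", keep]),
                 cov_macaque = mean(comp$coverage["macaque", keep]))
}

#' Build the exon/intron pair table for all coding exons of the transcripts
#' mapped to one composite region
#'
#' @param comp a `composite`.
#' @param tx_local region-local transcript tibble (one or more transcripts of
#'   the same region).
#' @param masks_local mask vectors from [region_masks()].
#' @param buffer,window see [select_intron_reference()].
#' @return Pair tibble, one row per coding exon, with genome coordinates
#'   (`chrom`, `gstart`, `gend`, `strand`, `gene_id`) for downstream
#'   deduplication and annotation.
#' @export
exon_pairs <- function(comp, tx_local, masks_local, buffer = 50L, window = 400L) {
  all_exons <- dplyr::bind_rows(tx_local$exons)
  rows <- list()
  for (i in seq_len(nrow(tx_local))) {
    t <- tx_local[i, ]
    ce <- t$coding_exons[[1]]
    for (j in seq_len(nrow(ce))) {
      w <- select_intron_reference(t, j, masks_local, all_exons = all_exons,
                                   buffer = buffer, window = window)
      pair <- count_differences(
        comp, ce$start[j], ce$end[j], w,
        exon_id = sprintf("%s:e%02d", t$transcript_id, j),
        transcript_id = t$transcript_id
      )
      pair$exon_index <- j
      pair$gene_id <- t$gene_id
      pair$chrom <- t$chrom
      pair$strand <- t$strand
      pair$gstart <- ce$start[j] + t$region_start
      pair$gend <- ce$end[j] + t$region_start
      rows[[length(rows) + 1L]] <- pair
    }
  }
  if (length(rows) == 0) return(tibble::tibble())
  dplyr::bind_rows(rows)
}

# Region-local positions of the transcript's coding sequence in translation
# order (5' -> 3' of the mRNA). For "-" transcripts this is the reversed
# genomic order; bases must additionally be complemented.
cds_map <- function(t) {
  stopifnot(nrow(t) == 1)
  ce <- t$coding_exons[[1]]
  pos <- unlist(purrr::map2(ce$start, ce$end, ~ .x:(.y - 1L)))
  if (t$strand == "-") rev(pos) else pos
}

COMPLEMENT <- function(x) chartr("ACGTacgt", "TGCAtgca", x)
STOP_CODONS <- c("TAA", "TAG", "TGA")

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Precompute a fast per-transcript substitution classifier. The returned
# function maps (pos, alt_base) to "synonymous"/"nonsynonymous"/"stop", or
# NA_character_ for positions outside complete codons of the coding sequence.
substitution_classifier <- function(region_seq, t) {
  map <- cds_map(t)
  L <- nchar(region_seq)
  cds_index <- rep(NA_integer_, L)
  cds_index[map + 1L] <- seq_along(map)
  chars <- toupper(strsplit(region_seq, "", fixed = TRUE)[[1]])
  minus <- t$strand == "-"
  n_codons <- length(map) %/% 3L
  function(pos, alt_base) {
    i <- cds_index[pos + 1L]
    if (is.na(i)) return(NA_character_)
    codon_i <- (i - 1L) %/% 3L
    if (codon_i >= n_codons) return(NA_character_)
    within <- (i - 1L) %% 3L
    cpos <- map[codon_i * 3L + 1:3]
    b <- chars[cpos + 1L]
    alt <- toupper(alt_base)
    if (minus) {
      b <- COMPLEMENT(b)
      alt <- COMPLEMENT(alt)
    }
    ref_codon <- paste(b, collapse = "")
    b[within + 1L] <- alt
    alt_codon <- paste(b, collapse = "")
    if (alt_codon %in% STOP_CODONS) return("stop")
    if (identical(translate_codon(ref_codon), translate_codon(alt_codon))) {
      "synonymous"
    } else {
      "nonsynonymous"
    }
  }
}

#' Classify a substitution in a coding exon
#'
#' Substitutes `alt_base` (genome strand) into the codon covering a
#' region-local position and classifies the change under the standard genetic
#' code.
#'
#' @param region_seq region sequence string.
#' @param t one-row region-local transcript tibble.
#' @param pos 0-based region-local position inside a coding exon.
#' @param alt_base alternative base, given on the genome (+) strand.
#' @return `"synonymous"`, `"nonsynonymous"` or `"stop"`.
#' @export
classify_substitution <- function(region_seq, t, pos, alt_base) {
  cls <- substitution_classifier(region_seq, t)(pos, alt_base)
  if (is.na(cls)) {
    map <- cds_map(t)
    if (!pos %in% map) {
      stop("position not inside a coding exon", call. = FALSE)
    }
    stop("position falls in an incomplete terminal codon", call. = FALSE)
  }
  cls
}

#' In-frame coding sequence of one exon, reference and composite versions
#'
#' Extracts the exon's coding positions in translation order, trims partial
#' codons at both edges (exon boundaries are generally not codon-aligned) and
#' returns the reference sequence alongside the composite sequence, i.e. the
#' reference with the majority alternative base substituted at every
#' difference position.
#'
#' @param comp a `composite`.
#' @param t one-row region-local transcript tibble.
#' @param exon_index coding-exon index.
#' @return List with strings `ref` and `alt` (equal length, multiple of 3;
#'   possibly empty for very short exons).
#' @export
exon_coding_sequences <- function(comp, t, exon_index) {
  ce <- t$coding_exons[[1]]
  if (exon_index < 1 || exon_index > nrow(ce)) {
    stop("exon not in transcript", call. = FALSE)
  }
  map <- cds_map(t)
  in_exon <- map >= ce$start[exon_index] & map < ce$end[exon_index]
  idx <- which(in_exon)
  if (length(idx) == 0) return(list(ref = "", alt = ""))
  # trim to whole codons of the transcript frame
  first <- idx[1]; last <- idx[length(idx)]
  first <- first + ((3L - ((first - 1L) %% 3L)) %% 3L)
  last <- last - (last %% 3L)
  if (last - first + 1L < 3L) return(list(ref = "", alt = ""))
  pos <- map[first:last]
  refb <- toupper(substring(comp$ref, pos + 1L, pos + 1L))
  altb <- refb
  has_diff <- comp$diff[pos + 1L] & !is.na(comp$alt[pos + 1L])
  altb[has_diff] <- comp$alt[pos + 1L][has_diff]
  if (t$strand == "-") {
    refb <- COMPLEMENT(refb)
    altb <- COMPLEMENT(altb)
  }
  list(ref = paste(refb, collapse = ""), alt = paste(altb, collapse = ""))
}
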