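# Read-alignment filtering and composite-sequence construction.
#
# Alignments are rows of a tibble (one row per aligned read):
#   read_id, species ("human"/"macaque"), score, pct_identity, read_length,
#   region_id, region_start (0-based region-local position of the first
#   aligned reference base), cigar, read_seq, qual (Phred+33 string).
# CIGAR ops: M (aligned column, consumes read+reference), I (insertion,
# consumes read), D or N (deletion / reference skip, consumes reference).
# Only M columns can carry differences; indel columns are ignored.

SPECIES <- c("human", "macaque")

#' Read / write the tabular alignment format
#'
#' @param path TSV file with the ten alignment columns documented above.
#' @return A tibble of read alignments.
#' @export
read_alignments <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    read_id = readr::col_character(),
    species = readr::col_character(),
    score = readr::col_double(),
    pct_identity = readr::col_double(),
    read_length = readr::col_integer(),
    region_id = readr::col_character(),
    region_start = readr::col_integer(),
    cigar = readr::col_character(),
    read_seq = readr::col_character(),
    qual = readr::col_character()
  ), progress = FALSE)
}

#' @rdname read_alignments
#' @param aln alignment tibble.
#' @export
write_alignments <- function(aln, path) {
  readr::write_tsv(aln, path, progress = FALSE)
  invisible(path)
}

parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDN]", cigar))[[1]]
  if (length(lens) != length(ops) || length(ops) == 0) {
    stop(sprintf("malformed CIGAR '%s'", cigar), call. = FALSE)
  }
  list(ops = ops, lens = lens)
}

# Aligned (read_pos, ref_pos) columns for M ops, plus reference-skip
# junctions (left = last ref position before the skip + 1 = skip start,
# right = first ref position after). All 0-based region-local.
alignment_pairs <- function(region_start, cigar) {
  cg <- parse_cigar(cigar)
  ref <- integer(0); rd <- integer(0)
  jl <- integer(0); jr <- integer(0)
  rpos <- as.integer(region_start); qpos <- 0L
  for (k in seq_along(cg$ops)) {
    n <- cg$lens[k]
    op <- cg$ops[k]
    if (op == "M") {
      ref <- c(ref, rpos + 0:(n - 1L))
      rd <- c(rd, qpos + 0:(n - 1L))
      rpos <- rpos + n; qpos <- qpos + n
    } else if (op == "I") {
      qpos <- qpos + n
    } else { # D / N
      jl <- c(jl, rpos); jr <- c(jr, rpos + n)
      rpos <- rpos + n
    }
  }
  list(ref = ref, read = rd, junctions = list(left = jl, right = jr))
}

check_species <- function(species) {
  bad <- setdiff(unique(species), SPECIES)
  if (length(bad) > 0) {
    stop(sprintf("unknown species tag(s): %s (expected %s)",
                 paste(bad, collapse = ", "), paste(SPECIES, collapse = "/")),
         call. = FALSE)
  }
}

#' Filter read alignments by the mapping quality criteria
#'
#' Applies, in fixed order: alignment score >= `score_min`; percent identity
#' >= the species threshold (94 human / 88 macaque); aligned length > 300 bp;
#' aligned fraction of the read > 40%; number of aligned bases with Phred >=
#' `q_min` > 200; number of aligned bases outside repeat/tandem/CpG/gap masks
#' > 200. The first failing criterion is reported.
#'
#' @param aln alignment tibble (see [read_alignments()]).
#' @param masked logical mask vector over the region (union of all tracks).
#' @param q_min Phred threshold defining a high-quality base (default 27).
#' @param score_min alignment score threshold (default 220).
#' @param identity_min named vector of identity thresholds per species.
#' @param min_aligned,min_aligned_frac,min_hq,min_unmasked remaining
#'   thresholds (strict `>`).
#' @return `aln` with logical `accept` and character `reject_reason` columns.
#' @export
filter_alignments <- function(aln, masked, q_min = 27,
                              score_min = 220,
                              identity_min = c(human = 94, macaque = 88),
                              min_aligned = 300, min_aligned_frac = 0.40,
                              min_hq = 200, min_unmasked = 200) {
  check_species(aln$species)
  L <- length(masked)
  n <- nrow(aln)
  accept <- logical(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    pr <- alignment_pairs(aln$region_start[i], aln$cigar[i])
    inside <- pr$ref >= 0L & pr$ref < L
    quals <- utf8ToInt(aln$qual[i]) - 33L
    aligned <- length(pr$ref)
    hq <- sum(quals[pr$read[inside] + 1L] >= q_min)
    unmasked <- sum(!masked[pr$ref[inside] + 1L])
    fail <-
      if (aln$score[i] < score_min) "score"
      else if (aln$pct_identity[i] < identity_min[[aln$species[i]]]) "identity"
      else if (!(aligned > min_aligned)) "aligned_length"
      else if (!(aligned / aln$read_length[i] > min_aligned_frac)) "aligned_fraction"
      else if (!(hq > min_hq)) "hq_bases"
      else if (!(unmasked > min_unmasked)) "unmasked_bases"
      else NA_character_
    accept[i] <- is.na(fail)
    reason[i] <- fail
  }
  dplyr::mutate(aln, accept = accept, reject_reason = reason)
}

#' Build the composite sequence for a region
#'
#' Summarizes all accepted read alignments of a region into per-position
#' binary difference flags. A candidate difference is a read base differing
#' from the reference at an unmasked M column with Phred >= `q_min`; the flag
#' is set when at least `min_support` reads (pooled across species by
#' default) carry a high-quality mismatch at the position. Multiple
#' alternative bases at one site collapse to a single binary change.
#'
#' @param aln accepted alignment tibble.
#' @param region_seq region sequence string (case preserved).
#' @param masked logical mask vector (union of all tracks incl. soft-masked
#'   repeats).
#' @param q_min Phred threshold (default 27).
#' @param min_support minimum supporting reads for a difference (default 2).
#' @param pool_species pool supporting reads across species (default TRUE);
#'   if FALSE one species alone must reach `min_support`.
#' @param same_allele require the supporting reads to carry the same
#'   alternative base (default FALSE: site-level support).
#' @param region_id identifier stored in the object.
#' @return An object of class `composite`.
#' @export
build_composite <- function(aln, region_seq, masked, q_min = 27,
                            min_support = 2, pool_species = TRUE,
                            same_allele = FALSE, region_id = "") {
  check_species(aln$species)
  L <- nchar(region_seq)
  stopifnot(length(masked) == L)
  ref <- toupper(strsplit(region_seq, "", fixed = TRUE)[[1]])
  bases <- c("A", "C", "G", "T")
  cnt <- lapply(SPECIES, function(s) matrix(0L, nrow = 4, ncol = L))
  names(cnt) <- SPECIES
  cov <- lapply(SPECIES, function(s) integer(L))
  names(cov) <- SPECIES
  rejected <- list()
  for (i in seq_len(nrow(aln))) {
    pr <- alignment_pairs(aln$region_start[i], aln$cigar[i])
    if (length(pr$ref) == 0) next
    if (min(pr$ref) < 0L || max(pr$ref) >= L) {
      rejected[[length(rejected) + 1L]] <-
        tibble::tibble(read_id = aln$read_id[i], reason = "outside_region")
      next
    }
    sp <- aln$species[i]
    p1 <- pr$ref + 1L
    cov[[sp]][p1] <- cov[[sp]][p1] + 1L
    rb <- substring(aln$read_seq[i], pr$read + 1L, pr$read + 1L)
    rb <- toupper(rb)
    quals <- utf8ToInt(aln$qual[i]) - 33L
    q <- quals[pr$read + 1L]
    cand <- q >= q_min & !masked[p1] & rb != ref[p1] &
      rb %in% bases & ref[p1] %in% bases
    if (any(cand)) {
      bi <- match(rb[cand], bases)
      idx <- cbind(bi, p1[cand])
      cnt[[sp]][idx] <- cnt[[sp]][idx] + 1L
    }
  }
  sup <- lapply(cnt, colSums)
  total_cnt <- cnt$human + cnt$macaque
  if (same_allele) {
    if (pool_species) {
      best <- apply(total_cnt, 2, max)
    } else {
      best <- pmax(apply(cnt$human, 2, max), apply(cnt$macaque, 2, max))
    }
    diff <- best >= min_support
  } else {
    if (pool_species) {
      diff <- (sup$human + sup$macaque) >= min_support
    } else {
      diff <- sup$human >= min_support | sup$macaque >= min_support
    }
  }
  alt <- rep(NA_character_, L)
  if (any(diff)) {
    wd <- which(diff)
    alt[wd] <- bases[apply(total_cnt[, wd, drop = FALSE], 2, which.max)]
  }
  structure(
    list(
      region_id = region_id, length = L, ref = region_seq,
      diff = unname(diff),
      support = rbind(human = sup$human, macaque = sup$macaque),
      coverage = rbind(human = cov$human, macaque = cov$macaque),
      masked = masked, alt = alt,
      rejected = if (length(rejected)) dplyr::bind_rows(rejected)
                 else tibble::tibble(read_id = character(), reason = character()),
      params = list(q_min = q_min, min_support = min_support,
                    pool_species = pool_species, same_allele = same_allele)
    ),
    class = "composite"
  )
}

#' @export
print.composite <- function(x, ...) {
  cat(sprintf("<composite> region '%s': %d bp, %d difference(s), %d masked bp\n",
              x$region_id, x$length, sum(x$diff), sum(x$masked)))
  invisible(x)
}

#' @export
#' @method as_tibble composite
#' @importFrom tibble as_tibble
as_tibble.composite <- function(x, ...) {
  tibble::tibble(
    position = 0:(x$length - 1L),
    diff = x$diff,
    support_hs = x$support["human", ],
    support_mmu = x$support["macaque", ],
    cov_hs = x$coverage["human", ],
    cov_mmu = x$coverage["macaque", ],
    masked = x$masked,
    alt = x$alt
  )
}

#' Mean per-species coverage over the unmasked positions of an interval
#'
#' @param comp a `composite`.
#' @param start,end 0-based half-open region-local interval.
#' @return One-row tibble with `cov_human`, `cov_macaque`, `n_unmasked` and
#'   `all_masked` (TRUE when every position is masked; coverages are then 0).
#' @export
coverage_profile <- function(comp, start, end) {
  if (end <= start || start < 0 || end > comp$length) {
    stop("empty or out-of-range interval", call. = FALSE)
  }
  idx <- (start + 1L):end
  keep <- idx[!comp$masked[idx]]
  if (length(keep) == 0) {
    return(tibble::tibble(cov_human = 0, cov_macaque = 0,
                          n_unmasked = 0L, all_masked = TRUE))
  }
  tibble::tibble(
    cov_human = mean(comp$coverage["human", keep]),
    cov_macaque = mean(comp$coverage["macaque", keep]),
    n_unmasked = length(keep),
    all_masked = FALSE
  )
}
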