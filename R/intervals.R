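# Interval utilities. All coordinates in this package are 0-based, half-open
# (BED convention); an interval tibble has integer columns `start` and `end`
# with start < end, plus optional `chrom`/`strand`.

#' Create an interval tibble
#'
#' @param chrom character vector of sequence names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand optional strand (`"+"`, `"-"` or `"."`).
#' @return A tibble with one row per interval.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0L) || any(end <= start)) {
    stop("intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  tibble::tibble(chrom = chrom, start = start, end = end, strand = strand)
}

# Union of intervals on a single sequence: merge overlapping/adjacent-disjoint
# rows. Returns a tibble(start, end) sorted by start.
iv_reduce <- function(iv) {
  if (nrow(iv) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = iv$start + 1L, end = iv$end))
  tibble::tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Does interval (start,end) overlap any row of iv by >= 1 bp?
iv_any_overlap <- function(iv, start, end) {
  if (nrow(iv) == 0) return(rep(FALSE, length(start)))
  q <- IRanges::IRanges(start = start + 1L, end = end)
  s <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
  IRanges::overlapsAny(q, s)
}

# Logical mask of length (region_end - region_start): TRUE where a position of
# [region_start, region_end) on `chrom` falls inside a row of `iv`.
iv_mask_vector <- function(iv, chrom, region_start, region_end) {
  len <- region_end - region_start
  out <- logical(len)
  if (is.null(iv) || nrow(iv) == 0) return(out)
  rows <- iv
  if ("chrom" %in% names(rows)) rows <- rows[rows$chrom == chrom, , drop = FALSE]
  for (k in seq_len(nrow(rows))) {
    s <- max(rows$start[k], region_start) - region_start
    e <- min(rows$end[k], region_end) - region_start
    if (e > s) out[(s + 1L):e] <- TRUE
  }
  out
}

# Convert a sorted logical vector of selected 0-based positions into
# half-open interval runs.
positions_to_intervals <- function(pos) {
  if (length(pos) == 0) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  pos <- sort(unique(as.integer(pos)))
  brk <- which(diff(pos) != 1L)
  starts <- pos[c(1L, brk + 1L)]
  ends <- pos[c(brk, length(pos))] + 1L
  tibble::tibble(start = starts, end = ends)
}
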