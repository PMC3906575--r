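# Annotation input: transcript models (GenePred / BED12), mask tracks (BED3+)
# and region extraction from an indexed or in-memory FASTA genome.
#
# A transcript model is one row of a tibble with list-columns:
#   transcript_id, gene_id, chrom, strand, tx_start, tx_end, cds_start,
#   cds_end, exons (tibble start/end, all exons), coding_exons (tibble
#   start/end, UTR-trimmed), region_start, region_end.
# The analysis region is the transcript span padded by `flank` bp (clipped at
# the chromosome start; the end is clipped against the genome at extraction).

#' Load transcript models
#'
#' Reads a GenePred (10- or 15-column UCSC format, with or without a leading
#' `bin` column) or BED12 file and returns one transcript model per coding
#' record. Non-coding records (empty CDS) are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param path annotation file.
#' @param flank bp of flanking sequence added to each side of the transcript
#'   span to form the analysis region (default 800).
#' @param format `"auto"` (by column count), `"genepred"` or `"bed12"`.
#' @return A tibble of transcript models with attribute `n_skipped`.
#' @export
load_transcripts <- function(path, flank = 800L, format = c("auto", "genepred", "bed12")) {
  format <- match.arg(format)
  stopifnot(flank >= 0)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    out <- empty_transcripts()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (format == "auto") {
    format <- if (all(nf == 12L) && all(grepl("^[0-9]+$", vapply(fields, `[`, "", 10L)))) {
      "bed12"
    } else {
      "genepred"
    }
  }
  if (format == "genepred") {
    parse_genepred(fields, flank, path)
  } else {
    parse_bed12(fields, flank, path)
  }
}

empty_transcripts <- function() {
  tibble::tibble(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), tx_start = integer(), tx_end = integer(),
    cds_start = integer(), cds_end = integer(),
    exons = list(), coding_exons = list(),
    region_start = integer(), region_end = integer()
  )
}

parse_int_list <- function(x) {
  as.integer(strsplit(sub(",$", "", x), ",", fixed = TRUE)[[1]])
}

parse_genepred <- function(fields, flank, path) {
  nf <- lengths(fields)
  # optional leading bin column (UCSC table dumps): strand must be field 3
  rows <- purrr::map(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) >= 11 && f[4] %in% c("+", "-", ".") && grepl("^[0-9]+$", f[1])) {
      f <- f[-1]
    }
    if (length(f) < 10 || !(f[3] %in% c("+", "-", "."))) {
      stop(sprintf("malformed GenePred record at line %d of %s", i, path), call. = FALSE)
    }
    tx_start <- as.integer(f[4]); tx_end <- as.integer(f[5])
    cds_start <- as.integer(f[6]); cds_end <- as.integer(f[7])
    ex_s <- parse_int_list(f[9]); ex_e <- parse_int_list(f[10])
    if (anyNA(c(tx_start, tx_end, cds_start, cds_end, ex_s, ex_e)) ||
        length(ex_s) != length(ex_e) || length(ex_s) != as.integer(f[8])) {
      stop(sprintf("malformed GenePred record at line %d of %s", i, path), call. = FALSE)
    }
    if (cds_start == cds_end) return(NULL) # non-coding
    gene_id <- if (length(f) >= 12 && nzchar(f[12])) f[12] else f[1]
    make_transcript(f[1], gene_id, f[2], f[3], tx_start, tx_end,
                    cds_start, cds_end, ex_s, ex_e, flank)
  })
  finish_transcripts(rows)
}

parse_bed12 <- function(fields, flank, path) {
  rows <- purrr::map(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 12) {
      stop(sprintf("malformed BED12 record at line %d of %s", i, path), call. = FALSE)
    }
    chrom_start <- as.integer(f[2]); chrom_end <- as.integer(f[3])
    thick_start <- as.integer(f[7]); thick_end <- as.integer(f[8])
    sizes <- parse_int_list(f[11]); starts <- parse_int_list(f[12])
    if (anyNA(c(chrom_start, chrom_end, thick_start, thick_end, sizes, starts)) ||
        length(sizes) != length(starts)) {
      stop(sprintf("malformed BED12 record at line %d of %s", i, path), call. = FALSE)
    }
    if (thick_start == thick_end) return(NULL)
    ex_s <- chrom_start + starts
    ex_e <- ex_s + sizes
    make_transcript(f[4], f[4], f[1], f[6], chrom_start, chrom_end,
                    thick_start, thick_end, ex_s, ex_e, flank)
  })
  finish_transcripts(rows)
}

make_transcript <- function(tx_id, gene_id, chrom, strand, tx_start, tx_end,
                            cds_start, cds_end, ex_s, ex_e, flank) {
  o <- order(ex_s)
  ex_s <- ex_s[o]; ex_e <- ex_e[o]
  ce_s <- pmax(ex_s, cds_start)
  ce_e <- pmin(ex_e, cds_end)
  keep <- ce_e > ce_s
  tibble::tibble(
    transcript_id = tx_id, gene_id = gene_id, chrom = chrom, strand = strand,
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    exons = list(tibble::tibble(start = ex_s, end = ex_e)),
    coding_exons = list(tibble::tibble(start = ce_s[keep], end = ce_e[keep])),
    region_start = max(0L, as.integer(tx_start) - as.integer(flank)),
    region_end = as.integer(tx_end) + as.integer(flank)
  )
}

finish_transcripts <- function(rows) {
  skipped <- sum(vapply(rows, is.null, logical(1)))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0) empty_transcripts() else dplyr::bind_rows(rows)
  if (skipped > 0) {
    message(sprintf("skipped %d non-coding record(s) (cdsStart == cdsEnd)", skipped))
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Load mask tracks
#'
#' Builds a mask set from BED3+ files: interspersed repeats (<10% divergence),
#' tandem repeats (period < 12), CpG islands, and assembly gaps. A missing
#' file is an error unless `allow_missing = TRUE`, in which case the track is
#' empty and a warning is emitted.
#'
#' @param repeats,tandem,cpg,gaps paths to BED3+ files (or `NULL`).
#' @param allow_missing treat a missing/NULL file as an empty track.
#' @return An object of class `mask_set`.
#' @export
load_masks <- function(repeats = NULL, tandem = NULL, cpg = NULL, gaps = NULL,
                       allow_missing = FALSE) {
  one <- function(path, label) {
    if (is.null(path) || !file.exists(path %||% "")) {
      if (!allow_missing) {
        stop(sprintf("mask track '%s' missing (set allow_missing = TRUE to use an empty track)",
                     label), call. = FALSE)
      }
      warning(sprintf("mask track '%s' missing; using empty track", label), call. = FALSE)
      return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
    }
    read_bed3(path)
  }
  mask_set(
    repeats = one(repeats, "repeats"),
    tandem = one(tandem, "tandem"),
    cpg = one(cpg, "cpg"),
    gaps = one(gaps, "gaps")
  )
}

#' Construct a mask set from interval tibbles
#'
#' @param repeats,tandem,cpg,gaps tibbles with columns chrom, start, end.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(repeats = NULL, tandem = NULL, cpg = NULL, gaps = NULL) {
  empty <- tibble::tibble(chrom = character(), start = integer(), end = integer())
  structure(
    list(
      repeats = repeats %||% empty, tandem = tandem %||% empty,
      cpg = cpg %||% empty, gaps = gaps %||% empty
    ),
    class = "mask_set"
  )
}

#' @export
print.mask_set <- function(x, ...) {
  cat("<mask_set>\n")
  for (nm in names(x)) cat(sprintf("  %-8s %d interval(s)\n", nm, nrow(x[[nm]])))
  invisible(x)
}

read_bed3 <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    stop(sprintf("%s is not BED3+", path), call. = FALSE)
  }
  tibble::tibble(
    chrom = vapply(fields, `[`, "", 1L),
    start = as.integer(vapply(fields, `[`, "", 2L)),
    end = as.integer(vapply(fields, `[`, "", 3L))
  )
}

#' Is a genomic position masked?
#'
#' @param masks a `mask_set`.
#' @param chrom sequence name.
#' @param pos 0-based position(s).
#' @param tracks which tracks to consult (default: all).
#' @return Logical vector.
#' @export
is_masked <- function(masks, chrom, pos, tracks = names(masks)) {
  out <- rep(FALSE, length(pos))
  for (tr in tracks) {
    iv <- masks[[tr]]
    iv <- iv[iv$chrom == chrom, , drop = FALSE]
    if (nrow(iv) == 0) next
    out <- out | iv_any_overlap(iv, pos, pos + 1L)
  }
  out
}

#' Extract a transcript's analysis region from the genome
#'
#' Returns the region sequence with repeat masking preserved as lower case.
#' Region-local coordinate 0 maps to `region_start` on the genome. Regions
#' running past the chromosome end are clipped with a warning.
#'
#' @param genome a named character vector or `Biostrings::DNAStringSet`.
#' @param t a one-row transcript tibble (see [load_transcripts()]).
#' @return A single string of length `region_end - region_start` (or shorter
#'   if clipped).
#' @export
extract_region <- function(genome, t) {
  stopifnot(nrow(t) == 1)
  if (inherits(genome, "DNAStringSet")) {
    genome <- as.character(genome)
  }
  chrom <- t$chrom
  if (!chrom %in% names(genome)) {
    stop(sprintf("chromosome '%s' not present in genome", chrom), call. = FALSE)
  }
  seq <- genome[[chrom]]
  len <- nchar(seq)
  if (t$region_start >= len) {
    stop(sprintf("region for %s starts beyond chromosome end", t$transcript_id), call. = FALSE)
  }
  end <- t$region_end
  if (end > len) {
    warning(sprintf("region for %s clipped at chromosome end (%d > %d)",
                    t$transcript_id, end, len), call. = FALSE)
    end <- len
  }
  substr(seq, t$region_start + 1L, end)
}

#' Convert a transcript model to region-local coordinates
#'
#' Shifts all exon coordinates by `-region_start` so they index directly into
#' the extracted region sequence.
#'
#' @param t a transcript tibble (one or more rows).
#' @return The same tibble with local `exons`/`coding_exons` and a
#'   `region_length` column.
#' @export
to_region_local <- function(t) {
  shift <- function(iv, off) tibble::tibble(start = iv$start - off, end = iv$end - off)
  t %>%
    dplyr::mutate(
      exons = purrr::map2(.data$exons, .data$region_start, shift),
      coding_exons = purrr::map2(.data$coding_exons, .data$region_start, shift),
      region_length = .data$region_end - .data$region_start
    )
}

#' Per-track logical mask vectors over an analysis region
#'
#' Lower-case runs in the region sequence (RepeatMasker soft masking) are
#' folded into the repeats track when `fold_lowercase = TRUE`.
#'
#' @param masks a `mask_set`.
#' @param t one-row transcript tibble.
#' @param region_seq the extracted region sequence (for lower-case folding).
#' @param fold_lowercase fold soft-masked (lower-case) runs into repeats.
#' @return A list of logical vectors `repeats`, `tandem`, `cpg`, `gaps`,
#'   `all` (their union), each of region length.
#' @export
region_masks <- function(masks, t, region_seq = NULL, fold_lowercase = TRUE) {
  stopifnot(nrow(t) == 1)
  rs <- t$region_start
  re <- if (!is.null(region_seq)) rs + nchar(region_seq) else t$region_end
  out <- purrr::map(masks, iv_mask_vector, chrom = t$chrom,
                    region_start = rs, region_end = re)
  if (fold_lowercase && !is.null(region_seq)) {
    ch <- strsplit(region_seq, "", fixed = TRUE)[[1]]
    out$repeats <- out$repeats | (ch != toupper(ch))
  }
  out$all <- Reduce(`|`, out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
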