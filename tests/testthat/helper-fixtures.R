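# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Phred+33 string of a constant quality
qual_str <- function(q, n) strrep(intToUtf8(q + 33L), n)

# One aligned read as a one-row alignment tibble. Defaults pass every
# alignment filter for a sufficiently long read.
make_read <- function(read_id, read_seq, region_start = 0L,
                      species = "human", cigar = NULL, qual = NULL,
                      score = 500, identity = 99,
                      read_length = nchar(read_seq), region_id = "r") {
  tibble::tibble(
    read_id = read_id, species = species, score = score,
    pct_identity = identity, read_length = as.integer(read_length),
    region_id = region_id, region_start = as.integer(region_start),
    cigar = cigar %||% paste0(nchar(read_seq), "M"),
    read_seq = read_seq,
    qual = qual %||% qual_str(40L, nchar(read_seq))
  )
}

# Transcript tibble in genome coordinates (same structure load_transcripts
# produces), built from exon vectors.
make_tx <- function(transcript_id = "tx1", gene_id = transcript_id,
                    chrom = "chr1", strand = "+", ex_start, ex_end,
                    cds_start = min(ex_start), cds_end = max(ex_end),
                    flank = 800L) {
  accelexon:::make_transcript(transcript_id, gene_id, chrom, strand,
                              min(ex_start), max(ex_end), cds_start, cds_end,
                              ex_start, ex_end, flank)
}

# Hand-built composite object for counting / filter unit tests.
make_composite <- function(ref, diff = NULL, masked = NULL,
                           cov_hs = NULL, cov_mmu = NULL,
                           sup_hs = NULL, sup_mmu = NULL, alt = NULL,
                           region_id = "r") {
  L <- nchar(ref)
  diff <- diff %||% logical(L)
  masked <- masked %||% logical(L)
  cov_hs <- cov_hs %||% rep(5L, L)
  cov_mmu <- cov_mmu %||% rep(5L, L)
  sup_hs <- sup_hs %||% as.integer(diff) * 2L
  sup_mmu <- sup_mmu %||% integer(L)
  structure(
    list(region_id = region_id, length = L, ref = ref, diff = diff,
         support = rbind(human = sup_hs, macaque = sup_mmu),
         coverage = rbind(human = cov_hs, macaque = cov_mmu),
         masked = masked, alt = alt %||% rep(NA_character_, L),
         rejected = tibble::tibble(read_id = character(), reason = character()),
         params = list(q_min = 27, min_support = 2, pool_species = TRUE,
                       same_allele = FALSE)),
    class = "composite"
  )
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Region-local single-exon transcript + clean region, used repeatedly in
# pairing tests: exon [1000, 1200) inside a 2600 bp region.
toy_region <- function(region_len = 2600L, exon_start = 1000L,
                       exon_end = 1200L, strand = "+", seed = 42) {
  t <- make_tx(ex_start = exon_start, ex_end = exon_end, strand = strand,
               flank = exon_start)
  t$region_start <- 0L
  t$region_end <- region_len
  t_local <- accelexon::to_region_local(t)
  list(
    t = t, t_local = t_local,
    region_seq = random_seq(region_len, seed = seed),
    masks = list(repeats = logical(region_len), tandem = logical(region_len),
                 cpg = logical(region_len), gaps = logical(region_len),
                 all = logical(region_len))
  )
}
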