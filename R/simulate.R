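# Synthetic-data generator: random genomes with configurable gene structure,
# paralogous copies recorded as segmental duplications, two species of
# Sanger-length reads with Phred qualities, planted exonic/intronic
# difference rates and retro-pseudogene (intronless) read contamination.
# Every output is a deterministic function of the seed.
#
# Generative model: for every gene the analysis region is
#   [flank | exon | intron | exon | ... | flank].
# Each (species, copy) pair owns one haplotype derived from the reference:
# the primary human copy is the reference itself; additional human copies
# diverge at `paralog_divergence` per bp; every macaque copy diverges at
# `intron_rate` per bp. Inside the coding exons of an accelerated gene the
# per-bp divergence is multiplied by `exon_rate_factor`. Reads sample
# uniformly from each haplotype and are emitted as perfect alignments in the
# coordinates of the primary locus, reproducing the cross-copy aggregation
# the composite sequence performs on real data.

#' Simulation configuration
#'
#' @param seed integer seed; fully determines all outputs.
#' @param n_genes number of genes.
#' @param n_accelerated how many genes (the first ones) carry accelerated
#'   coding exons.
#' @param exons_per_gene,exon_len,intron_len gene structure (bp).
#' @param flank flanking sequence per side of the transcript span (bp).
#' @param intron_rate per-bp difference probability of neutral sequence (the
#'   generative counterpart of D_i).
#' @param exon_rate_factor multiplier on `intron_rate` inside accelerated
#'   coding exons (1 = null).
#' @param copy_number gene copies per species (1 = single-copy).
#' @param paralog_divergence per-bp divergence of additional human copies.
#' @param read_len Sanger-like read length (bp, default 700).
#' @param reads_per_copy reads per species per copy.
#' @param phred_hq,phred_lq,lq_fraction base qualities: high-quality level,
#'   low-quality level, and the fraction of bases at the low level.
#' @param pseudogene_fraction fraction of additional reads drawn from an
#'   intronless retro-copy of the spliced transcript.
#' @param pseudogene_rate_factor multiplier on `intron_rate` for the
#'   retro-copy's divergence (released from coding constraint).
#' @param score planted alignment score per read.
#' @param repeat_density,tandem_density,cpg_density,gap_density approximate
#'   masked fraction per track (placed as random 50 bp intervals).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 1L, n_accelerated = 0L,
                       exons_per_gene = 1L, exon_len = 200L,
                       intron_len = 600L, flank = 800L,
                       intron_rate = 0.03, exon_rate_factor = 1,
                       copy_number = 1L, paralog_divergence = 0.02,
                       read_len = 700L, reads_per_copy = 10L,
                       phred_hq = 40L, phred_lq = 15L, lq_fraction = 0.1,
                       pseudogene_fraction = 0,
                       pseudogene_rate_factor = 3,
                       score = 500,
                       repeat_density = 0, tandem_density = 0,
                       cpg_density = 0, gap_density = 0) {
  cfg <- as.list(environment())
  rates <- c(cfg$intron_rate, cfg$lq_fraction, cfg$pseudogene_fraction,
             cfg$repeat_density, cfg$tandem_density, cfg$cpg_density,
             cfg$gap_density)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (any(c(cfg$exon_len, cfg$intron_len, cfg$read_len, cfg$n_genes,
            cfg$exons_per_gene, cfg$copy_number, cfg$reads_per_copy) <= 0)) {
    stop("lengths and counts must be positive", call. = FALSE)
  }
  if (cfg$intron_rate * cfg$exon_rate_factor > 1) {
    stop("exonic rate exceeds 1", call. = FALSE)
  }
  if (cfg$n_accelerated > cfg$n_genes) stop("n_accelerated > n_genes", call. = FALSE)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(chars, sites) {
  if (length(sites) == 0) return(chars)
  cur <- chars[sites]
  sub <- vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1), USE.NAMES = FALSE)
  chars[sites] <- sub
  chars
}

# Per-position difference probability over one region, for one haplotype with
# baseline divergence d: d everywhere, d * factor inside accelerated coding
# exons.
hap_site_rates <- function(region_len, coding_exons, d, factor) {
  r <- rep(d, region_len)
  if (factor != 1) {
    for (k in seq_len(nrow(coding_exons))) {
      idx <- (coding_exons$start[k] + 1L):coding_exons$end[k]
      r[idx] <- d * factor
    }
  }
  r
}

#' Simulate a reference dataset
#'
#' Generates the genome, transcript models, mask tracks, SD intervals, the
#' per-(species, copy) haplotypes and the planted truth for a configuration.
#'
#' @param cfg a [sim_config()].
#' @return List with `genome` (named character), `transcripts`, `masks`
#'   (`mask_set`), `sd` (tibble), `truth` (per-exon tibble), `haplotypes`
#'   (internal, consumed by [simulate_reads()]) and `cfg`.
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  gene_len <- cfg$exons_per_gene * cfg$exon_len +
    max(0L, cfg$exons_per_gene - 1L) * cfg$intron_len
  region_len <- gene_len + 2L * cfg$flank
  spacing <- 200L
  chrom <- "sim1"
  genome_parts <- character(0)
  offset <- 0L
  tx <- list(); truth <- list(); haps <- list(); sd <- list()
  accelerated <- seq_len(cfg$n_genes) <= cfg$n_accelerated
  for (g in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("gene%03d", g)
    region_seq <- random_dna(region_len)
    region_start <- offset
    ex_local_start <- cfg$flank + (seq_len(cfg$exons_per_gene) - 1L) *
      (cfg$exon_len + cfg$intron_len)
    ce_local <- tibble::tibble(start = ex_local_start,
                               end = ex_local_start + cfg$exon_len)
    t <- tibble::tibble(
      transcript_id = gene_id, gene_id = gene_id, chrom = chrom, strand = "+",
      tx_start = region_start + cfg$flank,
      tx_end = region_start + region_len - cfg$flank,
      cds_start = region_start + cfg$flank,
      cds_end = region_start + region_len - cfg$flank,
      exons = list(tibble::tibble(start = ce_local$start + region_start,
                                  end = ce_local$end + region_start)),
      coding_exons = list(tibble::tibble(start = ce_local$start + region_start,
                                         end = ce_local$end + region_start)),
      region_start = region_start,
      region_end = region_start + region_len
    )
    genome_parts <- c(genome_parts, region_seq,
                      paste(rep("N", spacing), collapse = ""))
    offset <- offset + region_len + spacing
    factor <- if (accelerated[g]) cfg$exon_rate_factor else 1
    # haplotypes: one per (species, copy)
    ref_chars <- strsplit(region_seq, "", fixed = TRUE)[[1]]
    ghaps <- list()
    for (copy in seq_len(cfg$copy_number)) {
      for (sp in SPECIES) {
        d <- if (sp == "human") {
          if (copy == 1L) 0 else cfg$paralog_divergence
        } else {
          cfg$intron_rate
        }
        rates <- hap_site_rates(region_len, ce_local, d, factor)
        sites <- which(stats::runif(region_len) < rates)
        ghaps[[length(ghaps) + 1L]] <- list(
          gene_id = gene_id, species = sp, copy = copy,
          chars = mutate_seq(ref_chars, sites), sites = sites,
          pseudogene = FALSE
        )
      }
    }
    # retro-pseudogene haplotype: the spliced exon sequence, diverged at the
    # released (neutral-or-faster) rate
    if (cfg$pseudogene_fraction > 0 && cfg$exons_per_gene >= 2) {
      mrna_pos <- unlist(purrr::map2(ce_local$start, ce_local$end,
                                     ~ .x:(.y - 1L)))
      mrna_chars <- ref_chars[mrna_pos + 1L]
      prate <- min(1, cfg$intron_rate * cfg$pseudogene_rate_factor)
      sites <- which(stats::runif(length(mrna_chars)) < prate)
      ghaps[[length(ghaps) + 1L]] <- list(
        gene_id = gene_id, species = NA_character_, copy = NA_integer_,
        chars = mutate_seq(mrna_chars, sites), sites = sites,
        pseudogene = TRUE, mrna_pos = mrna_pos, exons_local = ce_local
      )
    }
    haps[[gene_id]] <- ghaps
    # paralog loci appended to the genome; recorded as SD pairs
    if (cfg$copy_number > 1) {
      for (copy in 2:cfg$copy_number) {
        hap <- ghaps[[which(vapply(ghaps, function(h) {
          !h$pseudogene && h$species == "human" && h$copy == copy
        }, logical(1)))[1]]]
        locus_start <- offset
        genome_parts <- c(genome_parts, paste(hap$chars, collapse = ""),
                          paste(rep("N", spacing), collapse = ""))
        offset <- offset + region_len + spacing
        sd[[length(sd) + 1L]] <- tibble::tibble(
          chrom = chrom,
          start = c(region_start, locus_start),
          end = c(region_start + region_len, locus_start + region_len),
          name = sprintf("%s_copy%d", gene_id, copy)
        )
      }
    }
    tx[[g]] <- t
    truth[[g]] <- tibble::tibble(
      gene_id = gene_id,
      exon_id = sprintf("%s:e%02d", gene_id, seq_len(cfg$exons_per_gene)),
      accelerated = accelerated[g],
      true_intron_rate = cfg$intron_rate,
      true_exon_rate = cfg$intron_rate * factor,
      duplicated = cfg$copy_number > 1,
      copies = cfg$copy_number
    )
    # mask tracks: random 50 bp intervals at the configured density,
    # placed inside the region
    for (track in c("repeat", "tandem", "cpg", "gap")) {
      dens <- cfg[[paste0(track, "_density")]]
      if (dens > 0) {
        n_iv <- max(1L, round(dens * region_len / 50))
        st <- region_start + sort(sample.int(region_len - 50L, n_iv))
        key <- paste0(".mask_", track)
        haps[[gene_id]][[key]] <- tibble::tibble(chrom = chrom, start = st,
                                                 end = st + 50L)
      }
    }
  }
  pull_masks <- function(track) {
    rows <- purrr::map(haps, ~ .x[[paste0(".mask_", track)]])
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0) {
      tibble::tibble(chrom = character(), start = integer(), end = integer())
    } else {
      dplyr::bind_rows(rows)
    }
  }
  masks <- mask_set(repeats = pull_masks("repeat"), tandem = pull_masks("tandem"),
                    cpg = pull_masks("cpg"), gaps = pull_masks("gap"))
  # drop mask bookkeeping entries from the haplotype lists
  haps <- purrr::map(haps, function(gh) gh[!grepl("^\\.mask_", names(gh) %||% rep("", length(gh)))])
  list(
    genome = stats::setNames(paste(genome_parts, collapse = ""), chrom),
    transcripts = dplyr::bind_rows(tx),
    masks = masks,
    sd = if (length(sd)) dplyr::bind_rows(sd)
         else tibble::tibble(chrom = character(), start = integer(),
                             end = integer(), name = character()),
    truth = dplyr::bind_rows(truth),
    haplotypes = haps,
    cfg = cfg
  )
}

phred_string <- function(quals) {
  intToUtf8(quals + 33L)
}

#' Simulate reads and their alignments
#'
#' Samples `reads_per_copy` reads per (species, copy) haplotype of every gene,
#' uniformly over the region, plus retro-pseudogene reads at
#' `pseudogene_fraction` of the gene's read count. Base qualities are
#' `phred_hq` with a `lq_fraction` of `phred_lq` bases; each base is miscalled
#' with probability `10^(-q/10)`. The simulator acts as a perfect aligner:
#' alignments are emitted in primary-locus coordinates, pseudogene reads with
#' reference-skip CIGARs across the introns.
#'
#' @param cfg a [sim_config()].
#' @param ref output of [simulate_reference()].
#' @return List with `alignments` (the composite-module input tibble) and
#'   `read_truth` (per-read source and pseudogene flag).
#' @export
simulate_reads <- function(cfg, ref) {
  set.seed(cfg$seed + 1L)
  aln <- list(); rt <- list()
  for (g in seq_len(nrow(ref$transcripts))) {
    t <- ref$transcripts[g, ]
    gene_id <- t$gene_id
    region_len <- t$region_end - t$region_start
    ghaps <- ref$haplotypes[[gene_id]]
    normal <- ghaps[vapply(ghaps, function(h) !h$pseudogene, logical(1))]
    pseudo <- ghaps[vapply(ghaps, function(h) h$pseudogene, logical(1))]
    region_chars <- toupper(strsplit(
      substr(ref$genome[[t$chrom]], t$region_start + 1L, t$region_end),
      "", fixed = TRUE)[[1]])
    ridx <- 0L
    emit <- function(hap, n_reads) {
      hap_len <- length(hap$chars)
      rl <- min(cfg$read_len, hap_len)
      read_seq <- character(n_reads); qual <- character(n_reads)
      cig <- character(n_reads); rstart <- integer(n_reads)
      ident <- numeric(n_reads); ids <- character(n_reads)
      for (r in seq_len(n_reads)) {
        ridx <<- ridx + 1L
        start <- sample.int(hap_len - rl + 1L, 1L) - 1L
        chars <- hap$chars[(start + 1L):(start + rl)]
        quals <- ifelse(stats::runif(rl) < cfg$lq_fraction,
                        cfg$phred_lq, cfg$phred_hq)
        err <- stats::runif(rl) < 10^(-quals / 10)
        chars <- mutate_seq(chars, which(err))
        if (hap$pseudogene) {
          map <- hap$mrna_pos[(start + 1L):(start + rl)]
          cig[r] <- mrna_cigar(map)
          rstart[r] <- map[1]
          nm <- sum(region_chars[map + 1L] != toupper(chars))
        } else {
          cig[r] <- paste0(rl, "M")
          rstart[r] <- start
          nm <- sum(region_chars[(start + 1L):(start + rl)] != toupper(chars))
        }
        ids[r] <- sprintf("%s_r%04d", gene_id, ridx)
        read_seq[r] <- paste(chars, collapse = "")
        qual[r] <- phred_string(quals)
        ident[r] <- 100 * (1 - nm / rl)
      }
      # retro-copy reads are emitted as macaque: at the default retro-copy
      # divergence (several times the neutral rate) they sit inside the
      # macaque identity threshold, mimicking the cross-species pseudogene
      # reads that survive the alignment filters on real data
      species <- if (is.na(hap$species)) "macaque" else hap$species
      tibble::tibble(
        read_id = ids, species = species, score = cfg$score,
        pct_identity = ident, read_length = rl, region_id = gene_id,
        region_start = rstart, cigar = cig, read_seq = read_seq, qual = qual,
        .pseudogene = hap$pseudogene, .copy = hap$copy,
        .source_species = hap$species
      )
    }
    for (hap in normal) {
      aln[[length(aln) + 1L]] <- emit(hap, cfg$reads_per_copy)
    }
    if (length(pseudo) > 0 && cfg$pseudogene_fraction > 0) {
      n_total <- cfg$reads_per_copy * cfg$copy_number * length(SPECIES)
      n_pseudo <- round(cfg$pseudogene_fraction * n_total)
      if (n_pseudo > 0) {
        aln[[length(aln) + 1L]] <- emit(pseudo[[1]], n_pseudo)
      }
    }
  }
  aln <- dplyr::bind_rows(aln)
  truth <- tibble::tibble(
    read_id = aln$read_id, region_id = aln$region_id,
    species = aln$species, pseudogene = aln$.pseudogene,
    copy = aln$.copy, source_species = aln$.source_species
  )
  aln <- dplyr::select(aln, -dplyr::starts_with("."))
  list(alignments = aln, read_truth = truth)
}

# CIGAR of a read whose aligned reference positions are `map` (monotone,
# contiguous in read space): M runs separated by N skips.
mrna_cigar <- function(map) {
  iv <- positions_to_intervals(map)
  parts <- character(0)
  for (k in seq_len(nrow(iv))) {
    parts <- c(parts, sprintf("%dM", iv$end[k] - iv$start[k]))
    if (k < nrow(iv)) {
      parts <- c(parts, sprintf("%dN", iv$start[k + 1L] - iv$end[k]))
    }
  }
  paste(parts, collapse = "")
}

#' Run the LRT power study over a simulation grid
#'
#' For every (exon_rate_factor, copy_number, reads_per_copy) cell, simulates
#' `n_reps` single-gene replicates, runs the composite/pairing/LRT chain, and
#' reports the rejection rate at `q_cut` (q-values computed within the cell).
#'
#' @param cfg_base base [sim_config()] (seed taken from here).
#' @param factors,copy_numbers,reads_per_copy grid values.
#' @param n_reps replicates per cell (>= 1; the acceptance study uses >= 100).
#' @param q_cut q-value cutoff.
#' @return Tibble with one row per cell: grid values, `rejection_rate`,
#'   `n_reps`.
#' @export
run_power_study <- function(cfg_base, factors = c(1, 3),
                            copy_numbers = c(1L, 2L, 4L),
                            reads_per_copy = NULL, n_reps = 100L,
                            q_cut = 0.05) {
  if (n_reps < 1) stop("n_reps must be at least 1", call. = FALSE)
  reads_per_copy <- reads_per_copy %||% cfg_base$reads_per_copy
  grid <- expand.grid(factor = factors, copy_number = copy_numbers,
                      reads_per_copy = reads_per_copy)
  out <- list()
  for (row in seq_len(nrow(grid))) {
    ps <- numeric(n_reps)
    de_gt_di <- logical(n_reps)
    for (rep in seq_len(n_reps)) {
      cfg <- sim_config(
        seed = cfg_base$seed + 7919L * row + rep,
        n_genes = 1L, n_accelerated = 1L,
        exons_per_gene = cfg_base$exons_per_gene,
        exon_len = cfg_base$exon_len, intron_len = cfg_base$intron_len,
        flank = cfg_base$flank, intron_rate = cfg_base$intron_rate,
        exon_rate_factor = grid$factor[row],
        copy_number = grid$copy_number[row],
        paralog_divergence = cfg_base$paralog_divergence,
        read_len = cfg_base$read_len,
        reads_per_copy = grid$reads_per_copy[row],
        phred_hq = cfg_base$phred_hq, phred_lq = cfg_base$phred_lq,
        lq_fraction = cfg_base$lq_fraction
      )
      res <- simulate_and_test(cfg)
      ps[rep] <- res$p_value[1]
      de_gt_di[rep] <- !is.na(res$D_e[1]) && !is.na(res$D_i[1]) &&
        res$D_e[1] > res$D_i[1]
    }
    q <- storey_qvalues(ps)
    out[[row]] <- tibble::tibble(
      factor = grid$factor[row], copy_number = grid$copy_number[row],
      reads_per_copy = grid$reads_per_copy[row],
      rejection_rate = mean(q <= q_cut & de_gt_di),
      n_reps = n_reps
    )
  }
  dplyr::bind_rows(out)
}

# Minimal simulate -> composite -> pairs -> LRT chain for one configuration;
# returns the LRT results of the first exon of every gene.
simulate_and_test <- function(cfg) {
  ref <- simulate_reference(cfg)
  reads <- simulate_reads(cfg, ref)
  rows <- list()
  for (g in seq_len(nrow(ref$transcripts))) {
    t <- ref$transcripts[g, ]
    region_seq <- extract_region(ref$genome, t)
    t_local <- to_region_local(t)
    ml <- region_masks(ref$masks, t, region_seq)
    aln <- reads$alignments[reads$alignments$region_id == t$transcript_id, ]
    aln <- filter_alignments(aln, ml$all)
    aln <- aln[aln$accept, , drop = FALSE]
    comp <- build_composite(aln, region_seq, ml$all, region_id = t$transcript_id)
    rows[[g]] <- exon_pairs(comp, t_local, ml)
  }
  lrt_exon(dplyr::bind_rows(rows))
}
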