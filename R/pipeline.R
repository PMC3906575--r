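# End-to-end pipeline and the command-line front end: configuration with the
# published defaults, stage chaining, deterministic artifact serialization
# and a reproducible run manifest.

#' Run configuration
#'
#' Collects input paths, thresholds (defaulting to the published values) and
#' run metadata. Thresholds out of range fail validation before any compute.
#'
#' @param genome,transcripts,repeats,tandem,cpg,gaps,sd,alignments,tandem_genes
#'   input paths (all optional when `sim` is given).
#' @param sim optional [sim_config()]: simulate inputs instead of loading.
#' @param score_min,identity_human,identity_macaque,q_min,min_support,buffer,
#'   window,di_floor,q_cut,pg_window,flank analysis thresholds.
#' @param seed integer seed.
#' @param out_dir output directory for artifact-writing subcommands.
#' @return List of class `run_config`.
#' @export
run_config <- function(genome = NULL, transcripts = NULL, repeats = NULL,
                       tandem = NULL, cpg = NULL, gaps = NULL, sd = NULL,
                       alignments = NULL, tandem_genes = NULL, sim = NULL,
                       score_min = 220, identity_human = 94,
                       identity_macaque = 88, q_min = 27, min_support = 2,
                       buffer = 50, window = 400, di_floor = 0.01,
                       q_cut = 0.05, pg_window = 10, flank = 800,
                       seed = 1L, out_dir = ".") {
  cfg <- as.list(environment())
  checks <- c(
    score_min >= 0, identity_human >= 0 && identity_human <= 100,
    identity_macaque >= 0 && identity_macaque <= 100,
    q_min >= 0, min_support >= 1, buffer >= 0, window > 0,
    di_floor >= 0 && di_floor <= 1, q_cut > 0 && q_cut <= 1,
    pg_window > 0, flank >= 0
  )
  if (!all(checks)) stop("threshold out of range", call. = FALSE)
  structure(cfg, class = "run_config")
}

load_inputs <- function(cfg) {
  if (!is.null(cfg$sim)) {
    ref <- simulate_reference(cfg$sim)
    reads <- simulate_reads(cfg$sim, ref)
    return(list(genome = ref$genome, transcripts = ref$transcripts,
                masks = ref$masks, sd = ref$sd,
                alignments = reads$alignments, truth = ref$truth,
                read_truth = reads$read_truth,
                tandem_genes = character()))
  }
  for (p in c("genome", "transcripts", "alignments")) {
    if (is.null(cfg[[p]]) || !file.exists(cfg[[p]])) {
      stop(sprintf("missing input: %s (%s)", p, cfg[[p]] %||% "<unset>"),
           call. = FALSE)
    }
  }
  genome <- Biostrings::readDNAStringSet(cfg$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  list(
    genome = as.character(genome),
    transcripts = load_transcripts(cfg$transcripts, flank = cfg$flank),
    masks = load_masks(cfg$repeats, cfg$tandem, cfg$cpg, cfg$gaps,
                       allow_missing = TRUE),
    sd = if (!is.null(cfg$sd) && file.exists(cfg$sd)) read_bed3(cfg$sd)
         else tibble::tibble(chrom = character(), start = integer(),
                             end = integer()),
    alignments = read_alignments(cfg$alignments),
    truth = NULL, read_truth = NULL,
    tandem_genes = if (!is.null(cfg$tandem_genes) && file.exists(cfg$tandem_genes)) {
      readr::read_lines(cfg$tandem_genes)
    } else character()
  )
}

#' Run the full accelerated-exon scan
#'
#' Chains region extraction, alignment filtering, composite construction,
#' exon/intron pairing, the likelihood-ratio test, Storey q-values, the
#' significant set, the filter cascade and (when SD intervals are available)
#' the duplication enrichment test.
#'
#' @param cfg a [run_config()].
#' @return An object of class `accel_scan` with elements `results`,
#'   `significant`, `verdicts`, `cascade`, `enrichment`, `regions`, `truth`
#'   and `config`. Use [tidy()], [glance()] and `autoplot()` on it.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  inp <- load_inputs(cfg)
  regions <- list()
  pair_rows <- list()
  read_log <- list()
  for (i in seq_len(nrow(inp$transcripts))) {
    t <- inp$transcripts[i, ]
    region_seq <- extract_region(inp$genome, t)
    t_local <- to_region_local(t)
    ml <- region_masks(inp$masks, t, region_seq)
    aln_all <- inp$alignments[inp$alignments$region_id == t$transcript_id, ,
                              drop = FALSE]
    aln_all <- filter_alignments(
      aln_all, ml$all, q_min = cfg$q_min, score_min = cfg$score_min,
      identity_min = c(human = cfg$identity_human,
                       macaque = cfg$identity_macaque)
    )
    read_log[[i]] <- dplyr::select(aln_all, "read_id", "species", "region_id",
                                   "accept", "reject_reason")
    aln <- aln_all[aln_all$accept, , drop = FALSE]
    comp <- build_composite(aln, region_seq, ml$all, q_min = cfg$q_min,
                            min_support = cfg$min_support,
                            region_id = t$transcript_id)
    pairs <- exon_pairs(comp, t_local, ml, buffer = cfg$buffer,
                        window = cfg$window)
    regions[[t$transcript_id]] <- list(t = t, t_local = t_local,
                                       region_seq = region_seq,
                                       masks_local = ml, aln = aln,
                                       comp = comp)
    pair_rows[[i]] <- pairs
  }
  results <- lrt_exon(dplyr::bind_rows(pair_rows))
  results$q_value <- NA_real_
  testable <- results$testable
  if (any(testable)) {
    results$q_value[testable] <- storey_qvalues(results$p_value[testable])
  }
  if (nrow(inp$sd) > 0) {
    results <- annotate_duplication(results, inp$sd)
  } else {
    results$duplication <- "single_copy"
  }
  sig <- significant_set(results, q_cut = cfg$q_cut)
  verdicts <- filter_cascade(sig, regions, tandem_genes = inp$tandem_genes,
                             di_floor = cfg$di_floor,
                             pg_window = cfg$pg_window, p_cut = cfg$q_cut)
  cascade <- attr(sig, "cascade")
  cascade$passed_filters <- sum(verdicts$passed)
  final <- sig[sig$exon_id %in% verdicts$exon_id[verdicts$passed], ,
               drop = FALSE]
  enrichment <- NULL
  if (nrow(inp$sd) > 0 && nrow(results) > 0 &&
      length(unique(results$duplication)) == 2 && nrow(final) > 0) {
    dup_final <- sum(final$duplication == "duplicated")
    dup_rest <- sum(results$duplication == "duplicated") - dup_final
    sc_final <- nrow(final) - dup_final
    sc_rest <- sum(results$duplication == "single_copy") - sc_final
    enrichment <- dplyr::mutate(
      fisher_enrichment(dup_final, sc_final, dup_rest, sc_rest),
      a = dup_final, b = sc_final, c = dup_rest, d = sc_rest
    )
  }
  structure(
    list(results = results, significant = sig, final = final,
         verdicts = verdicts, cascade = cascade, enrichment = enrichment,
         regions = regions, read_log = dplyr::bind_rows(read_log),
         truth = inp$truth, read_truth = inp$read_truth, sd = inp$sd,
         config = cfg),
    class = "accel_scan"
  )
}

#' @export
print.accel_scan <- function(x, ...) {
  cat(sprintf(
    "<accel_scan> %d exon/intron pairs tested; %d with D_e > D_i; %d significant (q <= %.3g); %d pass all filters\n",
    x$cascade$tested, x$cascade$de_gt_di, x$cascade$significant,
    x$config$q_cut, x$cascade$passed_filters))
  invisible(x)
}

#' @export
#' @method tidy accel_scan
tidy.accel_scan <- function(x, ...) {
  dplyr::select(x$results, -"windows")
}

#' @export
#' @method glance accel_scan
glance.accel_scan <- function(x, ...) {
  out <- x$cascade
  if (!is.null(x$enrichment)) {
    out$enrichment_p <- x$enrichment$p_two_sided
  }
  out
}

#' In-frame coding sequences (reference and composite) for every exon pair
#'
#' @param scan an `accel_scan`.
#' @return Tibble `exon_id`, `ref`, `alt` for use with [permutation_dnds()].
#' @export
scan_exon_sequences <- function(scan) {
  rows <- purrr::map(seq_len(nrow(scan$results)), function(i) {
    r <- scan$results[i, ]
    reg <- scan$regions[[r$transcript_id]]
    cs <- exon_coding_sequences(reg$comp, reg$t_local, r$exon_index)
    tibble::tibble(exon_id = r$exon_id, ref = cs$ref, alt = cs$alt)
  })
  dplyr::bind_rows(rows)
}

# ---- deterministic artifact serialization -------------------------------

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == floor(x) & abs(x) < 1e15 & (x == 0 | abs(x) >= 1e-4),
                format(x, scientific = FALSE, trim = TRUE),
                formatC(x, digits = 6, format = "g")))
}

write_tsv_fixed <- function(df, path) {
  df <- dplyr::select(df, dplyr::where(~ !is.list(.x)))
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- fmt_num(df[[col]])
  }
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path, width = 80L)
  invisible(path)
}

write_genepred <- function(transcripts, path) {
  lines <- vapply(seq_len(nrow(transcripts)), function(i) {
    t <- transcripts[i, ]
    ex <- t$exons[[1]]
    paste(
      t$transcript_id, t$chrom, t$strand, t$tx_start, t$tx_end,
      t$cds_start, t$cds_end, nrow(ex),
      paste0(paste(ex$start, collapse = ","), ","),
      paste0(paste(ex$end, collapse = ","), ","),
      sep = "\t"
    )
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

write_bed <- function(iv, path) {
  df <- iv[, intersect(c("chrom", "start", "end", "name"), names(iv)),
           drop = FALSE]
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

write_manifest <- function(cfg, out_dir, inputs_written = character()) {
  # out_dir is machine-specific and would break byte-identical reruns
  serializable <- purrr::map(unclass(cfg)[setdiff(names(cfg), "out_dir")],
                             function(v) {
    if (inherits(v, "sim_config")) unclass(v) else v
  })
  checksums <- NULL
  existing <- inputs_written[file.exists(inputs_written)]
  if (length(existing) > 0) {
    checksums <- as.list(tools::md5sum(existing))
    names(checksums) <- basename(existing)
  }
  manifest <- list(
    package = "accelexon",
    version = as.character(utils::packageVersion("accelexon")),
    config = serializable,
    input_checksums = checksums
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# ---- subcommands --------------------------------------------------------

#' Run a pipeline subcommand
#'
#' Subcommands: `simulate` (write simulated inputs), `composite`, `pairs`,
#' `test` (LRT + q-values on a pairs table or a bare 4-column counts file),
#' `filter`, `enrich`, and `all` (the full chain). Every run writes a
#' `manifest.json` recording the configuration and input checksums.
#'
#' @param name subcommand name.
#' @param cfg a [run_config()].
#' @param counts for `test`: path to a TSV with columns `x_e`, `n_e`, `x_i`,
#'   `n_i` (or exactly four unnamed columns in that order).
#' @return Invisibly, the paths of the artifacts written.
#' @export
run_subcommand <- function(name, cfg, counts = NULL) {
  valid <- c("simulate", "composite", "pairs", "test", "filter", "enrich", "all")
  if (!name %in% valid) {
    stop(sprintf("unknown subcommand '%s' (expected one of: %s)",
                 name, paste(valid, collapse = ", ")), call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  add <- function(p) paths <<- c(paths, p)
  if (name == "simulate") {
    if (is.null(cfg$sim)) stop("simulate requires a sim_config", call. = FALSE)
    inp <- load_inputs(cfg)
    add(write_genome_fasta(inp$genome, file.path(cfg$out_dir, "genome.fa")))
    add(write_genepred(inp$transcripts, file.path(cfg$out_dir, "transcripts.gp")))
    for (track in names(inp$masks)) {
      add(write_bed(inp$masks[[track]],
                    file.path(cfg$out_dir, paste0("mask_", track, ".bed"))))
    }
    add(write_bed(inp$sd, file.path(cfg$out_dir, "sd.bed")))
    add(write_alignments(inp$alignments,
                         file.path(cfg$out_dir, "alignments.tsv")))
    add(write_tsv_fixed(inp$truth, file.path(cfg$out_dir, "truth.tsv")))
    add(write_tsv_fixed(inp$read_truth,
                        file.path(cfg$out_dir, "read_truth.tsv")))
  } else if (name == "test") {
    if (is.null(counts)) stop("test requires a counts file", call. = FALSE)
    df <- readr::read_tsv(counts, progress = FALSE,
                          show_col_types = FALSE)
    if (!all(c("x_e", "n_e", "x_i", "n_i") %in% names(df))) {
      if (ncol(df) < 4) stop("counts file needs 4 columns", call. = FALSE)
      df <- readr::read_tsv(counts, col_names = c("x_e", "n_e", "x_i", "n_i"),
                            progress = FALSE, show_col_types = FALSE)
    }
    res <- lrt_exon(df)
    res$q_value <- storey_qvalues(res$p_value)
    add(write_tsv_fixed(res, file.path(cfg$out_dir, "results.tsv")))
  } else {
    scan <- run_pipeline(cfg)
    if (name %in% c("composite", "all")) {
      comp_tbl <- dplyr::bind_rows(purrr::map(scan$regions, function(r) {
        dplyr::mutate(tibble::as_tibble(r$comp), region_id = r$comp$region_id,
                      .before = 1)
      }))
      add(write_tsv_fixed(comp_tbl, file.path(cfg$out_dir, "composites.tsv")))
      add(write_tsv_fixed(scan$read_log, file.path(cfg$out_dir, "reads_log.tsv")))
    }
    if (name %in% c("pairs", "all")) {
      add(write_tsv_fixed(scan$results[, setdiff(names(scan$results),
                                                 c("p_hat_e", "p_hat_i", "p_hat_0",
                                                   "lambda", "statistic", "p_value",
                                                   "q_value"))],
                          file.path(cfg$out_dir, "pairs.tsv")))
    }
    if (name %in% c("filter", "all")) {
      v <- dplyr::mutate(scan$verdicts,
                         failed_rules = purrr::map_chr(
                           scan$verdicts$failed_rules,
                           ~ paste(.x, collapse = ",")))
      add(write_tsv_fixed(v, file.path(cfg$out_dir, "verdicts.tsv")))
    }
    if (name %in% c("enrich", "all")) {
      if (!is.null(scan$enrichment)) {
        add(write_tsv_fixed(scan$enrichment,
                            file.path(cfg$out_dir, "enrichment.tsv")))
      }
    }
    if (name == "all") {
      add(write_tsv_fixed(tidy(scan), file.path(cfg$out_dir, "results.tsv")))
      add(write_tsv_fixed(scan$cascade, file.path(cfg$out_dir, "cascade.tsv")))
    }
  }
  add(write_manifest(cfg, cfg$out_dir, paths))
  invisible(paths)
}
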