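# Single entry point wiring all stages: simulate (or load) inputs,
# classify, discover, quantify, and write TSV artifacts plus a run
# manifest.  Identical config + seed gives byte-identical outputs.

#' Pipeline configuration
#'
#' Either simulate the inputs (`simulate = TRUE`, the default, using
#' `sim`) or point to files on disk: a genome FASTA, a directory of
#' per-class reference FASTAs (named `<class>.fa`), a counts TSV, and a
#' BED6 annotation (piRNA clusters / repeats).
#'
#' @param out_dir output directory.
#' @param seed integer seed for every stochastic stage.
#' @param simulate generate inputs with the synthetic-data module.
#' @param sim a [sim_config()] (used when `simulate = TRUE`).
#' @param genome_fasta,refs_dir,counts_tsv,annotation_bed input paths
#'   (used when `simulate = FALSE`).
#' @param discovery a [discovery_params()].
#' @param numerator_library,denominator_library library ids for the
#'   enrichment ratio (numerator is also the discovery library).
#' @param ratio_sig significant figures for ratio labels.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "sprfinder_out", seed = 1L,
                            simulate = TRUE, sim = sim_config(seed = seed),
                            genome_fasta = NULL, refs_dir = NULL,
                            counts_tsv = NULL, annotation_bed = NULL,
                            discovery = discovery_params(),
                            numerator_library = "sperm",
                            denominator_library = "testis",
                            ratio_sig = 2) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, sim = sim,
                 genome_fasta = genome_fasta, refs_dir = refs_dir,
                 counts_tsv = counts_tsv, annotation_bed = annotation_bed,
                 discovery = discovery,
                 numerator_library = numerator_library,
                 denominator_library = denominator_library,
                 ratio_sig = ratio_sig),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' The config round-trips: `read_config(write_config(cfg, p))` restores
#' every parameter.
#'
#' @param config a [pipeline_config()].
#' @param path YAML path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  # named vectors become YAML maps so their names survive the round trip
  x$sim <- lapply(unclass(x$sim), function(v)
    if (!is.null(names(v))) as.list(v) else v)
  x$discovery <- unclass(x$discovery)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) usage_error("config file not found: ", path)
  x <- yaml::read_yaml(path)
  sim <- do.call(sim_config, lapply(x$sim, function(v)
    if (is.list(v)) unlist(v) else v))
  disc <- do.call(discovery_params, x$discovery)
  pipeline_config(out_dir = x$out_dir, seed = x$seed,
                  simulate = x$simulate, sim = sim,
                  genome_fasta = x$genome_fasta, refs_dir = x$refs_dir,
                  counts_tsv = x$counts_tsv,
                  annotation_bed = x$annotation_bed, discovery = disc,
                  numerator_library = x$numerator_library,
                  denominator_library = x$denominator_library,
                  ratio_sig = x$ratio_sig)
}

load_pipeline_inputs <- function(config) {
  if (isTRUE(config$simulate)) {
    ds <- simulate_dataset(config$sim)
    ann <- ds$genome$truth
    return(list(genome = ds$genome, refs = ds$refs, counts = ds$counts,
                annotation = ann))
  }
  for (p in c(config$genome_fasta, config$counts_tsv)) {
    if (is.null(p)) usage_error("genome_fasta and counts_tsv are required ",
                                "when simulate = FALSE")
    if (!file.exists(p)) usage_error("input file not found: ", p)
  }
  if (is.null(config$refs_dir) || !dir.exists(config$refs_dir))
    usage_error("refs_dir not found")
  fa <- read_fasta(config$genome_fasta)
  genome <- setNames(fa$seq, fa$id)
  ref_files <- list.files(config$refs_dir, pattern = "\\.fa(sta)?$",
                          full.names = TRUE)
  if (!length(ref_files)) usage_error("no reference FASTAs in refs_dir")
  refs <- lapply(ref_files, read_fasta)
  names(refs) <- sub("\\.fa(sta)?$", "", basename(ref_files))
  ann <- if (!is.null(config$annotation_bed)) read_bed(config$annotation_bed)
  list(genome = genome, refs = refs,
       counts = read_counts_tsv(config$counts_tsv), annotation = ann)
}

#' Run the full pipeline
#'
#' Writes, under `config$out_dir`: per-library classification summaries
#' and length histograms, the candidate report, RPM and enrichment
#' tables for the candidates, 3'-variant tables for the stem-loop
#' candidates, dot-bracket structures of their folded windows, and a
#' run manifest recording the package version, parameters and seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `status` (0 on success), `files`
#'   (named vector of artifact paths), and `report` (the candidate
#'   report).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- load_pipeline_inputs(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(x, name) {
    p <- file.path(out, name)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- p
    p
  }

  index <- build_exact_index(inp$refs)
  libs <- unique(inp$counts$library_id)
  for (lib in libs) {
    sub <- inp$counts[inp$counts$library_id == lib, , drop = FALSE]
    cl <- classify_reads(sub, index, inp$genome, inp$annotation)
    emit(classify_library(cl), paste0("classification_", lib, ".tsv"))
    emit(length_histogram(sub), paste0("length_histogram_", lib, ".tsv"))
  }

  disc_counts <- inp$counts[inp$counts$library_id ==
                              config$numerator_library, , drop = FALSE]
  if (!nrow(disc_counts))
    usage_error("no reads for discovery library '",
                config$numerator_library, "'")
  report <- run_discovery(disc_counts, inp$genome, index, inp$annotation,
                          config$discovery)
  emit(report, "candidates.tsv")

  rpm <- rpm_normalize(inp$counts)
  cand_dna <- to_dna(report$seq)
  expr <- rpm[rpm$sequence %in% cand_dna, , drop = FALSE]
  emit(expr, "candidate_rpm.tsv")
  if (config$denominator_library %in% libs) {
    get_rpm <- function(seq, lib) {
      v <- rpm$rpm[rpm$sequence == seq & rpm$library_id == lib]
      if (length(v)) v else 0
    }
    enr <- do.call(rbind, lapply(cand_dna, function(s) {
      er <- enrichment_ratio(get_rpm(s, config$numerator_library),
                             get_rpm(s, config$denominator_library),
                             sig = config$ratio_sig)
      data.frame(sequence = to_rna(s),
                 rpm_num = get_rpm(s, config$numerator_library),
                 rpm_den = get_rpm(s, config$denominator_library),
                 ratio = er$value, ratio_label = er$label,
                 stringsAsFactors = FALSE)
    }))
    emit(enr, "enrichment.tsv")
  }

  gs <- as_genome_seqs(inp$genome)
  sl <- report[report$stem_loop %in% TRUE, , drop = FALSE]
  if (nrow(sl)) {
    vrows <- list()
    for (r in seq_len(nrow(sl))) {
      hit <- sl[r, ]
      canonical <- to_dna(hit$seq)
      ctx_len <- max(nchar(inp$counts$sequence)) + 5L
      chr <- gs[[hit$chrom]]
      ctx <- if (hit$strand == "+") {
        substr(chr, hit$start + 1L, min(nchar(chr), hit$start + ctx_len))
      } else {
        revcomp(substr(chr, max(1L, hit$end - ctx_len + 1L), hit$end))
      }
      anchor <- substr(canonical, 1L, min(13L, nchar(canonical)))
      at_locus <- inp$counts[startsWith(inp$counts$sequence, anchor), ,
                             drop = FALSE]
      ok <- vapply(unique(at_locus$sequence), function(s)
        substr(s, 1, 1) == substr(ctx, 1, 1) && nchar(s) <= nchar(ctx),
        logical(1))
      at_locus <- at_locus[at_locus$sequence %in%
                             names(ok)[ok], , drop = FALSE]
      if (!nrow(at_locus)) next
      v <- call_3prime_variants(at_locus, ctx)
      v <- cbind(candidate = hit$seq, v)
      vrows[[length(vrows) + 1L]] <- v

      win <- extract_window(hit, inp$genome, config$discovery$flank)
      st <- fold_nussinov(win$seq, min_loop = config$discovery$min_loop,
                          allow_gu = config$discovery$allow_gu)
      p <- file.path(out, paste0("structure_", hit$chrom, "_",
                                 hit$start + 1L, ".db"))
      write_dotbracket(st, p, id = format_location(win$chrom, win$start,
                                                   win$end, win$strand))
      files[[basename(p)]] <- p
    }
    if (length(vrows)) emit(do.call(rbind, vrows), "variants.tsv")
  }

  manifest <- list(package = "sprfinder",
                   version = as.character(packageVersion("sprfinder")),
                   seed = config$seed,
                   simulate = config$simulate,
                   discovery = unclass(config$discovery),
                   sim = if (isTRUE(config$simulate)) unclass(config$sim),
                   numerator_library = config$numerator_library,
                   denominator_library = config$denominator_library,
                   files = names(files))
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files[["manifest.json"]] <- mp
  message("run complete: ", length(files), " artifacts in ", out)
  invisible(list(status = 0L, files = files, report = report))
}
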