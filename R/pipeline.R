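# Stage orchestration: a validated flat config drives the triage, annotate,
# map and profile stages in dependency order, writing TSV reports and a
# machine-readable run manifest (inputs, parameters, output checksums) so a
# rerun with the same config and inputs is byte-identical.

pipeline_defaults <- list(
  stages = "triage,annotate,map,profile",
  contigs = NULL, viral_hits = NULL, all_hits = NULL,
  genome = NULL, reads = NULL,
  out = NULL,
  evalue_max = 1e-20, min_length = 3000L,
  min_aa = 100L, strands = "+",
  min_read_len = 18L, max_read_len = 30L,
  analysis_length = 21L,
  hotspot_window = 21L, hotspot_quantile = 0.99, hotspot_merge_gap = 10L,
  seed = 1L, log_level = "info"
)

#' Validate a pipeline run configuration
#'
#' Unknown keys are rejected; missing keys take the pipeline defaults
#' (E-value cutoff `1e-20`, minimum contig length 3000 nt, sRNA length range
#' 18-30 nt, analysis length 21 nt).
#'
#' @param config Named list, or path to a flat YAML file of key-value pairs.
#' @return The completed config list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(pipeline_defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  out <- utils::modifyList(pipeline_defaults, config, keep.null = TRUE)
  stopifnot(out$evalue_max > 0, out$min_length >= 1,
            out$min_read_len <= out$max_read_len)
  out
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order over the configured
#' inputs: `triage` (contigs + two hit tables -> verdict and summary TSVs),
#' `annotate` (genome FASTA -> feature TSV + protein FASTA), `map` (sRNA
#' FASTQ/FASTA + genome -> mapping TSV) and `profile` (mappings -> signature
#' TSVs). Outputs are written once into `config$out`; a `manifest.json`
#' records inputs, parameter values and MD5 checksums of every output.
#'
#' @param config A [run_config()] list or YAML path.
#' @return Path of the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  if (is.null(cfg$out)) abort("config key 'out' (output directory) is required")
  stages <- strsplit(cfg$stages, ",")[[1]] |> trimws()
  known_stages <- c("triage", "annotate", "map", "profile")
  if (!all(stages %in% known_stages)) {
    abort(sprintf("unknown stage(s): %s",
                  paste(setdiff(stages, known_stages), collapse = ", ")))
  }
  needed <- c(
    if ("triage" %in% stages) c("contigs", "viral_hits", "all_hits"),
    if (any(c("annotate", "map") %in% stages)) "genome",
    if ("map" %in% stages) "reads"
  )
  for (key in needed) {
    if (is.null(cfg[[key]])) abort(sprintf("config key '%s' is required", key))
    if (!file.exists(cfg[[key]])) {
      abort(sprintf("input file for '%s' not found: %s", key, cfg[[key]]))
    }
  }
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  log_info <- function(...) {
    if (identical(cfg$log_level, "info")) message(sprintf(...))
  }
  outputs <- character()

  if ("triage" %in% stages) {
    log_info("stage triage: screening and classifying contigs")
    res <- triage_contigs(
      read_fasta(cfg$contigs),
      read_tabular_hits(cfg$viral_hits),
      read_tabular_hits(cfg$all_hits),
      triage_config(cfg$evalue_max, cfg$min_length)
    )
    write_report_tsv(res$verdicts, file.path(cfg$out, "triage_verdicts.tsv"))
    write_report_tsv(res$summary, file.path(cfg$out, "triage_summary.tsv"))
    outputs <- c(outputs, "triage_verdicts.tsv", "triage_summary.tsv")
  }

  genome <- NULL
  if (any(c("annotate", "map", "profile") %in% stages) && !is.null(cfg$genome)) {
    genome <- read_fasta(cfg$genome)[1, ]
  }

  if ("annotate" %in% stages) {
    log_info("stage annotate: predicting ORFs on %s", genome$id)
    strands <- strsplit(cfg$strands, ",")[[1]] |> trimws()
    orfs <- find_orfs(genome, cfg$min_aa, strands)
    ann <- segment_genome(nchar(genome$residues), orfs, genome$id)
    annotation_report(ann, file.path(cfg$out, "annotation.tsv"))
    write_fasta(
      tibble(id = sprintf("%s_ORF%d", genome$id, seq_len(nrow(orfs))),
             residues = orfs$protein),
      file.path(cfg$out, "proteins.faa")
    )
    outputs <- c(outputs, "annotation.tsv", "proteins.faa")
  }

  mappings <- NULL
  if ("map" %in% stages) {
    log_info("stage map: zero-mismatch mapping of reads onto %s", genome$id)
    reads <- if (grepl("\\.(fastq|fq)$", cfg$reads)) {
      read_fastq(cfg$reads)
    } else {
      read_fasta(cfg$reads)
    }
    collapsed <- reads |>
      extract_by_length(cfg$min_read_len, cfg$max_read_len) |>
      collapse_reads()
    idx <- build_index(genome, cfg$min_read_len, cfg$max_read_len)
    mappings <- map_exact(collapsed, idx)
    mapping_report(mappings, file.path(cfg$out, "mappings.tsv"))
    outputs <- c(outputs, "mappings.tsv")
  }

  if ("profile" %in% stages) {
    if (is.null(mappings)) abort("the profile stage requires the map stage")
    log_info("stage profile: vsiRNA signature statistics")
    prof <- vsirna_profile(
      mappings, nchar(genome$residues), cfg$analysis_length,
      cfg$hotspot_window, cfg$hotspot_quantile, cfg$hotspot_merge_gap
    )
    profile_reports(prof, cfg$out)
    write_report_tsv(glance(prof), file.path(cfg$out, "profile_summary.tsv"))
    outputs <- c(outputs, "size_strand.tsv", "five_prime_unique.tsv",
                 "five_prime_total.tsv", "positional.tsv", "hotspots.tsv",
                 "profile_summary.tsv")
  }

  manifest <- list(
    config = cfg[!vapply(cfg, is.null, logical(1))],
    inputs = cfg[needed],
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(cfg$out, outputs))), outputs
    ))
  )
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg$out)
}
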