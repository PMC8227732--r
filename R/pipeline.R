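#' Pipeline configuration
#'
#' Collects every path and stage parameter of the end-to-end run in one
#' validated list. Values may come from a YAML config file, with arguments
#' given here overriding file values. Unknown keys are rejected.
#'
#' @param alignments Path to the SAM/BAM file of spliced read alignments.
#' @param genome Path to the reference FASTA, or a
#'   [Biostrings::DNAStringSet].
#' @param annotation Path to the BED12/GTF annotation of the annotated
#'   transcripts (ignored when `model` is given).
#' @param model Optional `gene_model` object used directly instead of
#'   loading `annotation`.
#' @param model_config Optional list or YAML path with codon/domain fields
#'   for [load_gene_model()].
#' @param out_dir Output directory for the report bundle.
#' @param catalogue Optional reference catalogue (tibble with `name`,
#'   `chain`) for [match_catalogue()]; `NULL` skips matching.
#' @param w Snap/cluster window in nt.
#' @param min_support Minimum reads per junction or novel exon.
#' @param min_frac Minimum junction support as a fraction of mapped reads.
#' @param min_isoform_support Minimum reads per reported variant.
#' @param t Terminal window of the full-length test, nt.
#' @param boundary_tol Block-to-exon boundary tolerance, nt.
#' @param d_nmd NMD junction-distance threshold, nt.
#' @param min_orf_aa Minimum protein length for the ORF scan fallback.
#' @param seed Integer seed governing all randomness of a run.
#' @param file Optional YAML config file providing defaults.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alignments = NULL, genome = NULL,
                            annotation = NULL, model = NULL,
                            model_config = NULL, out_dir = NULL,
                            catalogue = NULL,
                            w = 12L, min_support = 5L, min_frac = 1e-4,
                            min_isoform_support = 3L, t = 30L,
                            boundary_tol = 12L, d_nmd = 50L,
                            min_orf_aa = 50L, seed = 1L, file = NULL) {
  cfg <- list(alignments = alignments, genome = genome,
              annotation = annotation, model = model,
              model_config = model_config, out_dir = out_dir,
              catalogue = catalogue, w = w, min_support = min_support,
              min_frac = min_frac,
              min_isoform_support = min_isoform_support, t = t,
              boundary_tol = boundary_tol, d_nmd = d_nmd,
              min_orf_aa = min_orf_aa, seed = seed)
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    unknown <- setdiff(names(from_file), names(cfg))
    if (length(unknown)) {
      abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
    }
    # file values fill in anything not explicitly passed in this call
    passed <- names(match.call())[-1]
    for (k in names(from_file)) {
      if (!k %in% passed) cfg[[k]] <- from_file[[k]]
    }
  }
  for (k in c("w", "min_support", "min_isoform_support", "t",
              "boundary_tol", "d_nmd", "min_orf_aa", "seed")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      abort(paste0("config field '", k, "' must be a non-negative number"))
    }
  }
  structure(cfg, class = "pipeline_config")
}

resolved_config <- function(cfg) {
  out <- unclass(cfg)
  out$model <- if (is.null(out$model)) NULL else "<in-memory gene_model>"
  out$genome <- if (is.character(out$genome)) out$genome else
    if (is.null(out$genome)) NULL else "<in-memory DNAStringSet>"
  out$catalogue <- if (is.null(out$catalogue)) NULL else
    "<in-memory catalogue>"
  out$model_config <- if (is.character(out$model_config))
    out$model_config else if (is.null(out$model_config)) NULL else
      "<in-memory list>"
  out[!vapply(out, is.null, logical(1))]
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full splice-variant discovery pipeline
#'
#' Alignment block extraction, junction snapping and tabulation, novel-exon
#' discovery, variant assembly, optional catalogue matching, and ORF/NMD/
#' domain annotation, with all tables, a summary, the resolved
#' configuration and a run log written to `cfg$out_dir`. Outputs are
#' deterministic for a fixed configuration. Per-stage failures are
#' propagated as errors naming the stage; an empty alignment file yields
#' empty tables and a warning, not an error.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `nanosplice_run` with elements `model`,
#'   `chains`, `junctions`, `novel_exons`, `variants`, `match` (or `NULL`),
#'   `orf`, `summary`, `config`, `out_dir`, invisibly written to disk as:
#'   `junctions.tsv`, `novel_exons.tsv`, `variants.tsv`/`.bed`/`.gtf`/`.fa`,
#'   `orf_report.tsv`, `domain_table.tsv`, `summary.tsv`, `config.yaml`,
#'   `run.log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$alignments)) abort("config field 'alignments' is required")
  if (is.null(cfg$genome)) abort("config field 'genome' is required")
  if (!file.exists(cfg$alignments)) {
    abort(paste0("alignments file not found: ", cfg$alignments))
  }
  out_dir <- cfg$out_dir %||% tempfile("nanosplice_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- stage("load-genome",
    if (is.character(cfg$genome)) {
      if (!file.exists(cfg$genome))
        abort(paste0("genome file not found: ", cfg$genome))
      Biostrings::readDNAStringSet(cfg$genome)
    } else cfg$genome)
  model <- stage("load-annotation",
    cfg$model %||% {
      if (is.null(cfg$annotation))
        abort("either 'model' or 'annotation' must be supplied")
      load_gene_model(cfg$annotation, config = cfg$model_config)
    })

  log_lines <- c(
    paste0("nanosplice ", as.character(utils::packageVersion("nanosplice"))),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("config hash: ", rlang::hash(resolved_config(cfg))),
    paste0("seed: ", cfg$seed))
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  chains <- stage("extract-chains", extract_read_chains(cfg$alignments))
  note("stage extract-chains: ", dplyr::n_distinct(chains$read_id),
       " reads, ", nrow(chains), " aligned blocks")
  chains <- stage("snap-junctions",
                  snap_junctions(chains, model, w = cfg$w, genome = genome))
  junctions <- stage("call-junctions",
                     tabulate_junctions(chains, model,
                                        min_support = cfg$min_support,
                                        min_frac = cfg$min_frac))
  note("stage call-junctions: ", nrow(junctions), " junctions")
  novel_exons <- stage("find-exons",
                       discover_novel_exons(chains, model,
                                            min_support = cfg$min_support,
                                            w = cfg$w))
  note("stage find-exons: ", nrow(novel_exons), " novel exons")
  variants <- stage("assemble",
                    assemble_variants(chains, junctions, novel_exons, model,
                                      t = cfg$t,
                                      boundary_tol = cfg$boundary_tol,
                                      min_support = cfg$min_isoform_support))
  note("stage assemble: ", nrow(variants), " variants")
  match <- if (!is.null(cfg$catalogue)) {
    stage("match-catalogue", match_catalogue(variants, cfg$catalogue))
  }
  orf <- stage("annotate-orf", {
    ext_model <- model_with_exons(model, novel_exons)
    if (nrow(variants)) {
      orf_report(variants, ext_model, genome,
                 min_orf_aa = cfg$min_orf_aa, d_nmd = cfg$d_nmd)
    } else orf_tbl_empty(model)
  })
  note("stage annotate-orf: ", nrow(orf), " predictions")

  stage("report", {
    readr::write_tsv(flatten_chain(junctions), file.path(out_dir, "junctions.tsv"))
    readr::write_tsv(novel_exons, file.path(out_dir, "novel_exons.tsv"))
    write_variant_bundle(variants, model, novel_exons, genome, out_dir)
    readr::write_tsv(
      select(orf, "name", origin = "start_origin", length = "protein_length",
             "ptc", nmd = "nmd_candidate", "coding_status"),
      file.path(out_dir, "orf_report.tsv"))
    readr::write_tsv(domain_table(orf, model),
                     file.path(out_dir, "domain_table.tsv"))
    if (nrow(orf)) {
      prot <- Biostrings::AAStringSet(setNames(orf$protein, orf$name))
      Biostrings::writeXStringSet(prot[Biostrings::width(prot) > 0L],
                                  file.path(out_dir, "proteins.fa"))
    }
    yaml::write_yaml(resolved_config(cfg), file.path(out_dir, "config.yaml"))
  })

  run <- structure(
    list(model = model, chains = chains, junctions = junctions,
         novel_exons = novel_exons, variants = variants, match = match,
         orf = orf, config = cfg, out_dir = out_dir),
    class = "nanosplice_run")
  run$summary <- summarize_run(run)
  readr::write_tsv(run$summary, file.path(out_dir, "summary.tsv"))
  note("summary: ", paste(run$summary$field, run$summary$value,
                          sep = "=", collapse = ", "))
  readr::write_lines(log_lines, file.path(out_dir, "run.log"))
  run
}

# a model extended with discovered novel exons (annotated = FALSE), so
# chains containing them can be spliced and length-checked
model_with_exons <- function(model, novel_exons) {
  if (is.null(novel_exons) || nrow(novel_exons) == 0L) return(model)
  extra <- novel_exons |>
    select("id", "start", "end") |>
    filter(!.data$id %in% model$exons$id) |>
    mutate(annotated = FALSE)
  model$exons <- arrange(bind_rows(model$exons, extra), .data$start)
  model
}

flatten_chain <- function(x) {
  if ("chain" %in% names(x)) {
    x$chain <- vapply(x$chain, chain_key, character(1))
  }
  x
}

orf_tbl_empty <- function(model) {
  out <- tibble(name = character(), start_origin = character(),
                start = integer(), stop = integer(),
                protein_length = integer(), has_orf = logical(),
                ptc = logical(), protein = character(),
                anchor_matching = character(), last_junction = integer(),
                stop_to_junction = integer(), nmd_candidate = logical(),
                coding_status = character())
  if (!is.null(model$domain_defs)) {
    for (d in model$domain_defs$name) out[[d]] <- logical()
  }
  class(out) <- c("orf_tbl", class(out))
  out
}

# Table 2-style layout: one row per variant, one logical column per domain
domain_table <- function(orf, model) {
  if (is.null(model$domain_defs)) return(tibble(name = orf$name))
  select(orf, "name", "coding_status",
         dplyr::any_of(model$domain_defs$name))
}

write_variant_bundle <- function(variants, model, novel_exons, genome,
                                 out_dir) {
  readr::write_tsv(flatten_chain(variants), file.path(out_dir, "variants.tsv"))
  if (nrow(variants) == 0L) return(invisible(NULL))
  ext_model <- model_with_exons(model, novel_exons)
  vmodel <- gene_model(
    gene = model$gene, contig = model$contig, strand = model$strand,
    exons = ext_model$exons,
    transcripts = setNames(variants$chain, variants$name),
    annotated_start_codon = model$annotated_start_codon,
    alt_start_codons = model$alt_start_codons,
    stop_codon = model$stop_codon, domain_defs = model$domain_defs)
  write_gene_model(vmodel, file.path(out_dir, "variants.bed"), "bed12")
  write_gene_model(vmodel, file.path(out_dir, "variants.gtf"), "gtf")
  cdna <- Biostrings::DNAStringSet(vapply(variants$chain, function(ch) {
    as.character(splice_cdna(ext_model, genome, ch))
  }, character(1)))
  names(cdna) <- variants$name
  Biostrings::writeXStringSet(cdna, file.path(out_dir, "variants.fa"))
  invisible(NULL)
}

#' Summarise a pipeline run
#'
#' Counts are recomputed from the in-memory result tables, so the summary is
#' always consistent with the written TSVs. Missing stages yield `NA`
#' values, not errors.
#'
#' @param run A `nanosplice_run` from [run_pipeline()].
#' @return Tibble with columns `field` and `value`: mapped read count,
#'   junction counts by status, novel-exon count, variant counts, coding and
#'   NMD-candidate counts.
#' @export
summarize_run <- function(run) {
  jn <- run$junctions
  va <- run$variants
  orf <- run$orf
  n <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)
  tibble(field = c("mapped_reads", "junctions_total", "junctions_annotated",
                   "junctions_novel_combination", "junctions_cryptic",
                   "novel_exons", "variants_total", "variants_annotated",
                   "novel_variants", "coding_variants", "nmd_candidates"),
         value = c(
           n(attr(jn, "n_reads")),
           n(nrow(jn)),
           n(sum(jn$status == "annotated")),
           n(sum(jn$status == "novel_combination")),
           n(sum(jn$status == "cryptic")),
           n(nrow(run$novel_exons)),
           n(nrow(va)),
           n(sum(va$category == "annotated")),
           n(sum(va$category != "annotated")),
           if (is.null(orf)) NA_integer_ else
             n(sum(orf$coding_status == "coding")),
           if (is.null(orf)) NA_integer_ else
             n(sum(orf$nmd_candidate))))
}

#' @export
print.nanosplice_run <- function(x, ...) {
  cat("<nanosplice_run> output:", x$out_dir, "\n")
  s <- x$summary
  cat(paste0("  ", format(s$field), " ", s$value, collapse = "\n"), "\n")
  invisible(x)
}

#' @describeIn summarize_run One-row wide summary of a run.
#' @param x A `nanosplice_run`.
#' @param ... Unused.
#' @method glance nanosplice_run
#' @export
glance.nanosplice_run <- function(x, ...) {
  s <- x$summary
  as_tibble(setNames(as.list(s$value), s$field))
}
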