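#' Gene model for a single-gene amplicon locus
#'
#' A `gene_model` bundles everything the pipeline needs to know about the
#' targeted gene: its exons, the annotated transcript exon chains, the
#' annotated and alternative translation initiation codons, the annotated stop
#' codon, and the protein-domain intervals on the annotated protein. All
#' genomic coordinates are 1-based and closed, the convention used by SAM,
#' GTF and the Bioconductor ranges infrastructure.
#'
#' @param gene Gene symbol.
#' @param contig Reference sequence name the gene lives on.
#' @param strand `"+"` or `"-"`.
#' @param exons Tibble with columns `id`, `start`, `end`, `annotated`
#'   (logical). Exon ids must be unique; `start <= end`.
#' @param transcripts Named list; each element is a character vector of exon
#'   ids in transcript order. These are the *annotated* transcripts.
#' @param annotated_start_codon List `list(exon =, offset =)` giving the exon
#'   id and 1-based offset (within that exon) of the first base of the
#'   annotated initiation ATG, or `NULL`.
#' @param alt_start_codons Named list of `list(exon =, offset =)` entries for
#'   designated alternative initiation codons (e.g. in exons 3 and 4).
#' @param stop_codon List `list(exon =, offset =)` locating the first base of
#'   the annotated termination codon, or `NULL`.
#' @param domain_defs Tibble with columns `name`, `aa_start`, `aa_end`:
#'   1-based inclusive amino-acid intervals of the protein domains on the
#'   annotated protein.
#'
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene, contig, strand = "+", exons, transcripts,
                       annotated_start_codon = NULL,
                       alt_start_codons = list(),
                       stop_codon = NULL,
                       domain_defs = NULL) {
  exons <- as_tibble(exons)
  stopifnot(all(c("id", "start", "end") %in% names(exons)))
  if (is.null(exons[["annotated"]])) exons$annotated <- TRUE
  if (anyDuplicated(exons$id)) {
    abort("exon ids must be unique within a gene model")
  }
  if (any(exons$start > exons$end)) {
    abort("exon start must not exceed exon end")
  }
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  if (length(transcripts) == 0L) {
    abort("a gene model needs at least one transcript")
  }
  missing <- setdiff(unlist(transcripts), exons$id)
  if (length(missing)) {
    abort(paste0("transcripts reference unknown exons: ",
                 paste(missing, collapse = ", ")))
  }
  model <- structure(
    list(gene = gene, contig = contig, strand = strand,
         exons = arrange(exons, .data$start),
         transcripts = transcripts,
         annotated_start_codon = annotated_start_codon,
         alt_start_codons = alt_start_codons,
         stop_codon = stop_codon,
         domain_defs = domain_defs),
    class = "gene_model")
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene, " (", x$contig, x$strand, ")\n", sep = "")
  cat("  exons:       ", nrow(x$exons), " (",
      sum(x$exons$annotated), " annotated)\n", sep = "")
  cat("  transcripts: ", length(x$transcripts), " [",
      paste(names(x$transcripts), collapse = ", "), "]\n", sep = "")
  if (!is.null(x$domain_defs)) {
    cat("  domains:     ", paste(x$domain_defs$name, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @describeIn gene_model Exon table of a gene model as a tibble.
#' @param x A `gene_model`.
#' @param ... Unused.
#' @method tidy gene_model
#' @export
tidy.gene_model <- function(x, ...) {
  mutate(x$exons, length = .data$end - .data$start + 1L,
         contig = x$contig, strand = x$strand)
}

exon_row <- function(model, id) {
  i <- match(id, model$exons$id)
  if (anyNA(i)) abort(paste0("unknown exon id: ", paste(id[is.na(i)], collapse = ", ")))
  model$exons[i, , drop = FALSE]
}

exon_length <- function(model, id) {
  e <- exon_row(model, id)
  e$end - e$start + 1L
}

#' Human-readable exon labels
#'
#' Alternative first exons are labelled by their length (e.g.
#' `"Exon 1 (120 bp)"`), other annotated exons as `"Exon 2"` ... and novel
#' exons as `"Exon N1"`.
#'
#' @param model A `gene_model`.
#' @param id Character vector of exon ids.
#' @return Character vector of display labels.
#' @export
exon_label <- function(model, id) {
  vapply(id, function(one) {
    if (grepl("^E1[a-z]$", one)) {
      sprintf("Exon 1 (%d bp)", exon_length(model, one))
    } else if (grepl("^E[0-9]+$", one)) {
      paste0("Exon ", sub("^E", "", one))
    } else {
      paste0("Exon ", one)
    }
  }, character(1), USE.NAMES = FALSE)
}

# (donor, acceptor) pairs used by the annotated transcripts, 1-based:
# donor = last base of the upstream exon, acceptor = first base of the
# downstream exon.
annotated_junctions <- function(model) {
  purrr::map_dfr(names(model$transcripts), function(tx) {
    chain <- model$transcripts[[tx]]
    if (length(chain) < 2L) return(tibble())
    up <- chain[-length(chain)]
    dn <- chain[-1L]
    tibble(transcript = tx,
           from = up, to = dn,
           donor = exon_row(model, up)$end,
           acceptor = exon_row(model, dn)$start)
  }) |> distinct(.data$from, .data$to, .data$donor, .data$acceptor)
}

# All annotated splice sites (from annotated exon boundaries that the
# annotated transcripts actually use).
annotated_sites <- function(model) {
  j <- annotated_junctions(model)
  list(donors = sort(unique(j$donor)), acceptors = sort(unique(j$acceptor)))
}

#' Spliced cDNA of an exon chain
#'
#' @param model A `gene_model`.
#' @param genome A [Biostrings::DNAStringSet] holding the reference contig.
#' @param chain Character vector of exon ids in transcript order.
#' @return A [Biostrings::DNAString] with the spliced sequence.
#' @export
splice_cdna <- function(model, genome, chain) {
  ref <- genome[[model$contig]]
  e <- exon_row(model, chain)
  parts <- Biostrings::DNAStringSet(ref, start = e$start, end = e$end)
  Biostrings::DNAString(paste(as.character(parts), collapse = ""))
}

chain_key <- function(chain) paste(chain, collapse = "-")

# ---------------------------------------------------------------------------
# Readers / writers for standard annotation formats
# ---------------------------------------------------------------------------

model_to_grangeslist <- function(model) {
  grl <- S4Vectors::List(lapply(model$transcripts, function(chain) {
    e <- exon_row(model, chain)
    GenomicRanges::GRanges(model$contig,
                           IRanges::IRanges(e$start, e$end),
                           strand = model$strand)
  }))
  methods::as(grl, "GRangesList")
}

#' Write a gene model to BED12 or GTF
#'
#' @param model A `gene_model`.
#' @param path Output file path.
#' @param format `"bed12"` or `"gtf"`; guessed from the file extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path, format = NULL) {
  format <- format %||% guess_annot_format(path)
  grl <- model_to_grangeslist(model)
  if (format == "bed12") {
    bed <- rtracklayer::asBED(grl)
    bed$name <- names(grl)
    rtracklayer::export(bed, path, format = "bed")
  } else if (format == "gtf") {
    gr <- unlist(grl)
    S4Vectors::mcols(gr)$type <- "exon"
    S4Vectors::mcols(gr)$gene_id <- model$gene
    S4Vectors::mcols(gr)$transcript_id <- rep(names(grl), lengths(grl))
    rtracklayer::export(gr, path, format = "gtf")
  } else {
    abort(paste0("unsupported annotation format: ", format))
  }
  invisible(path)
}

guess_annot_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         bed = "bed12", bed12 = "bed12",
         gtf = "gtf", gff = "gtf", gff2 = "gtf",
         abort(paste0("cannot guess annotation format from '", path, "'")))
}

#' Load a gene model from BED12 or GTF
#'
#' Transcript block structures are read with \pkg{rtracklayer}; the exon set
#' is the union of all transcript blocks, deduplicated by coordinates. When
#' the transcripts use more than one distinct first exon, the alternative
#' first exons are labelled `E1a`, `E1b`, ... in genomic order and the
#' remaining exons `E2`, `E3`, ... downstream; otherwise exons are numbered
#' `E1` onward.
#'
#' @param path Path to a BED12 or GTF file describing the transcripts of one
#'   gene on one contig and strand.
#' @param config Optional list (or path to a YAML file) supplying the fields
#'   annotation formats cannot carry: `gene`, `annotated_start_codon`,
#'   `alt_start_codons`, `stop_codon`, `domain_defs`.
#' @param format `"bed12"` or `"gtf"`; guessed from the extension by default.
#' @return A `gene_model`.
#' @export
load_gene_model <- function(path, config = NULL, format = NULL) {
  format <- format %||% guess_annot_format(path)
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()

  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0L) abort("annotation contains zero transcripts")
    blocks <- rtracklayer::blocks(gr)
    names(blocks) <- gr$name %||% paste0("tx", seq_along(gr))
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L) abort("annotation contains zero transcripts")
    blocks <- GenomicRanges::split(gr, gr$transcript_id)
  }
  blocks <- methods::as(blocks, "GRangesList")

  contigs <- unique(as.character(GenomicRanges::seqnames(unlist(blocks))))
  strands <- unique(as.character(GenomicRanges::strand(unlist(blocks))))
  if (length(contigs) != 1L) {
    abort("all transcripts must be on a single contig")
  }
  if (length(strands) != 1L) {
    abort("all transcripts must be on a single strand")
  }
  strand <- if (strands == "*") "+" else strands

  tx_coords <- lapply(blocks, function(g) {
    g <- GenomicRanges::sort(g)
    tibble(start = GenomicRanges::start(g), end = GenomicRanges::end(g))
  })
  uniq <- distinct(bind_rows(tx_coords)) |> arrange(.data$start, .data$end)
  uniq$id <- name_exons(uniq, tx_coords)

  coord_key <- function(d) paste(d$start, d$end)
  id_of <- setNames(uniq$id, coord_key(uniq))
  transcripts <- lapply(tx_coords, function(d) unname(id_of[coord_key(d)]))

  gene_model(gene = config$gene %||% "gene",
             contig = contigs, strand = strand,
             exons = mutate(uniq, annotated = TRUE),
             transcripts = transcripts,
             annotated_start_codon = config$annotated_start_codon,
             alt_start_codons = config$alt_start_codons %||% list(),
             stop_codon = config$stop_codon,
             domain_defs = if (!is.null(config$domain_defs))
               as_tibble(config$domain_defs) else NULL)
}

# Assign exon ids: alternative first exons (distinct across transcripts) get
# E1a/E1b/..., everything downstream E2, E3, ... in genomic order.
name_exons <- function(uniq, tx_coords) {
  firsts <- distinct(bind_rows(lapply(tx_coords, function(d) d[1, ])))
  is_first <- paste(uniq$start, uniq$end) %in% paste(firsts$start, firsts$end)
  ids <- character(nrow(uniq))
  if (sum(is_first) > 1L) {
    ids[is_first] <- paste0("E1", letters[seq_len(sum(is_first))])
    ids[!is_first] <- paste0("E", seq_len(sum(!is_first)) + 1L)
  } else {
    ids <- paste0("E", seq_len(nrow(uniq)))
  }
  ids
}

#' Write a genome (contig set) to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
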