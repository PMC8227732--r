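#' Simulation configuration for nanopore-like amplicon reads
#'
#' The error model is i.i.d. per base: each transcript base is deleted with
#' probability `p_del`, otherwise substituted with probability `p_sub`, and a
#' single random base is inserted before each base (except the first) with
#' probability `p_ins`. Defaults mimic R9.4.1-era nanopore read accuracy.
#' Optionally a read is truncated by removing a uniformly chosen terminal
#' fraction, which makes it fail the full-length filter downstream.
#'
#' @param mixture Tibble with columns `name`, `chain` (list of exon-id
#'   vectors) and `weight` (relative abundance, positive; normalised to 1).
#'   See [catalogue_mixture()].
#' @param n_reads Total number of reads to draw (multinomially across the
#'   mixture).
#' @param p_sub,p_ins,p_del Per-base error probabilities, each in `[0, 0.5)`.
#' @param truncation_rate Probability that a read loses a terminal fraction
#'   (uniform 5-50% of its length, random end).
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mixture, n_reads = 1000L, p_sub = 0.03, p_ins = 0.02,
                       p_del = 0.03, truncation_rate = 0, seed = 1L) {
  mixture <- as_tibble(mixture)
  stopifnot(all(c("name", "chain", "weight") %in% names(mixture)))
  if (nrow(mixture) == 0L) abort("mixture must contain at least one transcript")
  if (any(mixture$weight <= 0)) abort("mixture weights must be positive")
  for (p in c(p_sub, p_ins, p_del)) {
    if (p < 0 || p >= 0.5) abort("error probabilities must lie in [0, 0.5)")
  }
  if (truncation_rate < 0 || truncation_rate > 1) {
    abort("truncation_rate must lie in [0, 1]")
  }
  mixture$weight <- mixture$weight / sum(mixture$weight)
  structure(list(mixture = mixture, n_reads = as.integer(n_reads),
                 p_sub = p_sub, p_ins = p_ins, p_del = p_del,
                 truncation_rate = truncation_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Transcript mixtures over the reference catalogue
#'
#' `"uniform"` weights every catalogue transcript equally (handy for recovery
#' experiments that need a guaranteed read count per transcript).
#' `"table1"` emulates the abundance regime of the targeted amplicon run the
#' pipeline was built for: the main annotated transcript dominates, its
#' 5'-UTR sibling is rare, and the 25 novel variants span roughly 0.3%-5%
#' on a log scale.
#'
#' @param catalogue Tibble as returned by [elf3_catalogue()].
#' @param profile `"table1"` or `"uniform"`.
#' @param transcripts Optional subset of transcript names.
#' @return Mixture tibble for [sim_config()].
#' @export
catalogue_mixture <- function(catalogue = elf3_catalogue(),
                              profile = c("table1", "uniform"),
                              transcripts = NULL) {
  profile <- match.arg(profile)
  if (!is.null(transcripts)) {
    catalogue <- filter(catalogue, .data$name %in% transcripts)
  }
  if (nrow(catalogue) == 0L) abort("no transcripts selected")
  w <- if (profile == "uniform") {
    rep(1, nrow(catalogue))
  } else {
    novel <- catalogue$category != "annotated"
    out <- numeric(nrow(catalogue))
    out[!novel] <- c(0.62, 0.01)[seq_len(sum(!novel))]
    out[novel] <- exp(seq(log(0.0033), log(0.045), length.out = sum(novel)))
    out
  }
  tibble(name = catalogue$name, chain = catalogue$chain, weight = w / sum(w))
}

#' Simulate nanopore-like amplicon reads from a transcript mixture
#'
#' Draws reads multinomially from the mixture, applies the seeded i.i.d.
#' error model of [sim_config()] and keeps a per-read error log so that
#' [emit_oracle_alignments()] can later reconstruct the exact spliced
#' alignment of every read. Optionally writes the reads as FASTQ (constant
#' placeholder qualities) and the truth table as TSV.
#'
#' @param model A `gene_model` whose exon table covers every exon id used in
#'   the mixture chains.
#' @param genome [Biostrings::DNAStringSet] with the model's contig.
#' @param cfg A [sim_config()].
#' @param fastq,truth Optional output paths.
#' @return An object of class `amplicon_sim`: list with `reads` (tibble:
#'   `read_id`, `transcript`, `sequence`, per-read error-position list
#'   columns), `truth` (tibble: `read_id`, `transcript`, `chain`, `n_sub`,
#'   `n_ins`, `n_del`, `truncated`), `contig`, `contig_length`, `cfg`.
#' @export
simulate_reads <- function(model, genome, cfg, fastq = NULL, truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  missing <- setdiff(unique(unlist(cfg$mixture$chain)), model$exons$id)
  if (length(missing)) {
    abort(paste0("mixture chains reference exons absent from the model: ",
                 paste(missing, collapse = ", ")))
  }
  sim <- withr::with_seed(cfg$seed, simulate_reads_impl(model, genome, cfg))
  if (!is.null(fastq)) write_fastq(sim, fastq)
  if (!is.null(truth)) readr::write_tsv(sim$truth, truth)
  sim
}

simulate_reads_impl <- function(model, genome, cfg) {
  ref <- genome[[model$contig]]
  mix <- cfg$mixture

  # per-transcript templates: base vector + genomic position of every base
  templates <- lapply(mix$chain, function(chain) {
    e <- exon_row(model, chain)
    gpos <- unlist(lapply(seq_len(nrow(e)), function(k) e$start[k]:e$end[k]))
    bases <- strsplit(as.character(splice_cdna(model, genome, chain)), "")[[1]]
    list(bases = bases, gpos = as.integer(gpos))
  })

  counts <- as.integer(rmultinom(1L, cfg$n_reads, mix$weight))
  tx_of_read <- rep(seq_len(nrow(mix)), counts)
  n <- length(tx_of_read)
  read_id <- sprintf("read_%06d", seq_len(n))

  seqs <- character(n)
  sub_pos <- ins_pos <- del_pos <- vector("list", n)
  ins_base <- vector("list", n)
  win_from <- win_to <- integer(n)
  truncated <- logical(n)

  for (r in seq_len(n)) {
    tpl <- templates[[tx_of_read[r]]]
    L <- length(tpl$bases)
    from <- 1L; to <- L
    if (cfg$truncation_rate > 0 && runif(1L) < cfg$truncation_rate) {
      truncated[r] <- TRUE
      frac <- runif(1L, 0.05, 0.5)
      cut <- max(1L, as.integer(round(frac * L)))
      if (runif(1L) < 0.5) from <- 1L + cut else to <- L - cut
    }
    idx <- from:to
    m <- length(idx)
    del <- runif(m) < cfg$p_del
    sub <- !del & (runif(m) < cfg$p_sub)
    ins <- runif(m) < cfg$p_ins
    # keep alignment anchored: no leading/trailing deletions, no leading
    # insertion (they would be soft-clipped by an aligner anyway)
    keep <- which(!del)
    if (length(keep) == 0L) { del[] <- FALSE; keep <- seq_len(m) }
    lo <- keep[1L]; hi <- keep[length(keep)]
    sel <- lo:hi
    del <- del[sel]; sub <- sub[sel]; ins <- ins[sel]
    ins[1L] <- FALSE
    idx <- idx[sel]
    m <- length(idx)

    bases <- tpl$bases[idx]
    if (any(sub)) {
      bases[sub] <- vapply(bases[sub], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, character(1))
    }
    ib <- character(0)
    if (any(ins)) ib <- sample(DNA_BASES, sum(ins), replace = TRUE)
    insb <- rep(NA_character_, m)
    insb[ins] <- ib
    emit <- rbind(insb, ifelse(del, NA_character_, bases))
    seqs[r] <- paste(emit[!is.na(emit)], collapse = "")

    sub_pos[[r]] <- idx[sub]
    ins_pos[[r]] <- idx[ins]
    del_pos[[r]] <- idx[del]
    ins_base[[r]] <- ib
    win_from[r] <- idx[1L]; win_to[r] <- idx[m]
  }

  reads <- tibble(read_id = read_id,
                  transcript = mix$name[tx_of_read],
                  sequence = seqs,
                  sub_pos = sub_pos, ins_pos = ins_pos, del_pos = del_pos,
                  ins_base = ins_base,
                  win_from = win_from, win_to = win_to)
  truth <- tibble(read_id = read_id,
                  transcript = mix$name[tx_of_read],
                  chain = vapply(mix$chain[tx_of_read], chain_key, character(1)),
                  n_sub = lengths(sub_pos), n_ins = lengths(ins_pos),
                  n_del = lengths(del_pos), truncated = truncated)
  structure(list(reads = reads, truth = truth,
                 templates = templates, tx_of_read = tx_of_read,
                 contig = model$contig,
                 contig_length = length(ref), cfg = cfg),
            class = "amplicon_sim")
}

#' @export
print.amplicon_sim <- function(x, ...) {
  cat("<amplicon_sim>", nrow(x$reads), "reads from",
      nrow(x$cfg$mixture), "transcripts on", x$contig, "\n")
  invisible(x)
}

#' Write simulated reads as FASTQ
#'
#' @param sim An `amplicon_sim`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  dna <- Biostrings::DNAStringSet(setNames(sim$reads$sequence,
                                           sim$reads$read_id))
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(dna)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Emit exact spliced alignments for simulated reads
#'
#' Writes one primary SAM record per simulated read. Intron gaps (`N`
#' operations) are placed exactly at the source transcript's introns;
#' simulated substitutions stay matches (`M`) with altered bases, insertions
#' and deletions become `I`/`D` operations at their simulated positions. This
#' plays the role of a perfectly calibrated spliced aligner, so downstream
#' junction extraction can be validated against the simulation truth.
#'
#' @param sim An `amplicon_sim` from [simulate_reads()].
#' @param path Output SAM path.
#' @param model Optional `gene_model`; when supplied, its contig must match
#'   the simulation's.
#' @return `path`, invisibly.
#' @export
emit_oracle_alignments <- function(sim, path, model = NULL) {
  stopifnot(inherits(sim, "amplicon_sim"))
  if (!is.null(model) && !identical(model$contig, sim$contig)) {
    abort("model contig does not match the simulation")
  }
  n <- nrow(sim$reads)
  pos <- integer(n)
  cigar <- character(n)
  for (r in seq_len(n)) {
    tpl <- sim$templates[[sim$tx_of_read[r]]]
    idx <- sim$reads$win_from[r]:sim$reads$win_to[r]
    op <- rep("M", length(idx))
    op[match(sim$reads$del_pos[[r]], idx)] <- "D"
    insflag <- logical(length(idx))
    insflag[match(sim$reads$ins_pos[[r]], idx)] <- TRUE
    g <- tpl$gpos[idx]
    pos[r] <- g[1L]
    brk <- which(diff(g) > 1L)
    seg_start <- c(1L, brk + 1L)
    seg_end <- c(brk, length(idx))
    parts <- character(length(seg_start))
    for (s in seq_along(seg_start)) {
      ii <- seg_start[s]:seg_end[s]
      emit <- rbind(ifelse(insflag[ii], "I", NA_character_), op[ii])
      v <- emit[!is.na(emit)]
      rl <- rle(v)
      parts[s] <- paste0(rl$lengths, rl$values, collapse = "")
      if (s < length(seg_start)) {
        gap <- g[seg_end[s] + 1L] - g[seg_end[s]] - 1L
        parts[s] <- paste0(parts[s], gap, "N")
      }
    }
    cigar[r] <- paste(parts, collapse = "")
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", sim$contig, "\tLN:", sim$contig_length),
              "@PG\tID:nanosplice\tPN:nanosplice")
  rec <- paste(sim$reads$read_id, 0L, sim$contig, pos, 60L, cigar, "*", 0L,
               0L, sim$reads$sequence,
               strrep("I", nchar(sim$reads$sequence)), sep = "\t")
  readr::write_lines(c(header, rec), path)
  invisible(path)
}
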