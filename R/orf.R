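#' Predict the open reading frame of a variant cDNA
#'
#' Initiation codons are located by anchor subsequences (see
#' [extract_anchors()]) rather than genome coordinates, so prediction also
#' works on deposited cDNA sequences. The annotated initiation anchor takes
#' priority; if absent, the designated alternative anchors are tried in
#' order (exon 3, then exon 4); if none is present the cDNA is scanned for
#' the longest ATG-initiated ORF of at least `min_orf_aa` codons. Anchors
#' are matched exactly first, then with up to `max_mismatch` mismatches
#' (deposited cDNAs may carry sequencing variants). An anchor only counts
#' when an in-frame stop codon exists downstream. The prediction is flagged
#' as carrying a premature termination codon (PTC) when its stop codon lies
#' upstream of the annotated termination anchor.
#'
#' @param cdna A [Biostrings::DNAString] or character scalar: the spliced
#'   variant cDNA.
#' @param anchors Named character vector with elements `annotated`,
#'   optionally `alt_exon3`/`alt_exon4` (in priority order) and `stop`.
#' @param min_orf_aa Minimum protein length for the scan fallback.
#' @param max_mismatch Mismatch allowance of the anchor fallback pass.
#' @return One-row tibble: `start_origin` (`annotated_exon2`, `alt_exon3`,
#'   `alt_exon4`, `scan` or `none`), `start` (1-based first nt of the ATG),
#'   `stop` (last nt of the stop codon), `protein_length` (initiator Met
#'   counted, stop excluded), `has_orf`, `ptc`, `protein`,
#'   `anchor_matching`.
#' @export
predict_orf <- function(cdna, anchors, min_orf_aa = 50L, max_mismatch = 1L) {
  cdna <- Biostrings::DNAString(as.character(cdna))
  stopifnot("annotated" %in% names(anchors), "stop" %in% names(anchors))
  if (length(cdna) < max(nchar(anchors))) {
    abort("cDNA is shorter than the anchor subsequences")
  }

  loc <- function(anchor) {
    hit <- Biostrings::matchPattern(anchor, cdna)
    if (length(hit)) return(list(pos = Biostrings::start(hit)[1],
                                 matching = "exact"))
    if (max_mismatch > 0L) {
      hit <- Biostrings::matchPattern(anchor, cdna,
                                      max.mismatch = max_mismatch)
      if (length(hit)) return(list(pos = Biostrings::start(hit)[1],
                                   matching = "mismatch"))
    }
    NULL
  }

  first_stop <- function(from) {
    # index (in codons) of the first stop codon at or after `from`
    n_codon <- (length(cdna) - from + 1L) %/% 3L
    if (n_codon < 1L) return(NA_integer_)
    aa <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::subseq(cdna, from, from + 3L * n_codon - 1L))))
    k <- regexpr("*", aa, fixed = TRUE)
    if (k < 0L) NA_integer_ else as.integer(k)
  }

  stop_hit <- loc(anchors[["stop"]])
  ann_stop_pos <- if (is.null(stop_hit)) NA_integer_ else stop_hit$pos

  build <- function(origin, pos, matching) {
    k <- first_stop(pos)
    if (is.na(k)) return(NULL)
    stop_last <- pos + 3L * k - 1L
    prot <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::subseq(cdna, pos, stop_last - 3L))))
    tibble(start_origin = origin, start = pos, stop = stop_last,
           protein_length = k - 1L, has_orf = TRUE,
           ptc = if (is.na(ann_stop_pos)) NA else
             (stop_last - 2L) < ann_stop_pos,
           protein = prot, anchor_matching = matching)
  }

  origins <- c(annotated = "annotated_exon2",
               alt_exon3 = "alt_exon3", alt_exon4 = "alt_exon4")
  for (nm in intersect(names(origins), names(anchors))) {
    hit <- loc(anchors[[nm]])
    if (is.null(hit)) next
    out <- build(origins[[nm]], hit$pos, hit$matching)
    if (!is.null(out)) return(out)
  }

  # fallback: longest ATG-initiated ORF
  starts <- Biostrings::start(Biostrings::matchPattern("ATG", cdna))
  best <- NULL
  for (pos in starts) {
    k <- first_stop(pos)
    if (is.na(k) || k - 1L < min_orf_aa) next
    if (is.null(best) || (k - 1L) > best$protein_length) {
      best <- list(pos = pos, k = k, protein_length = k - 1L)
    }
  }
  if (!is.null(best)) return(build("scan", best$pos, "exact"))

  tibble(start_origin = "none", start = NA_integer_, stop = NA_integer_,
         protein_length = 0L, has_orf = FALSE, ptc = FALSE,
         protein = "", anchor_matching = NA_character_)
}

#' Flag a prediction as a nonsense-mediated decay candidate
#'
#' Applies the 50-nt rule: a PTC-bearing transcript is an NMD candidate when
#' its stop codon ends more than `d_nmd` nt upstream of the final exon-exon
#' junction (strict inequality); a stop in the final exon is never a
#' candidate.
#'
#' @param orf Prediction from [predict_orf()].
#' @param chain Exon-id chain of the variant.
#' @param model A `gene_model` providing exon lengths.
#' @param d_nmd Junction distance threshold in nt (default 50).
#' @return `orf` with columns `last_junction` (transcript coordinate of the
#'   last nt before the final exon), `stop_to_junction` and `nmd_candidate`.
#' @export
classify_nmd <- function(orf, chain, model, d_nmd = 50L) {
  lens <- exon_length(model, chain)
  last_junction <- if (length(chain) < 2L) NA_integer_ else
    as.integer(sum(lens) - lens[length(lens)])
  dist <- if (isTRUE(orf$has_orf) && !is.na(last_junction))
    last_junction - orf$stop else NA_integer_
  mutate(orf,
         last_junction = last_junction,
         stop_to_junction = as.integer(dist),
         nmd_candidate = isTRUE(orf$ptc) && !is.na(dist) && dist > d_nmd)
}

#' Protein-domain presence in a predicted isoform
#'
#' A domain is present iff its exact amino-acid subsequence on the reference
#' protein occurs as a contiguous substring of the predicted protein. Exon
#' skips, internal insertions and frameshifts that disrupt any part of a
#' domain therefore mark it absent without needing coordinates.
#'
#' @param protein Predicted protein sequence (character).
#' @param ref_protein Annotated reference protein sequence.
#' @param domain_defs Tibble with `name`, `aa_start`, `aa_end` on the
#'   reference protein.
#' @return Tibble with columns `domain` and `present`.
#' @export
domain_presence <- function(protein, ref_protein, domain_defs) {
  protein <- as.character(protein)
  tibble(domain = domain_defs$name,
         present = vapply(seq_len(nrow(domain_defs)), function(i) {
           if (!nzchar(protein)) return(FALSE)
           sub <- substr(ref_protein, domain_defs$aa_start[i],
                         domain_defs$aa_end[i])
           grepl(sub, protein, fixed = TRUE)
         }, logical(1)))
}

#' ORF, NMD and domain report over a set of variant chains
#'
#' Splices each variant cDNA from the genome, predicts its ORF, applies the
#' NMD rule and computes domain presence against the annotated protein
#' (derived from the first annotated transcript unless supplied).
#'
#' @param variants Tibble with columns `name` and `chain` (list of exon-id
#'   vectors): an assembled `variant_tbl` or [elf3_catalogue()].
#' @param model A `gene_model` with codon annotations and domain
#'   definitions.
#' @param genome Matching [Biostrings::DNAStringSet].
#' @param anchors Anchor set (default [extract_anchors()] on the model).
#' @param ref_protein Reference protein (default: translated from the first
#'   annotated transcript).
#' @param min_orf_aa,max_mismatch Passed to [predict_orf()].
#' @param d_nmd Passed to [classify_nmd()].
#' @return Tibble of class `orf_tbl`: one row per variant with ORF fields,
#'   `nmd_candidate`, `coding_status` (`coding`, `noncoding_ptc`,
#'   `noncoding_no_orf`) and one logical column per domain.
#' @export
orf_report <- function(variants, model, genome,
                       anchors = NULL, ref_protein = NULL,
                       min_orf_aa = 50L, max_mismatch = 1L, d_nmd = 50L) {
  anchors <- anchors %||% extract_anchors(model, genome)
  if (is.null(ref_protein)) {
    ref_cdna <- splice_cdna(model, genome, model$transcripts[[1]])
    ref_protein <- predict_orf(ref_cdna, anchors,
                               min_orf_aa = min_orf_aa,
                               max_mismatch = max_mismatch)$protein
  }
  rows <- purrr::map2_dfr(variants$name, variants$chain, function(nm, ch) {
    cdna <- splice_cdna(model, genome, ch)
    orf <- predict_orf(cdna, anchors, min_orf_aa = min_orf_aa,
                       max_mismatch = max_mismatch)
    orf <- classify_nmd(orf, ch, model, d_nmd = d_nmd)
    dom <- domain_presence(orf$protein, ref_protein, model$domain_defs)
    wide <- setNames(as.list(dom$present), dom$domain)
    dplyr::bind_cols(tibble(name = nm), orf, as_tibble(wide))
  })
  out <- mutate(rows, coding_status = dplyr::case_when(
    .data$has_orf & !isTRUE_vec(.data$ptc) ~ "coding",
    .data$has_orf ~ "noncoding_ptc",
    TRUE ~ "noncoding_no_orf"), .after = "nmd_candidate")
  class(out) <- c("orf_tbl", class(out))
  attr(out, "ref_protein") <- ref_protein
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' ORF predictions for cDNA sequences in a FASTA file
#'
#' Entry point for accession-based checks: runs [predict_orf()] on each
#' sequence of a cDNA FASTA (e.g. downloaded deposited variant sequences).
#' Junction positions are unknown for plain cDNAs, so only PTC status (via
#' the termination anchor), not NMD candidacy, is reported.
#'
#' @param path FASTA file of cDNA sequences.
#' @param anchors Anchor set (see [extract_anchors()]).
#' @param ... Passed to [predict_orf()].
#' @return Tibble with one prediction row per sequence.
#' @export
orf_from_fasta <- function(path, anchors, ...) {
  seqs <- Biostrings::readDNAStringSet(path)
  purrr::map_dfr(seq_along(seqs), function(i) {
    dplyr::bind_cols(tibble(name = names(seqs)[i]),
                     predict_orf(seqs[[i]], anchors, ...))
  })
}
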