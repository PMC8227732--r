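#' Configuration of the built-in ELF3-like gene fixture
#'
#' The fixture is a fully synthetic single-gene locus engineered to have the
#' same architecture as the human ELF3 amplicon targeted by the pipeline: two
#' alternative first exons of 120 and 234 bp that differ only in the 5' UTR,
#' eight further annotated exons, a 156-nt cryptic exon locus (N1) hidden in
#' the intron between exons 7 and 8 and a 92-nt one (N2) between exons 8 and
#' 9, GT..AG introns throughout, an annotated initiation codon in exon 2,
#' designated alternative in-frame ATGs in exons 3 and 4, and a coding
#' sequence laid out so that the five protein domains map onto exons as
#' PNT (exons 2-3), TAD (exon 4), SAR (exon 6), AT_hook (exon 7) and
#' ETS (exons 8-9).
#'
#' Exon lengths other than the two first exons and the two cryptic exons are
#' not dictated by the gene's published architecture; the defaults are
#' arbitrary but frame-consistent. Overrides must keep the frame engineering
#' intact:
#' * the exon-2 coding part and exons 3-7 are multiples of 3 (so individual
#'   cassette-exon skips preserve the reading frame),
#' * exon 8 is *not* a multiple of 3 and `E8 + N2` is (so skipping exon 8 and
#'   inserting N2 shift translation into one common alternative frame in
#'   exon 9, for which a single downstream stop codon is planted),
#' * N1 is a multiple of 3 and carries an in-frame premature stop.
#'
#' @param exon_lengths Named integer vector of exon lengths
#'   (`E1a`, `E1b`, `E2`..`E9`).
#' @param utr5_e2 Length of the untranslated 5' part of exon 2.
#' @param cds_e9 Length of the coding part of exon 9 (annotated stop codon
#'   included).
#' @param n1_length,n2_length Cryptic exon lengths.
#' @param intron_length Length of each intron segment.
#' @param pad Plain sequence padding either side of the gene.
#' @param alt_start_aa Amino-acid positions (on the annotated protein) of the
#'   designated alternative initiation codons in exons 3 and 4. The exon-4
#'   codon must fall inside the TAD interval so that initiation there yields
#'   a protein lacking an intact TAD.
#' @param domain_defs Tibble of domain amino-acid intervals (1-based,
#'   inclusive) on the annotated protein.
#' @param anchor_length Length of the initiation/termination anchor
#'   subsequences extracted for ORF calling.
#' @return A list of class `elf3_fixture_config`.
#' @export
elf3_fixture_config <- function(
    exon_lengths = c(E1a = 120L, E1b = 234L, E2 = 150L, E3 = 150L, E4 = 180L,
                     E5 = 150L, E6 = 120L, E7 = 120L, E8 = 130L, E9 = 306L),
    utr5_e2 = 90L,
    cds_e9 = 206L,
    n1_length = 156L,
    n2_length = 92L,
    intron_length = 300L,
    pad = 100L,
    alt_start_aa = c(alt_exon3 = 50L, alt_exon4 = 100L),
    domain_defs = tibble(
      name = c("PNT", "TAD", "SAR", "AT_hook", "ETS"),
      aa_start = c(10L, 75L, 185L, 225L, 265L),
      aa_end = c(40L, 125L, 215L, 255L, 350L)),
    anchor_length = 15L) {
  cfg <- list(exon_lengths = exon_lengths, utr5_e2 = utr5_e2,
              cds_e9 = cds_e9, n1_length = n1_length, n2_length = n2_length,
              intron_length = intron_length, pad = pad,
              alt_start_aa = alt_start_aa, domain_defs = domain_defs,
              anchor_length = anchor_length)
  class(cfg) <- "elf3_fixture_config"
  validate_fixture_config(cfg)
  cfg
}

validate_fixture_config <- function(cfg) {
  len <- cfg$exon_lengths
  need <- c("E1a", "E1b", "E2", paste0("E", 3:9))
  if (!all(need %in% names(len))) {
    abort("exon_lengths must name E1a, E1b and E2..E9")
  }
  cds <- fixture_cds_lengths(cfg)
  bad <- function(msg) abort(paste0("fixture frame engineering violated: ", msg))
  if (cds[["E2"]] <= 0L || cds[["E2"]] %% 3L != 0L) {
    bad("exon 2 coding part must be a positive multiple of 3")
  }
  for (e in paste0("E", 3:7)) {
    if (len[[e]] %% 3L != 0L) bad(paste0(e, " length must be a multiple of 3"))
  }
  if (len[["E8"]] %% 3L == 0L) bad("E8 length must not be a multiple of 3")
  if ((len[["E8"]] + cfg$n2_length) %% 3L != 0L) {
    bad("E8 + N2 must be a multiple of 3")
  }
  if (cfg$n1_length %% 3L != 0L || cfg$n1_length < 12L) {
    bad("N1 length must be a multiple of 3 and at least 12")
  }
  if (sum(cds) %% 3L != 0L) bad("total CDS length must be a multiple of 3")
  if (len[["E9"]] < cfg$cds_e9 + 10L) {
    bad("E9 must extend at least 10 nt beyond its coding part")
  }
  aa <- fixture_aa_map(cfg)
  a3 <- cfg$alt_start_aa[["alt_exon3"]]
  a4 <- cfg$alt_start_aa[["alt_exon4"]]
  if (a3 < aa$first[["E3"]] || a3 > aa$last_full[["E3"]]) {
    bad("alternative start for exon 3 must lie within exon 3 codons")
  }
  if (a4 < aa$first[["E4"]] || a4 > aa$last_full[["E4"]]) {
    bad("alternative start for exon 4 must lie within exon 4 codons")
  }
  dd <- cfg$domain_defs
  if (!setequal(dd$name, c("PNT", "TAD", "SAR", "AT_hook", "ETS"))) {
    abort("domain_defs must define PNT, TAD, SAR, AT_hook and ETS")
  }
  n_aa <- sum(cds) / 3L - 1L
  if (any(dd$aa_start < 1L) || any(dd$aa_end > n_aa) ||
      any(dd$aa_start > dd$aa_end)) {
    abort("domain intervals must satisfy 1 <= aa_start <= aa_end <= protein length")
  }
  get <- function(nm, fld) dd[[fld]][dd$name == nm]
  if (get("PNT", "aa_start") > aa$last_full[["E2"]] ||
      get("PNT", "aa_end") < aa$first[["E3"]] ||
      get("PNT", "aa_end") > aa$last_full[["E3"]]) {
    bad("PNT must span the exon 2 / exon 3 junction")
  }
  if (get("TAD", "aa_start") < aa$first[["E4"]] ||
      get("TAD", "aa_end") > aa$last_full[["E4"]]) bad("TAD must lie inside exon 4")
  if (a4 <= get("TAD", "aa_start")) {
    bad("exon 4 alternative start must fall after the start of TAD")
  }
  if (get("SAR", "aa_start") < aa$first[["E6"]] ||
      get("SAR", "aa_end") > aa$last_full[["E6"]]) bad("SAR must lie inside exon 6")
  if (get("AT_hook", "aa_start") < aa$first[["E7"]] ||
      get("AT_hook", "aa_end") > aa$last_full[["E7"]]) {
    bad("AT_hook must lie inside exon 7")
  }
  if (get("ETS", "aa_start") < aa$first[["E8"]] ||
      get("ETS", "aa_start") > aa$last_full[["E8"]] ||
      get("ETS", "aa_end") < aa$first[["E9"]]) {
    bad("ETS must span the exon 8 / exon 9 junction")
  }
  invisible(cfg)
}

# Coding-sequence length contributed by each CDS exon.
fixture_cds_lengths <- function(cfg) {
  len <- cfg$exon_lengths
  c(E2 = unname(len[["E2"]] - cfg$utr5_e2),
    E3 = unname(len[["E3"]]), E4 = unname(len[["E4"]]),
    E5 = unname(len[["E5"]]), E6 = unname(len[["E6"]]),
    E7 = unname(len[["E7"]]), E8 = unname(len[["E8"]]),
    E9 = unname(cfg$cds_e9))
}

# First and last *fully contained* codon (amino-acid index) per CDS exon.
fixture_aa_map <- function(cfg) {
  cds <- fixture_cds_lengths(cfg)
  offs <- cumsum(c(0L, unname(cds)))[seq_along(cds)]
  names(offs) <- names(cds)
  first <- floor(offs / 3L) + 1L + as.integer(offs %% 3L != 0L)
  last_full <- floor((offs + cds) / 3L)
  # the final codon of E9 is the stop codon, not an amino acid
  last_full[["E9"]] <- last_full[["E9"]] - 1L
  list(cds_offset = offs, first = first, last_full = last_full)
}

# ---------------------------------------------------------------------------
# Constrained nucleotide sampling
# ---------------------------------------------------------------------------

# Sample a sequence of length n in which
#  * positions named in `forced` take the given base,
#  * no "ATG" occurs at any offset (planted anchors are forced, hence exempt),
#  * no stop codon (TAA/TAG/TGA) starts at any position in `stop_starts`.
# Sampling is left-to-right; at most two bases are ever excluded at once, so
# the sampler cannot dead-end.
sample_constrained <- function(n, forced = integer(0), forced_base = character(0),
                               stop_starts = integer(0), no_atg = TRUE) {
  s <- character(n)
  s[forced] <- forced_base
  is_stop_start <- logical(n)
  is_stop_start[stop_starts] <- TRUE
  for (i in seq_len(n)) {
    if (nzchar(s[i])) next
    cand <- DNA_BASES
    if (i >= 3L) {
      w2 <- paste0(s[i - 2L], s[i - 1L])
      if (no_atg && w2 == "AT") cand <- setdiff(cand, "G")
      if (is_stop_start[i - 2L]) {
        if (w2 == "TA") cand <- setdiff(cand, c("A", "G"))
        if (w2 == "TG") cand <- setdiff(cand, "A")
      }
    }
    s[i] <- sample(cand, 1L)
  }
  paste(s, collapse = "")
}

# Codon-start positions (1-based, fully contained) in a segment of length n,
# given the number of CDS nucleotides already consumed upstream.
codon_starts_in <- function(n, consumed_upstream) {
  p0 <- ((1L - consumed_upstream) %% 3L + 3L) %% 3L
  if (p0 == 0L) p0 <- 3L
  starts <- seq.int(p0, n, by = 3L)
  starts[starts + 2L <= n]
}

# ---------------------------------------------------------------------------
# Fixture construction
# ---------------------------------------------------------------------------

#' Build the synthetic ELF3-like gene fixture
#'
#' Generates a synthetic contig and matching [gene_model()] under the frame
#' engineering described in [elf3_fixture_config()]. The same seed always
#' yields a byte-identical genome. The returned model contains the ten
#' annotated exons (annotated = TRUE) plus the two cryptic exon loci N1 and
#' N2 (annotated = FALSE) so that catalogue chains can be spliced directly;
#' only the two annotated transcripts v.1 and v.2 are registered as
#' transcripts.
#'
#' @param seed Integer seed controlling all random sequence content.
#' @param config An [elf3_fixture_config()].
#' @return A list of class `elf3_fixture` with elements `model`
#'   ([gene_model()]), `genome` ([Biostrings::DNAStringSet]), `anchors`
#'   (named character: `annotated`, `alt_exon3`, `alt_exon4`, `stop`),
#'   `protein` (annotated protein sequence), `config` and `layout` (segment
#'   coordinate tibble).
#' @export
elf3_fixture <- function(seed = 1L, config = elf3_fixture_config()) {
  validate_fixture_config(config)
  withr::with_seed(seed, build_elf3_fixture(config))
}

build_elf3_fixture <- function(cfg) {
  len <- cfg$exon_lengths
  il <- cfg$intron_length
  cds <- fixture_cds_lengths(cfg)
  aa <- fixture_aa_map(cfg)

  seg_names <- c("pad1", "E1a", "I1a", "E1b", "I1b", "E2", "I2", "E3", "I3",
                 "E4", "I4", "E5", "I5", "E6", "I6", "E7", "I7a", "N1", "I7b",
                 "E8", "I8a", "N2", "I8b", "E9", "pad2")
  seg_len <- c(cfg$pad, len[["E1a"]], il, len[["E1b"]], il, len[["E2"]], il,
               len[["E3"]], il, len[["E4"]], il, len[["E5"]], il, len[["E6"]],
               il, len[["E7"]], il, cfg$n1_length, il, len[["E8"]], il,
               cfg$n2_length, il, len[["E9"]], cfg$pad)
  ends <- cumsum(seg_len)
  layout <- tibble(segment = seg_names,
                   start = c(1L, head(ends, -1L) + 1L),
                   end = as.integer(ends),
                   length = as.integer(seg_len))

  is_intron <- grepl("^I", seg_names)
  is_exonic <- grepl("^(E|N)", seg_names)

  # local positions of the planted features
  start_local <- cfg$utr5_e2 + 1L                      # ATG in E2
  alt3_aa <- cfg$alt_start_aa[["alt_exon3"]]
  alt4_aa <- cfg$alt_start_aa[["alt_exon4"]]
  alt3_local <- 3L * alt3_aa - 2L - aa$cds_offset[["E3"]]
  alt4_local <- 3L * alt4_aa - 2L - aa$cds_offset[["E4"]]
  stop_local <- cfg$cds_e9 - 2L                        # annotated TAA in E9
  # alternative-frame stop for exon-8-skip / N2-insertion variants: first
  # codon of the frame entered at the E9 boundary that clears the coding part
  alt_stop_local <- cfg$cds_e9 + 1L
  while ((alt_stop_local - 1L) %% 3L != 0L) alt_stop_local <- alt_stop_local + 1L
  n1_stop_local <- 7L                                  # premature TAA in N1

  seqs <- vector("list", length(seg_names))
  names(seqs) <- seg_names
  for (k in seq_along(seg_names)) {
    nm <- seg_names[k]
    n <- seg_len[k]
    forced <- integer(0); forced_base <- character(0)
    stop_starts <- integer(0)
    add <- function(pos, base) {
      forced <<- c(forced, pos)
      forced_base <<- c(forced_base, base)
    }
    if (is_intron[k]) {
      add(1:2, c("G", "T")); add((n - 1L):n, c("A", "G"))
    } else if (is_exonic[k]) {
      # exon termini are fixed to C so that neither an ATG nor a stop codon
      # can ever span a splice junction
      add(1L, "C"); add(n, "C")
    }
    if (nm == "E2") {
      add(start_local:(start_local + 2L), c("A", "T", "G"))
      stop_starts <- codon_starts_in(n, -cfg$utr5_e2)
      stop_starts <- stop_starts[stop_starts > cfg$utr5_e2]
    } else if (nm %in% paste0("E", 3:8)) {
      if (nm == "E3") add(alt3_local:(alt3_local + 2L), c("A", "T", "G"))
      if (nm == "E4") add(alt4_local:(alt4_local + 2L), c("A", "T", "G"))
      stop_starts <- codon_starts_in(n, aa$cds_offset[[nm]])
    } else if (nm == "E9") {
      ann <- codon_starts_in(n, aa$cds_offset[["E9"]])
      ann <- ann[ann < stop_local]
      alt <- codon_starts_in(n, 0L)      # frame entered at the exon boundary
      alt <- alt[alt < alt_stop_local]
      stop_starts <- sort(c(ann, alt))
      add(stop_local:(stop_local + 2L), c("T", "A", "A"))
      add(alt_stop_local:(alt_stop_local + 2L), c("T", "A", "A"))
    } else if (nm == "N1") {
      frame <- codon_starts_in(n, 0L)    # entered in-frame after exon 7
      stop_starts <- frame[frame < n1_stop_local]
      add(n1_stop_local:(n1_stop_local + 2L), c("T", "A", "A"))
    } else if (nm == "N2") {
      # entered mid-codon after exon 8; translation of the N2-bearing variant
      # must pass through without terminating
      stop_starts <- codon_starts_in(n, cds[["E8"]] %% 3L)
    }
    seqs[[nm]] <- sample_constrained(n, forced, forced_base, stop_starts)
  }

  genome_seq <- paste(unlist(seqs[seg_names]), collapse = "")
  contig <- "synthetic_ELF3_locus"
  genome <- Biostrings::DNAStringSet(setNames(genome_seq, contig))

  seg <- function(nm) layout[layout$segment == nm, ]
  exon_ids <- c("E1a", "E1b", paste0("E", 2:9), "N1", "N2")
  exons <- purrr::map_dfr(exon_ids, function(id) {
    s <- seg(id)
    tibble(id = id, start = s$start, end = s$end,
           annotated = !id %in% c("N1", "N2"))
  })

  chain_ann <- c("E2", paste0("E", 3:9))
  model <- gene_model(
    gene = "ELF3like", contig = contig, strand = "+",
    exons = exons,
    transcripts = list(v.1 = c("E1a", chain_ann), v.2 = c("E1b", chain_ann)),
    annotated_start_codon = list(exon = "E2", offset = start_local),
    alt_start_codons = list(
      alt_exon3 = list(exon = "E3", offset = alt3_local),
      alt_exon4 = list(exon = "E4", offset = alt4_local)),
    stop_codon = list(exon = "E9", offset = stop_local),
    domain_defs = cfg$domain_defs)

  anchors <- extract_anchors(model, genome, cfg$anchor_length)

  # --- build-time integrity checks -------------------------------------
  n_atg <- Biostrings::countPattern("ATG", genome[[contig]])
  stopifnot(n_atg == 3L)
  for (a in anchors) {
    stopifnot(Biostrings::countPattern(a, genome[[contig]]) == 1L)
  }
  cdna1 <- splice_cdna(model, genome, model$transcripts$v.1)
  cds_seq <- Biostrings::subseq(
    cdna1, len[["E1a"]] + cfg$utr5_e2 + 1L,
    len[["E1a"]] + cfg$utr5_e2 + sum(cds))
  prot_with_stop <- as.character(suppressWarnings(
    Biostrings::translate(cds_seq)))
  n_aa <- sum(cds) / 3L - 1L
  stopifnot(substr(prot_with_stop, n_aa + 1L, n_aa + 1L) == "*",
            !grepl("\\*", substr(prot_with_stop, 1L, n_aa)))
  protein <- substr(prot_with_stop, 1L, n_aa)
  met_at <- as.integer(gregexpr("M", protein, fixed = TRUE)[[1]])
  stopifnot(identical(met_at, sort(c(1L, alt3_aa, alt4_aa))))
  assert_gt_ag_introns(model, genome)

  structure(list(model = model, genome = genome, anchors = anchors,
                 protein = protein, config = cfg, layout = layout),
            class = "elf3_fixture")
}

#' @export
print.elf3_fixture <- function(x, ...) {
  cat("<elf3_fixture> contig of", Biostrings::width(x$genome)[1], "nt,",
      nrow(x$model$exons), "exon loci,", nchar(x$protein), "aa protein\n")
  invisible(x)
}

#' Initiation and termination anchor subsequences
#'
#' Extracts the short genomic subsequences starting at the annotated
#' initiation codon, the designated alternative initiation codons and the
#' annotated termination codon. ORF prediction locates these anchors in a
#' variant cDNA by (mismatch-tolerant) substring search, so it also works on
#' deposited cDNA sequences that carry no genome coordinates.
#'
#' @param model A `gene_model` with codon annotations.
#' @param genome Matching [Biostrings::DNAStringSet].
#' @param anchor_length Anchor length in nt.
#' @return Named character vector (`annotated`, any alternative starts,
#'   `stop`).
#' @export
extract_anchors <- function(model, genome, anchor_length = 15L) {
  ref <- genome[[model$contig]]
  take <- function(codon) {
    e <- exon_row(model, codon$exon)
    from <- e$start + codon$offset - 1L
    as.character(Biostrings::subseq(ref, from, from + anchor_length - 1L))
  }
  out <- c(annotated = take(model$annotated_start_codon))
  for (nm in names(model$alt_start_codons)) {
    out[[nm]] <- take(model$alt_start_codons[[nm]])
  }
  out[["stop"]] <- take(model$stop_codon)
  out
}

# every intron used by any pair of consecutive exon loci in the fixture
# catalogue starts with GT and ends with AG
assert_gt_ag_introns <- function(model, genome) {
  ref <- genome[[model$contig]]
  e <- model$exons
  donors <- e$end[e$id != "E9"]
  acceptors <- e$start[!e$id %in% c("E1a", "E1b")]
  for (d in donors) {
    stopifnot(as.character(Biostrings::subseq(ref, d + 1L, d + 2L)) == "GT")
  }
  for (a in acceptors) {
    stopifnot(as.character(Biostrings::subseq(ref, a - 2L, a - 1L)) == "AG")
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Reference transcript catalogue
# ---------------------------------------------------------------------------

#' Reference catalogue of transcript variant exon chains
#'
#' The two annotated transcripts (v.1, v.2) and the 25 novel transcript
#' variants (v.3-v.27) as ordered exon-id chains on the fixture's exon
#' naming. Chains marked `source = "text"` are fully determined by the
#' published variant descriptions; chains marked `source = "inferred"` are
#' synthetic reconstructions completed under the published constraints (the
#' novel-junction list, the per-variant domain table, and the coding /
#' non-coding partition) and stand in for structures available only as
#' figures and database accessions.
#'
#' @return Tibble with columns `name`, `chain` (list of exon-id vectors),
#'   `category`, `source`.
#' @export
elf3_catalogue <- function() {
  ch <- function(...) c(...)
  all29 <- c("E2", paste0("E", 3:9))
  def <- list(
    v.1 = list(ch("E1a", all29), "annotated", "text"),
    v.2 = list(ch("E1b", all29), "annotated", "text"),
    v.3 = list(ch("E1a", "E2", "E3", "E4", "E5", "E7", "E8", "E9"),
               "novel_known_exons", "text"),
    v.4 = list(ch("E1a", "E2", "E3", "E5", "E6", "E7", "E8", "E9"),
               "novel_known_exons", "text"),
    v.5 = list(ch("E1a", "E2", "E4", "E5", "E6", "E7", "E8", "E9"),
               "novel_known_exons", "text"),
    v.6 = list(ch("E1a", "E2", "E3", "E4", "E5", "E6", "E7", "E9"),
               "novel_known_exons", "text"),
    v.7 = list(ch("E1b", "E2", "E3", "E5", "E6", "E7", "E8", "E9"),
               "novel_known_exons", "text"),
    v.8 = list(ch("E1a", "E2", "E3", "E5", "E7", "E8", "E9"),
               "novel_known_exons", "text"),
    v.9 = list(ch("E1a", "E2", "E3", "E5", "E6", "E7", "E9"),
               "novel_known_exons", "text"),
    v.10 = list(ch("E1a", "E2", "E3", "E4", "E8", "E9"),
                "novel_known_exons", "inferred"),
    v.11 = list(ch("E1a", "E2", "E8", "E9"), "novel_known_exons", "inferred"),
    v.12 = list(ch("E1a", "E2", "E9"), "novel_known_exons", "inferred"),
    v.13 = list(ch("E1b", "E2", "E9"), "novel_known_exons", "inferred"),
    v.14 = list(ch("E1a", "E2", "E3", "E4", "E5", "E6", "E7", "E8", "N2", "E9"),
                "novel_with_cryptic_exon", "text"),
    v.15 = list(ch("E1a", "E2", "E3", "E4", "E5", "E6", "E7", "N1", "E8", "E9"),
                "novel_with_cryptic_exon", "text"),
    v.16 = list(ch("E1a", "E3", "E4", "E5", "E6", "E7", "E8", "E9"),
                "novel_known_exons", "text"),
    v.17 = list(ch("E1b", "E3", "E4", "E5", "E6", "E7", "E8", "E9"),
                "novel_known_exons", "text"),
    v.18 = list(ch("E1a", "E3", "E5", "E6", "E7", "E8", "E9"),
                "novel_known_exons", "text"),
    v.19 = list(ch("E1a", "E3", "E4", "E5", "E7", "E8", "E9"),
                "novel_known_exons", "text"),
    v.20 = list(ch("E1a", "E3", "E7", "E8", "E9"),
                "novel_known_exons", "inferred"),
    v.21 = list(ch("E1a", "E3", "E5", "E6", "E7", "E9"),
                "novel_known_exons", "inferred"),
    v.22 = list(ch("E1a", "E3", "E5", "E7", "E8", "E9"),
                "novel_known_exons", "inferred"),
    v.23 = list(ch("E1a", "E3", "E8", "E9"), "novel_known_exons", "inferred"),
    v.24 = list(ch("E1a", "E4", "E5", "E6", "E7", "E8", "E9"),
                "novel_known_exons", "text"),
    v.25 = list(ch("E1a", "E5", "E6", "E7", "E8", "E9"),
                "novel_known_exons", "inferred"),
    v.26 = list(ch("E1a", "E7", "E8", "E9"), "novel_known_exons", "inferred"),
    v.27 = list(ch("E1a", "E8", "E9"), "novel_known_exons", "inferred"))
  tibble(name = names(def),
         chain = purrr::map(def, 1),
         category = purrr::map_chr(def, 2),
         source = purrr::map_chr(def, 3))
}
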