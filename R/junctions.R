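#' Extract per-read aligned block chains from spliced alignments
#'
#' Reads primary alignments (secondary, supplementary and unmapped records
#' are skipped) and splits each into its aligned reference blocks. Blocks are
#' separated only by intron gaps (`N` CIGAR operations); deletions do not
#' split a block. The gaps between consecutive blocks of a read are its
#' splice junctions.
#'
#' @param alignments Path to a SAM or BAM file with a valid header. SAM input
#'   is converted on the fly with [Rsamtools::asBam()].
#' @return Tibble with one row per aligned block: `read_id`, `block`
#'   (1-based index along the read), `start`, `end` (1-based, closed). The
#'   reference contig is recorded in the `"contig"` attribute.
#' @export
extract_read_chains <- function(alignments) {
  path <- alignments
  if (tolower(tools::file_ext(path)) %in% c("sam", "txt")) {
    first <- readr::read_lines(path, n_max = 1L)
    if (length(first) && !grepl("^@", first)) {
      abort("cannot parse SAM input: no header (@HD/@SQ lines) present")
    }
    dest <- tempfile(fileext = "")
    path <- tryCatch(
      Rsamtools::asBam(alignments, dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) {
        abort(paste0("cannot parse SAM input (missing/invalid header?): ",
                     conditionMessage(e)))
      })
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE))
  aln <- GenomicAlignments::readGAlignments(path, param = param,
                                            use.names = TRUE)
  if (length(aln) == 0L) {
    warn("no mapped primary alignments in input")
    out <- tibble(read_id = character(), block = integer(),
                  start = integer(), end = integer())
    attr(out, "contig") <- NA_character_
    return(out)
  }
  blocks <- GenomicAlignments::grglist(aln)  # split on N gaps only
  flat <- unlist(blocks, use.names = FALSE)
  nb <- lengths(blocks)
  out <- tibble(read_id = rep(names(blocks), nb),
                block = unlist(lapply(nb, seq_len), use.names = FALSE),
                start = GenomicRanges::start(flat),
                end = GenomicRanges::end(flat))
  attr(out, "contig") <- as.character(GenomicRanges::seqnames(flat)[1])
  out
}

# per-read junction list: one row per gap between consecutive blocks
read_junctions <- function(chains) {
  chains |>
    arrange(.data$read_id, .data$block) |>
    group_by(.data$read_id) |>
    mutate(acceptor = lead(.data$start)) |>
    ungroup() |>
    filter(!is.na(.data$acceptor)) |>
    select(read_id = "read_id", upstream_block = "block",
           donor = "end", acceptor = "acceptor")
}

#' Snap noisy junction coordinates to annotated splice sites
#'
#' Each junction end lying within `w` nt of an annotated splice site is moved
#' to a site, choosing the donor/acceptor assignment that minimises the total
#' shift. Ties are broken in favour of the pair forming an annotated
#' junction, then (when `genome` is supplied) a GT..AG junction, then the
#' smaller coordinates. Junction ends with no annotated site within `w` are
#' left untouched; these are the candidate cryptic splice sites.
#'
#' @param chains Block tibble from [extract_read_chains()].
#' @param model A `gene_model`.
#' @param w Snap window in nt (default 12).
#' @param genome Optional [Biostrings::DNAStringSet] for the GT-AG tie-break.
#' @return The block tibble with corrected block boundaries.
#' @export
snap_junctions <- function(chains, model, w = 12L, genome = NULL) {
  stopifnot(w >= 0)
  if (nrow(chains) == 0L) return(chains)
  jx <- read_junctions(chains)
  if (nrow(jx) == 0L) return(chains)
  sites <- annotated_sites(model)
  annpairs <- annotated_junctions(model)
  annkey <- paste(annpairs$donor, annpairs$acceptor)
  ref <- if (!is.null(genome)) genome[[model$contig]] else NULL

  uniq <- distinct(jx, .data$donor, .data$acceptor)
  snap_one <- function(d, a) {
    dc <- sites$donors[abs(sites$donors - d) <= w]
    ac <- sites$acceptors[abs(sites$acceptors - a) <= w]
    if (length(dc) == 0L) dc <- d
    if (length(ac) == 0L) ac <- a
    grid <- expand.grid(d2 = dc, a2 = ac)
    grid$shift <- abs(grid$d2 - d) + abs(grid$a2 - a)
    grid$ann <- paste(grid$d2, grid$a2) %in% annkey
    grid$gtag <- if (is.null(ref)) FALSE else {
      vapply(seq_len(nrow(grid)), function(i) {
        d2 <- grid$d2[i]; a2 <- grid$a2[i]
        a2 - d2 >= 4L &&
          as.character(Biostrings::subseq(ref, d2 + 1L, d2 + 2L)) == "GT" &&
          as.character(Biostrings::subseq(ref, a2 - 2L, a2 - 1L)) == "AG"
      }, logical(1))
    }
    o <- order(grid$shift, !grid$ann, !grid$gtag, grid$d2, grid$a2)
    c(grid$d2[o[1L]], grid$a2[o[1L]])
  }
  snapped <- t(mapply(snap_one, uniq$donor, uniq$acceptor))
  uniq$new_donor <- as.integer(snapped[, 1L])
  uniq$new_acceptor <- as.integer(snapped[, 2L])

  jx <- left_join(jx, uniq, by = c("donor", "acceptor"))
  ends <- select(jx, "read_id", block = "upstream_block", new_end = "new_donor")
  starts <- jx |>
    mutate(block = .data$upstream_block + 1L) |>
    select("read_id", "block", new_start = "new_acceptor")
  contig <- attr(chains, "contig")
  out <- chains |>
    left_join(ends, by = c("read_id", "block")) |>
    left_join(starts, by = c("read_id", "block")) |>
    mutate(start = if_else(is.na(.data$new_start), .data$start, .data$new_start),
           end = if_else(is.na(.data$new_end), .data$end, .data$new_end)) |>
    select("read_id", "block", "start", "end")
  attr(out, "contig") <- contig
  out
}

#' Tabulate splice junctions with read support
#'
#' Counts distinct junctions over all reads (one vote per read per junction)
#' and classifies each junction: `annotated` if the (donor, acceptor) pair
#' occurs in an annotated transcript, `novel_combination` if both sites are
#' annotated splice sites but the pair is not, and `cryptic` otherwise.
#' Junctions are reported when their support reaches both `min_support`
#' reads and `min_frac` of the mapped reads.
#'
#' @param chains Snapped block tibble (see [snap_junctions()]).
#' @param model A `gene_model`.
#' @param min_support Minimum supporting reads (default 5).
#' @param min_frac Minimum supporting fraction of mapped reads (default
#'   1e-4).
#' @return Tibble of class `junction_tbl` with columns `label`, `from_exon`,
#'   `to_exon`, `donor`, `acceptor`, `status`, `support`.
#' @export
tabulate_junctions <- function(chains, model, min_support = 5L,
                               min_frac = 1e-4) {
  n_reads <- dplyr::n_distinct(chains$read_id)
  jx <- read_junctions(chains) |>
    distinct(.data$read_id, .data$donor, .data$acceptor) |>
    count(.data$donor, .data$acceptor, name = "support")
  sites <- annotated_sites(model)
  annpairs <- annotated_junctions(model)
  annkey <- paste(annpairs$donor, annpairs$acceptor)
  ann_exons <- filter(model$exons, .data$annotated)
  threshold <- max(min_support, ceiling(min_frac * n_reads))

  out <- jx |>
    filter(.data$support >= threshold) |>
    mutate(
      status = dplyr::case_when(
        paste(.data$donor, .data$acceptor) %in% annkey ~ "annotated",
        .data$donor %in% sites$donors &
          .data$acceptor %in% sites$acceptors ~ "novel_combination",
        TRUE ~ "cryptic"),
      from_exon = ann_exons$id[match(.data$donor, ann_exons$end)],
      to_exon = ann_exons$id[match(.data$acceptor, ann_exons$start)],
      label = if_else(
        is.na(.data$from_exon) | is.na(.data$to_exon),
        NA_character_,
        paste0(exon_label(model, dplyr::coalesce(.data$from_exon, "?")), "-",
               exon_label(model, dplyr::coalesce(.data$to_exon, "?"))))) |>
    arrange(.data$donor, .data$acceptor) |>
    select("label", "from_exon", "to_exon", "donor", "acceptor", "status",
           "support")
  class(out) <- c("junction_tbl", class(out))
  attr(out, "n_reads") <- n_reads
  out
}

#' Discover cryptic (novel) exons from internal aligned blocks
#'
#' A candidate novel exon is an internal aligned block (flanked by junctions
#' on both sides) that overlaps no annotated exon. Candidates are clustered
#' by proximity (boundaries within `w` nt) and each cluster is reported with
#' its modal start and end; calls supported by fewer than `min_support`
#' reads are suppressed. Calls are named `N1`, `N2`, ... in genomic order.
#'
#' @param chains Snapped block tibble.
#' @param model A `gene_model`.
#' @param min_support Minimum supporting reads (default 5).
#' @param w Clustering window in nt (default 12).
#' @return Tibble of class `novel_exon_tbl`: `id`, `start`, `end`, `length`,
#'   `upstream_exon`, `downstream_exon`, `support`.
#' @export
discover_novel_exons <- function(chains, model, min_support = 5L, w = 12L) {
  empty <- tibble(id = character(), start = integer(), end = integer(),
                  length = integer(), upstream_exon = character(),
                  downstream_exon = character(), support = integer())
  class(empty) <- c("novel_exon_tbl", class(empty))
  if (nrow(chains) == 0L) return(empty)
  internal <- chains |>
    group_by(.data$read_id) |>
    filter(.data$block > 1L, .data$block < max(.data$block)) |>
    ungroup()
  if (nrow(internal) == 0L) return(empty)
  ann <- filter(model$exons, .data$annotated)
  overlaps <- purrr::map_lgl(seq_len(nrow(internal)), function(i) {
    any(internal$start[i] <= ann$end & internal$end[i] >= ann$start)
  })
  cand <- internal[!overlaps, ]
  if (nrow(cand) == 0L) return(empty)

  cand <- arrange(cand, .data$start, .data$end)
  cl <- cumsum(c(1L, as.integer(diff(cand$start) > w)))
  modal <- function(x) as.integer(names(which.max(table(x))))
  calls <- cand |>
    mutate(cluster = cl) |>
    group_by(.data$cluster) |>
    summarise(start = modal(.data$start), end = modal(.data$end),
              support = dplyr::n_distinct(.data$read_id), .groups = "drop") |>
    filter(.data$support >= min_support) |>
    arrange(.data$start)
  if (nrow(calls) == 0L) return(empty)
  calls <- calls |>
    mutate(id = paste0("N", row_number()),
           length = .data$end - .data$start + 1L,
           upstream_exon = purrr::map_chr(.data$start, function(s) {
             up <- ann[ann$end < s, ]
             if (nrow(up)) up$id[which.max(up$end)] else NA_character_
           }),
           downstream_exon = purrr::map_chr(.data$end, function(e) {
             dn <- ann[ann$start > e, ]
             if (nrow(dn)) dn$id[which.min(dn$start)] else NA_character_
           })) |>
    select("id", "start", "end", "length", "upstream_exon",
           "downstream_exon", "support")
  class(calls) <- c("novel_exon_tbl", class(calls))
  calls
}
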