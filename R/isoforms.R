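#' Collapse full-length reads into transcript variants
#'
#' A read is *full-length* when its alignment starts within `t` nt of the
#' amplicon 5' end (the start of an annotated first exon) and ends within `t`
#' nt of the amplicon 3' end (the end of the last annotated exon); targeted
#' PCR places the primers in the terminal exons, so only such reads give an
#' unambiguous exon chain. Full-length reads are mapped to exon-id chains
#' over the registered exons (annotated exons plus discovered novel exons),
#' identical chains are merged with summed support, chains containing any
#' junction absent from the filtered junction table are dropped, and chains
#' below `min_support` reads are suppressed. Reads with a block spanning an
#' annotated intron (intron retention) are excluded from the spliced
#' catalogue and only counted.
#'
#' @param chains Snapped block tibble (see [snap_junctions()]).
#' @param junctions Junction table from [tabulate_junctions()].
#' @param novel_exons Novel-exon calls from [discover_novel_exons()] (may be
#'   empty).
#' @param model A `gene_model`.
#' @param t Terminal window for the full-length test, nt (default 30).
#' @param boundary_tol Tolerance for matching snapped block boundaries to
#'   registered exon boundaries, nt (default 12).
#' @param min_support Minimum reads per reported variant (default 3).
#' @return Tibble of class `variant_tbl`: `name`, `chain` (list column of
#'   exon ids), `chain_key`, `n_exons`, `support`, `category`,
#'   `retains_exon2`. Attribute `"read_status"` tabulates the fate of every
#'   read; attribute `"exons"` holds the registered exon table.
#' @export
assemble_variants <- function(chains, junctions, novel_exons, model,
                              t = 30L, boundary_tol = 12L, min_support = 3L) {
  empty <- variant_tbl_empty()
  if (nrow(chains) == 0L) {
    warn("no aligned reads; returning an empty variant catalogue")
    return(empty)
  }
  ann <- filter(model$exons, .data$annotated)
  registered <- bind_rows(
    select(ann, "id", "start", "end"),
    if (!is.null(novel_exons) && nrow(novel_exons))
      select(novel_exons, "id", "start", "end")) |>
    arrange(.data$start)
  firsts <- unique(vapply(model$transcripts, first, character(1)))
  lasts <- unique(vapply(model$transcripts, last, character(1)))

  near_id <- function(x, boundary, tol) {
    d <- abs(outer(x, boundary, "-"))
    j <- apply(d, 1L, which.min)
    ok <- d[cbind(seq_along(x), j)] <= tol
    if_else(ok, registered$id[j], NA_character_)
  }

  b <- chains |>
    arrange(.data$read_id, .data$block) |>
    group_by(.data$read_id) |>
    mutate(n_blocks = dplyr::n()) |>
    ungroup() |>
    mutate(
      start_id = near_id(.data$start, registered$start, boundary_tol),
      end_id = near_id(.data$end, registered$end, boundary_tol),
      is_first = .data$block == 1L,
      is_last = .data$block == .data$n_blocks)

  exon_start <- setNames(registered$start, registered$id)
  exon_end <- setNames(registered$end, registered$id)

  b <- b |>
    mutate(
      exon_id = dplyr::case_when(
        .data$is_first & .data$is_last ~ NA_character_,
        .data$is_first ~ .data$end_id,
        .data$is_last ~ .data$start_id,
        !is.na(.data$start_id) & !is.na(.data$end_id) &
          .data$start_id == .data$end_id ~ .data$start_id,
        TRUE ~ NA_character_),
      retention = !.data$is_first & !.data$is_last &
        !is.na(.data$start_id) & !is.na(.data$end_id) &
        .data$start_id != .data$end_id,
      fl5 = .data$is_first & !is.na(.data$exon_id) &
        .data$exon_id %in% firsts &
        abs(.data$start - unname(exon_start[.data$exon_id])) <= t,
      fl3 = .data$is_last & !is.na(.data$exon_id) &
        .data$exon_id %in% lasts &
        abs(.data$end - unname(exon_end[.data$exon_id])) <= t)

  per_read <- b |>
    group_by(.data$read_id) |>
    summarise(
      unassigned = any(is.na(.data$exon_id) & !.data$retention),
      retention = any(.data$retention),
      full_length = any(.data$fl5) && any(.data$fl3),
      chain_key = paste(.data$exon_id, collapse = "-"),
      .groups = "drop") |>
    mutate(status = dplyr::case_when(
      .data$retention ~ "intron_retention",
      .data$unassigned ~ "unassigned_block",
      !.data$full_length ~ "not_full_length",
      TRUE ~ "full_length"))

  status_tbl <- count(per_read, .data$status, name = "reads")
  fl <- filter(per_read, .data$status == "full_length")
  if (nrow(fl) == 0L) {
    warn("no full-length reads; returning an empty variant catalogue")
    attr(empty, "read_status") <- status_tbl
    return(empty)
  }

  # junction-table consistency: every junction of a chain must have survived
  # the junction filter
  jkey <- paste(junctions$donor, junctions$acceptor)
  chain_supported <- function(ids) {
    if (length(ids) < 2L) return(TRUE)
    d <- unname(exon_end[ids[-length(ids)]])
    a <- unname(exon_start[ids[-1L]])
    all(paste(d, a) %in% jkey)
  }

  ann_keys <- vapply(model$transcripts, chain_key, character(1))
  out <- fl |>
    count(.data$chain_key, name = "support") |>
    filter(.data$support >= min_support) |>
    mutate(chain = strsplit(.data$chain_key, "-", fixed = TRUE)) |>
    filter(purrr::map_lgl(.data$chain, chain_supported)) |>
    mutate(
      n_exons = lengths(.data$chain),
      category = dplyr::case_when(
        .data$chain_key %in% ann_keys ~ "annotated",
        purrr::map_lgl(.data$chain, function(x) !all(x %in% ann$id)) ~
          "novel_with_cryptic_exon",
        TRUE ~ "novel_known_exons"),
      retains_exon2 = purrr::map_lgl(.data$chain, function(x) "E2" %in% x),
      name = if_else(.data$category == "annotated",
                     names(ann_keys)[match(.data$chain_key, ann_keys)],
                     NA_character_)) |>
    arrange(dplyr::desc(.data$support))
  novel_idx <- which(is.na(out$name))
  out$name[novel_idx] <- sprintf("novel_%02d", seq_along(novel_idx))
  out <- select(out, "name", "chain", "chain_key", "n_exons", "support",
                "category", "retains_exon2")
  class(out) <- c("variant_tbl", class(out))
  attr(out, "read_status") <- status_tbl
  attr(out, "exons") <- registered
  out
}

variant_tbl_empty <- function() {
  out <- tibble(name = character(), chain = list(), chain_key = character(),
                n_exons = integer(), support = integer(),
                category = character(), retains_exon2 = logical())
  class(out) <- c("variant_tbl", class(out))
  out
}

#' Match assembled variants against a reference catalogue
#'
#' Labels each assembled variant with the unique reference name whose exon
#' chain it equals (`"unassigned"` otherwise) and reports reference chains
#' that were missed and assembled chains that match no reference entry.
#'
#' @param variants A `variant_tbl` from [assemble_variants()].
#' @param reference Tibble with columns `name` and `chain` (list of exon-id
#'   vectors), e.g. [elf3_catalogue()]. Duplicate chains are rejected.
#' @return List of class `catalogue_match` with elements `assignments`
#'   (variants plus `assigned_to`), `missed` (reference rows not assembled)
#'   and `spurious` (assembled chains not in the reference).
#' @export
match_catalogue <- function(variants, reference) {
  reference <- as_tibble(reference)
  ref_keys <- vapply(reference$chain, chain_key, character(1))
  if (anyDuplicated(ref_keys)) {
    abort("reference catalogue contains duplicate chains")
  }
  assignments <- variants |>
    mutate(assigned_to = dplyr::coalesce(
      reference$name[match(.data$chain_key, ref_keys)], "unassigned"))
  missed <- reference[!ref_keys %in% variants$chain_key,
                      c("name", "chain")]
  spurious <- filter(assignments, .data$assigned_to == "unassigned")
  structure(list(assignments = assignments, missed = missed,
                 spurious = spurious),
            class = "catalogue_match")
}

#' @export
print.catalogue_match <- function(x, ...) {
  cat("<catalogue_match>", nrow(x$assignments), "variants:",
      sum(x$assignments$assigned_to != "unassigned"), "assigned,",
      nrow(x$spurious), "spurious,", nrow(x$missed),
      "reference chains missed\n")
  invisible(x)
}
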