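#' Plot junction support by classification
#'
#' Horizontal bar chart of read support per splice junction (log10 scale),
#' coloured by junction status.
#'
#' @param object A `junction_tbl` from [tabulate_junctions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot junction_tbl
#' @export
autoplot.junction_tbl <- function(object, ...) {
  d <- mutate(as_tibble(object),
              label = dplyr::coalesce(.data$label,
                                      paste0(.data$donor, "..",
                                             .data$acceptor)))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$support,
    y = stats::reorder(.data$label, .data$support),
    fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "supporting reads", y = NULL, fill = "status",
                  title = "Splice junction support") +
    ggplot2::theme_minimal()
}

#' Plot variant exon structures
#'
#' Transcript-diagram view of assembled variants: one row per variant, exon
#' boxes at genomic coordinates joined by a line, novel exons highlighted.
#'
#' @param variants A `variant_tbl` from [assemble_variants()] or any tibble
#'   with `name` and `chain` columns.
#' @param model A `gene_model` (extended with any novel exons present in
#'   the chains).
#' @return A ggplot object.
#' @export
plot_variant_structures <- function(variants, model) {
  d <- purrr::map2_dfr(variants$name, variants$chain, function(nm, ch) {
    e <- exon_row(model, ch)
    tibble(name = nm, exon = ch, start = e$start, end = e$end,
           annotated = e$annotated)
  })
  d$name <- factor(d$name, levels = rev(unique(variants$name)))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$name)) +
    ggplot2::geom_line(ggplot2::aes(x = .data$start, group = .data$name),
                       linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = as.numeric(.data$name) - 0.35,
                                    ymax = as.numeric(.data$name) + 0.35,
                                    fill = .data$annotated)) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "grey30", `FALSE` = "firebrick"),
      labels = c(`TRUE` = "annotated", `FALSE` = "novel"), name = "exon") +
    ggplot2::labs(x = paste0("position on ", model$contig), y = NULL,
                  title = "Variant exon structures") +
    ggplot2::theme_minimal()
}

#' Plot the domain-presence table
#'
#' Tile view of protein-domain presence across variants: one row per
#' variant, one column per domain.
#'
#' @param orf An `orf_tbl` from [orf_report()].
#' @param model A `gene_model` supplying the domain order.
#' @return A ggplot object.
#' @export
plot_domain_table <- function(orf, model) {
  long <- tidyr::pivot_longer(
    select(as_tibble(orf), "name",
           dplyr::any_of(model$domain_defs$name)),
    -"name", names_to = "domain", values_to = "present")
  long$domain <- factor(long$domain, levels = model$domain_defs$name)
  long$name <- factor(long$name, levels = rev(unique(orf$name)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$domain, y = .data$name,
                                     fill = .data$present)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "grey25", `FALSE` = "grey90")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "present",
                  title = "Protein domains per variant") +
    ggplot2::theme_minimal()
}

#' @method tidy junction_tbl
#' @export
tidy.junction_tbl <- function(x, ...) as_tibble(x)

#' @method glance junction_tbl
#' @export
glance.junction_tbl <- function(x, ...) {
  tibble(n_reads = attr(x, "n_reads") %||% NA_integer_,
         junctions = nrow(x),
         annotated = sum(x$status == "annotated"),
         novel_combination = sum(x$status == "novel_combination"),
         cryptic = sum(x$status == "cryptic"))
}

#' @method tidy variant_tbl
#' @export
tidy.variant_tbl <- function(x, ...) flatten_chain(as_tibble(x))

#' @method glance variant_tbl
#' @export
glance.variant_tbl <- function(x, ...) {
  tibble(variants = nrow(x),
         annotated = sum(x$category == "annotated"),
         novel = sum(x$category != "annotated"),
         with_cryptic_exon = sum(x$category == "novel_with_cryptic_exon"),
         reads = sum(x$support))
}

#' @method tidy orf_tbl
#' @export
tidy.orf_tbl <- function(x, ...) as_tibble(x)

#' @method glance orf_tbl
#' @export
glance.orf_tbl <- function(x, ...) {
  tibble(variants = nrow(x),
         coding = sum(x$coding_status == "coding"),
         noncoding = sum(x$coding_status != "coding"),
         nmd_candidates = sum(x$nmd_candidate))
}
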