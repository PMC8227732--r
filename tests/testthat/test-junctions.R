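test_that("N CIGAR operations split blocks; M/D/I do not", {
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, c(
    sam_record("r1", 1001L, "100M500N80M", strrep("A", 180L)),
    sam_record("r2", 2001L, "50M5D30M2I20M", strrep("A", 102L))))
  ch <- extract_read_chains(sam)
  r1 <- ch[ch$read_id == "r1", ]
  expect_equal(r1$start, c(1001L, 1601L))
  expect_equal(r1$end, c(1100L, 1680L))
  r2 <- ch[ch$read_id == "r2", ]
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$start, 2001L)
  expect_equal(r2$end, 2001L + 50L + 5L + 30L + 20L - 1L)
})

test_that("headerless SAM input is rejected with a clear error", {
  bad <- tempfile(fileext = ".sam")
  readr::write_lines(sam_record("r1", 1L, "10M", strrep("A", 10L)), bad)
  expect_error(extract_read_chains(bad), "header")
})

test_that("a SAM with no mapped records warns and returns an empty table", {
  empty <- tempfile(fileext = ".sam")
  write_test_sam(empty, character(0))
  expect_warning(ch <- extract_read_chains(empty), "no mapped")
  expect_equal(nrow(ch), 0L)
})

test_that("noiseless junction observations equal the truth multiset", {
  truth_jx <- function(chain_ids) {
    e <- fx$model$exons[match(chain_ids, fx$model$exons$id), ]
    if (nrow(e) < 2L) return(character(0))
    paste(e$end[-nrow(e)], e$start[-1])
  }
  expected <- table(unlist(lapply(
    clean_run$sim$truth$chain,
    function(k) truth_jx(strsplit(k, "-")[[1]]))))
  observed <- nanosplice:::read_junctions(clean_chains)
  observed_tab <- table(paste(observed$donor, observed$acceptor))
  expect_equal(sort(names(observed_tab)), sort(names(expected)))
  expect_equal(as.integer(observed_tab[names(expected)]),
               as.integer(expected))
})

test_that("snapping is a fixed point on already-annotated junctions", {
  snapped <- snap_junctions(clean_chains, fx$model, genome = fx$genome)
  expect_identical(snapped$start, clean_chains$start)
  expect_identical(snapped$end, clean_chains$end)
})

test_that("snapping corrects every displacement within the window exactly", {
  e5 <- nanosplice:::exon_row(fx$model, "E5")
  e7 <- nanosplice:::exon_row(fx$model, "E7")
  w <- 12L
  for (dd in c(-w, -3L, -1L, 0L, 1L, 3L, w)) {
    for (da in c(-w, -1L, 0L, 1L, w)) {
      ch <- tibble::tibble(
        read_id = "r", block = 1:2,
        start = c(e5$start, e7$start + da),
        end = c(e5$end + dd, e7$end))
      attr(ch, "contig") <- fx$model$contig
      out <- snap_junctions(ch, fx$model, w = w, genome = fx$genome)
      expect_equal(out$end[1], e5$end)
      expect_equal(out$start[2], e7$start)
    }
  }
  # one past the window: left untouched
  ch <- tibble::tibble(read_id = "r", block = 1:2,
                       start = c(e5$start, e7$start + w + 1L),
                       end = c(e5$end + w + 1L, e7$end))
  attr(ch, "contig") <- fx$model$contig
  out <- snap_junctions(ch, fx$model, w = w, genome = fx$genome)
  expect_equal(out$end[1], e5$end + w + 1L)
  expect_equal(out$start[2], e7$start + w + 1L)
})

test_that("snapped junctions match the truth on >= 99% of observations", {
  truth_key <- vapply(full_run$sim$truth$chain, function(k) {
    ids <- strsplit(k, "-")[[1]]
    e <- fx$model$exons[match(ids, fx$model$exons$id), ]
    paste(paste(e$end[-nrow(e)], e$start[-1]), collapse = ";")
  }, character(1))
  names(truth_key) <- full_run$sim$truth$read_id
  obs <- nanosplice:::read_junctions(full_chains) |>
    dplyr::group_by(read_id) |>
    dplyr::summarise(key = paste(paste(donor, acceptor), collapse = ";"))
  ok <- obs$key == truth_key[obs$read_id]
  expect_gte(mean(ok), 0.99)
})

test_that("junction classification separates the three statuses", {
  jx <- full_junctions
  expect_setequal(unique(jx$status),
                  c("annotated", "novel_combination", "cryptic"))
  expect_equal(sum(jx$status == "annotated"), 9L)
  expect_equal(sum(jx$status == "novel_combination"), 15L)
  got <- jx[jx$status == "novel_combination", c("from_exon", "to_exon")]
  expect_setequal(paste(got$from_exon, got$to_exon),
                  paste(novel_pairs$from, novel_pairs$to))
  # the four cryptic junctions flank the two cryptic exons
  expect_equal(sum(jx$status == "cryptic"), 4L)
})

test_that("junction support threshold is monotone", {
  lo <- tabulate_junctions(full_chains, fx$model, min_support = 5L)
  hi <- tabulate_junctions(full_chains, fx$model, min_support = 100L)
  expect_true(all(paste(hi$donor, hi$acceptor) %in%
                    paste(lo$donor, lo$acceptor)))
  expect_lte(nrow(hi), nrow(lo))
  merged <- dplyr::inner_join(as.data.frame(lo), as.data.frame(hi),
                              by = c("donor", "acceptor"))
  expect_equal(merged$support.x, merged$support.y)
})

test_that("annotated-only reads produce no novel calls", {
  mix <- catalogue_mixture(cat27, "uniform",
                           transcripts = c("v.1", "v.2"))
  run <- sim_to_sam(mix, 200L, seed = 4L)
  ch <- snap_junctions(extract_read_chains(run$sam), fx$model,
                       genome = fx$genome)
  jx <- tabulate_junctions(ch, fx$model)
  expect_true(all(jx$status == "annotated"))
  expect_equal(nrow(discover_novel_exons(ch, fx$model)), 0L)
})

test_that("novel exon boundaries are exact on noiseless reads", {
  mix <- catalogue_mixture(cat27, "uniform", transcripts = "v.15")
  run <- sim_to_sam(mix, 30L, seed = 6L, p_sub = 0, p_ins = 0, p_del = 0)
  ch <- extract_read_chains(run$sam)
  ne <- discover_novel_exons(ch, fx$model)
  n1 <- nanosplice:::exon_row(fx$model, "N1")
  expect_equal(nrow(ne), 1L)
  expect_equal(ne$start, n1$start)
  expect_equal(ne$end, n1$end)
  expect_equal(ne$length, 156L)
  expect_equal(ne$upstream_exon, "E7")
  expect_equal(ne$downstream_exon, "E8")
  expect_equal(ne$support, 30L)
})

test_that("novel exon discovery reports modal boundaries under noise", {
  ne <- full_novel_exons
  expect_equal(nrow(ne), 2L)
  expect_equal(ne$length, c(156L, 92L))
  expect_equal(ne$upstream_exon, c("E7", "E8"))
  expect_equal(ne$downstream_exon, c("E8", "E9"))
  n1 <- nanosplice:::exon_row(fx$model, "N1")
  n2 <- nanosplice:::exon_row(fx$model, "N2")
  expect_equal(ne$start, c(n1$start, n2$start))
  expect_equal(ne$end, c(n1$end, n2$end))
})
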