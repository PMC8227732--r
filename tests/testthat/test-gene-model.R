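test_that("fixture exon architecture has the expected lengths", {
  e <- tidy(fx$model)
  len <- setNames(e$length, e$id)
  expect_equal(len[["E1a"]], 120L)
  expect_equal(len[["E1b"]], 234L)
  expect_equal(len[["N1"]], 156L)
  expect_equal(len[["N2"]], 92L)
  expect_equal(sum(e$annotated), 10L)
  expect_equal(nrow(e), 12L)
})

test_that("every intron of the fixture uses GT..AG splice sites", {
  ref <- fx$genome[[fx$model$contig]]
  ex <- dplyr::arrange(fx$model$exons, start)
  for (i in seq_len(nrow(ex) - 1L)) {
    d <- ex$end[i]
    a <- ex$start[i + 1L]
    expect_equal(as.character(Biostrings::subseq(ref, d + 1L, d + 2L)), "GT")
    expect_equal(as.character(Biostrings::subseq(ref, a - 2L, a - 1L)), "AG")
  }
})

test_that("fixture generation is deterministic and FASTA output byte-stable", {
  fx2 <- elf3_fixture(seed = 1)
  expect_identical(as.character(fx2$genome), as.character(fx$genome))
  expect_identical(fx2$model$exons, fx$model$exons)
  p1 <- tempfile(fileext = ".fa")
  p2 <- tempfile(fileext = ".fa")
  write_genome_fasta(fx$genome, p1)
  write_genome_fasta(fx2$genome, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  fx3 <- elf3_fixture(seed = 99)
  expect_false(identical(as.character(fx3$genome), as.character(fx$genome)))
})

test_that("gene model round-trips through BED12 and GTF", {
  bed <- tempfile(fileext = ".bed")
  gtf <- tempfile(fileext = ".gtf")
  write_gene_model(fx$model, bed)
  write_gene_model(fx$model, gtf)
  from_bed <- load_gene_model(bed)
  from_gtf <- load_gene_model(gtf)
  ann <- dplyr::filter(fx$model$exons, annotated)
  for (m in list(from_bed, from_gtf)) {
    expect_equal(m$contig, fx$model$contig)
    expect_setequal(paste(m$exons$start, m$exons$end),
                    paste(ann$start, ann$end))
    key <- function(model, tx) {
      e <- model$exons[match(tx, model$exons$id), ]
      paste(e$start, e$end, collapse = ";")
    }
    for (tx in names(fx$model$transcripts)) {
      expect_true(key(fx$model, fx$model$transcripts[[tx]]) %in%
                    vapply(m$transcripts, function(ch) key(m, ch),
                           character(1)))
    }
  }
  # alternative first exons get E1a/E1b labels
  expect_true(all(c("E1a", "E1b") %in% from_bed$exons$id))
})

test_that("annotated transcript translates to the engineered 371-aa protein", {
  anch <- extract_anchors(fx$model, fx$genome)
  cdna <- splice_cdna(fx$model, fx$genome, fx$model$transcripts[["v.1"]])
  orf <- predict_orf(cdna, anch)
  expect_equal(orf$protein_length, 371L)
  expect_identical(orf$protein, fx$protein)
  expect_identical(substr(fx$protein, 1, 1), "M")
  for (i in seq_len(nrow(fx$model$domain_defs))) {
    sub <- substr(fx$protein, fx$model$domain_defs$aa_start[i],
                  fx$model$domain_defs$aa_end[i])
    expect_equal(
      length(Biostrings::matchPattern(sub, Biostrings::AAString(fx$protein))),
      1L)
  }
})

test_that("gene_model rejects malformed input", {
  ex <- tibble::tibble(id = c("A", "A"), start = c(1L, 10L),
                       end = c(5L, 20L), annotated = TRUE)
  expect_error(gene_model("g", "c", "+", ex, list(t1 = c("A"))),
               "unique")
  ex2 <- tibble::tibble(id = "A", start = 10L, end = 5L, annotated = TRUE)
  expect_error(gene_model("g", "c", "+", ex2, list(t1 = "A")),
               "start")
  ex3 <- tibble::tibble(id = "A", start = 1L, end = 5L, annotated = TRUE)
  expect_error(gene_model("g", "c", "+", ex3, list(t1 = c("A", "B"))),
               "unknown")
  expect_error(gene_model("g", "c", "+", ex3, list()), "transcript")
})

test_that("fixture configuration rejects frame-inconsistent overrides", {
  base <- fx$config$exon_lengths
  broken <- base
  broken[["E5"]] <- 151L  # not a multiple of 3
  expect_error(elf3_fixture_config(exon_lengths = broken),
               "frame engineering")
  broken2 <- base
  broken2[["E8"]] <- 132L  # multiple of 3: breaks the common-frame design
  expect_error(elf3_fixture_config(exon_lengths = broken2),
               "frame engineering")
  expect_error(elf3_fixture_config(n1_length = 155L), "frame engineering")
  expect_error(elf3_fixture_config(n2_length = 93L), "frame engineering")
})
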