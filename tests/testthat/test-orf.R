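anchors <- extract_anchors(fx$model, fx$genome)
report <- orf_report(cat27, fx$model, fx$genome)

test_that("the annotated transcripts give the full-length protein", {
  for (nm in c("v.1", "v.2")) {
    row <- report[report$name == nm, ]
    expect_equal(row$start_origin, "annotated_exon2")
    expect_equal(row$protein_length, 371L)
    expect_false(row$ptc)
    expect_false(row$nmd_candidate)
    expect_equal(row$coding_status, "coding")
    expect_true(all(unlist(row[, fx$model$domain_defs$name])))
  }
})

test_that("start-codon priority follows annotated > exon 3 > exon 4 > scan", {
  expect_equal(report$start_origin[report$name == "v.16"], "alt_exon3")
  expect_equal(report$start_origin[report$name == "v.24"], "alt_exon4")
  expect_true(all(report$start_origin[report$name %in%
    paste0("v.", 3:15)] == "annotated_exon2"))
  expect_true(all(report$start_origin[report$name %in%
    paste0("v.", 25:27)] == "none"))
})

test_that("coding and non-coding counts match the catalogue design", {
  novel <- report[!report$name %in% c("v.1", "v.2"), ]
  expect_equal(sum(novel$coding_status == "coding"), 21L)
  expect_equal(sum(novel$coding_status != "coding"), 4L)
  expect_equal(sum(novel$coding_status == "noncoding_ptc"), 1L)
  expect_equal(sum(novel$coding_status == "noncoding_no_orf"), 3L)
})

test_that("the N1-carrying variant is a PTC/NMD candidate", {
  v15 <- report[report$name == "v.15", ]
  expect_true(v15$ptc)
  expect_true(v15$nmd_candidate)
  expect_equal(v15$coding_status, "noncoding_ptc")
  expect_gt(v15$stop_to_junction, 50L)
})

test_that("frameshifted stops in the final exon are not NMD candidates", {
  for (nm in c("v.6", "v.9", "v.14")) {
    row <- report[report$name == nm, ]
    expect_false(row$ptc)
    expect_false(row$nmd_candidate)
    expect_equal(row$coding_status, "coding")
    # frameshift: the protein differs from the annotated one
    expect_false(row$protein_length == 371L)
  }
})

test_that("the NMD distance rule uses a strict 50-nt boundary", {
  base <- tibble::tibble(start_origin = "annotated_exon2", start = 1L,
                         stop = NA_integer_, protein_length = 10L,
                         has_orf = TRUE, ptc = TRUE, protein = "M",
                         anchor_matching = "exact")
  chain <- c("E8", "E9")
  lens <- nanosplice:::exon_length(fx$model, chain)
  last_junction <- sum(lens) - lens[2]
  at <- function(d) {
    o <- base
    o$stop <- as.integer(last_junction - d)
    classify_nmd(o, chain, fx$model)$nmd_candidate
  }
  expect_false(at(50L))
  expect_true(at(51L))
  expect_false(at(0L))
  expect_false(at(-10L))
})

test_that("domain presence reproduces the expected matrix row for row", {
  got <- report[match(domain_expect$name, report$name),
                c("name", fx$model$domain_defs$name)]
  expect_equal(as.data.frame(got), as.data.frame(domain_expect),
               ignore_attr = TRUE)
})

test_that("a present domain implies its coding exons are in the chain", {
  aa <- nanosplice:::fixture_aa_map(fx$config)
  dd <- fx$model$domain_defs
  cds_exons <- names(aa$first)
  for (i in seq_len(nrow(report))) {
    ch <- cat27$chain[[which(cat27$name == report$name[i])]]
    for (k in seq_len(nrow(dd))) {
      if (!isTRUE(report[[dd$name[k]]][i])) next
      carriers <- cds_exons[aa$first <= dd$aa_end[k] &
                              aa$last_full >= dd$aa_start[k]]
      expect_true(all(carriers %in% ch),
                  info = paste(report$name[i], dd$name[k]))
    }
  }
})

test_that("ORF prediction falls back to anchors with one mismatch", {
  cdna <- splice_cdna(fx$model, fx$genome, cat27$chain[[1]])
  mut <- anchors
  a <- mut[["annotated"]]
  flip <- function(b) c(A = "C", C = "A", G = "T", T = "A")[[b]]
  substr(a, 8, 8) <- flip(substr(a, 8, 8))
  mut[["annotated"]] <- a
  orf <- predict_orf(cdna, mut)
  expect_equal(orf$start_origin, "annotated_exon2")
  expect_equal(orf$anchor_matching, "mismatch")
  expect_equal(orf$protein_length, 371L)
})

test_that("a cDNA without any ATG yields no ORF", {
  orf <- predict_orf(strrep("CT", 300L), anchors)
  expect_equal(orf$start_origin, "none")
  expect_false(orf$has_orf)
  expect_equal(orf$protein_length, 0L)
})

test_that("ORF calling works from a cDNA FASTA", {
  fa <- tempfile(fileext = ".fa")
  cdna <- Biostrings::DNAStringSet(vapply(cat27$chain[1:3], function(ch) {
    as.character(splice_cdna(fx$model, fx$genome, ch))
  }, character(1)))
  names(cdna) <- cat27$name[1:3]
  Biostrings::writeXStringSet(cdna, fa)
  out <- orf_from_fasta(fa, anchors)
  expect_equal(out$name, cat27$name[1:3])
  expect_equal(out$protein_length[1:2], c(371L, 371L))
  expect_equal(out$protein_length[3],
               report$protein_length[report$name == "v.3"])
})
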