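test_that("noiseless reads are exact spliced cDNAs of their transcripts", {
  reads <- clean_run$sim$reads
  cdna <- lapply(full_mix$chain, function(ch) {
    as.character(splice_cdna(fx$model, fx$genome, ch))
  })
  names(cdna) <- full_mix$name
  expect_identical(reads$sequence, unlist(cdna[reads$transcript],
                                          use.names = FALSE))
  expect_true(all(clean_run$sim$truth$n_sub == 0L))
  expect_true(all(clean_run$sim$truth$n_del == 0L))
  expect_true(all(clean_run$sim$truth$n_ins == 0L))
})

test_that("realised error rates match the configured rates within 3 SE", {
  sim <- full_run$sim
  m <- sim$reads$win_to - sim$reads$win_from + 1L
  total <- sum(m)
  cfg <- sim$cfg
  check <- function(observed, p) {
    se <- sqrt(p * (1 - p) / total)
    expect_lt(abs(observed / total - p), 3 * se + 2 / total * nrow(sim$reads))
  }
  check(sum(sim$truth$n_del), cfg$p_del)
  # substitutions only hit non-deleted bases
  check(sum(sim$truth$n_sub), cfg$p_sub * (1 - cfg$p_del))
  check(sum(sim$truth$n_ins), cfg$p_ins)
})

test_that("transcript abundances are recovered within 3 SE", {
  counts <- table(full_run$sim$truth$transcript)
  n <- nrow(full_run$sim$truth)
  for (nm in c("v.1", "v.14", "v.27")) {
    p <- full_mix$weight[full_mix$name == nm]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(counts[[nm]] / n - p), 3 * se)
  }
})

test_that("identical configurations give byte-identical FASTQ and SAM", {
  mix <- catalogue_mixture(cat27, "uniform", transcripts = c("v.1", "v.4"))
  paths <- replicate(2, {
    cfg <- sim_config(mixture = mix, n_reads = 50L, seed = 11L)
    sim <- simulate_reads(fx$model, fx$genome, cfg)
    fq <- tempfile(fileext = ".fastq")
    sam <- tempfile(fileext = ".sam")
    write_fastq(sim, fq)
    emit_oracle_alignments(sim, sam)
    c(fq, sam)
  })
  for (k in 1:2) {
    expect_identical(readBin(paths[k, 1], "raw", file.size(paths[k, 1])),
                     readBin(paths[k, 2], "raw", file.size(paths[k, 2])))
  }
})

test_that("oracle SAM records are internally consistent", {
  lines <- readr::read_lines(full_run$sam)
  rec <- lines[!startsWith(lines, "@")]
  fields <- strsplit(rec, "\t", fixed = TRUE)
  ops <- function(cig) {
    n <- as.integer(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
    o <- regmatches(cig, gregexpr("[A-Z]", cig))[[1]]
    setNames(
      vapply(c("M", "I", "D", "N"), function(x) sum(n[o == x]), numeric(1)),
      c("M", "I", "D", "N"))
  }
  glen <- sum(Biostrings::width(fx$genome))
  for (f in fields[seq(1, length(fields), by = 37)]) {
    op <- ops(f[6])
    expect_equal(unname(op[["M"]] + op[["I"]]), nchar(f[10]))
    expect_lte(as.integer(f[4]) + op[["M"]] + op[["D"]] + op[["N"]] - 1L, glen)
  }
})

test_that("a noiseless nine-exon read aligns with exactly eight N gaps", {
  mix <- catalogue_mixture(cat27, "uniform", transcripts = "v.1")
  run <- sim_to_sam(mix, 3L, seed = 3L, p_sub = 0, p_ins = 0, p_del = 0)
  lines <- readr::read_lines(run$sam)
  rec <- lines[!startsWith(lines, "@")]
  for (r in rec) {
    cig <- strsplit(r, "\t")[[1]][6]
    expect_equal(lengths(regmatches(cig, gregexpr("N", cig))), 8L)
  }
})

test_that("aligned blocks of noiseless reads equal the exon coordinates", {
  blocks <- extract_read_chains(clean_run$sam)
  truth <- clean_run$sim$truth
  ex <- fx$model$exons
  some <- truth[seq(1, nrow(truth), by = 53), ]
  for (i in seq_len(nrow(some))) {
    b <- blocks[blocks$read_id == some$read_id[i], ]
    # every consecutive exon pair in the fixture is separated by an intron,
    # so aligned blocks coincide with the chain's exons
    e <- ex[match(strsplit(some$chain[i], "-")[[1]], ex$id), ]
    expect_equal(b$start, e$start)
    expect_equal(b$end, e$end)
  }
})

test_that("sim_config validates its inputs", {
  mix <- catalogue_mixture(cat27, "uniform")
  expect_error(sim_config(mixture = mix, p_sub = 0.6), "probabilities")
  expect_error(sim_config(mixture = mix, truncation_rate = 2), "truncation")
  bad <- mix
  bad$weight[1] <- -1
  expect_error(sim_config(mixture = bad), "positive")
  expect_error(catalogue_mixture(cat27, transcripts = "nope"),
               "no transcripts")
})

test_that("truncated reads fail the full-length filter downstream", {
  mix <- catalogue_mixture(cat27, "uniform", transcripts = "v.1")
  run <- sim_to_sam(mix, 60L, seed = 5L, truncation_rate = 1,
                    p_sub = 0, p_ins = 0, p_del = 0)
  ch <- extract_read_chains(run$sam)
  ch <- snap_junctions(ch, fx$model, genome = fx$genome)
  jx <- tabulate_junctions(ch, fx$model)
  va <- suppressWarnings(
    assemble_variants(ch, jx, discover_novel_exons(ch, fx$model), fx$model))
  status <- attr(va, "read_status")
  expect_true(all(run$sim$truth$truncated))
  expect_equal(sum(status$reads[status$status == "full_length"]), 0L)
})
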