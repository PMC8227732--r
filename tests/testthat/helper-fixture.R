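# Shared fixture and simulations, built once per test run.

fx <- elf3_fixture(seed = 1)
cat27 <- elf3_catalogue()

sim_to_sam <- function(mix, n_reads, seed, ...) {
  cfg <- sim_config(mixture = mix, n_reads = n_reads, seed = seed, ...)
  sim <- simulate_reads(fx$model, fx$genome, cfg)
  sam <- tempfile(fileext = ".sam")
  emit_oracle_alignments(sim, sam, model = fx$model)
  list(sim = sim, sam = sam)
}

# full catalogue, default error rates (150 reads per chain in expectation)
full_mix <- catalogue_mixture(cat27, profile = "uniform")
full_run <- sim_to_sam(full_mix, 4050L, seed = 1L)
full_chains_raw <- extract_read_chains(full_run$sam)
full_chains <- snap_junctions(full_chains_raw, fx$model, genome = fx$genome)
full_junctions <- tabulate_junctions(full_chains, fx$model)
full_novel_exons <- discover_novel_exons(full_chains, fx$model)
full_variants <- assemble_variants(full_chains, full_junctions,
                                   full_novel_exons, fx$model)

# same catalogue, error-free
clean_run <- sim_to_sam(full_mix, 2700L, seed = 2L,
                        p_sub = 0, p_ins = 0, p_del = 0)
clean_chains <- extract_read_chains(clean_run$sam)

# the 15 novel exon-pair junctions between annotated exons
novel_pairs <- data.frame(
  from = c("E1a", "E1a", "E1a", "E1a", "E1a", "E1b", "E2", "E2", "E2",
           "E3", "E3", "E3", "E4", "E5", "E7"),
  to   = c("E3", "E4", "E5", "E7", "E8", "E3", "E4", "E8", "E9",
           "E5", "E7", "E8", "E8", "E7", "E9"))

# expected domain-presence matrix for the novel coding variants
domain_expect <- tibble::tribble(
  ~name,  ~PNT,  ~TAD,  ~SAR,  ~AT_hook, ~ETS,
  "v.3",  TRUE,  TRUE,  FALSE, TRUE,  TRUE,
  "v.4",  TRUE,  FALSE, TRUE,  TRUE,  TRUE,
  "v.5",  FALSE, TRUE,  TRUE,  TRUE,  TRUE,
  "v.6",  TRUE,  TRUE,  TRUE,  TRUE,  FALSE,
  "v.7",  TRUE,  FALSE, TRUE,  TRUE,  TRUE,
  "v.8",  TRUE,  FALSE, FALSE, TRUE,  TRUE,
  "v.9",  TRUE,  FALSE, TRUE,  TRUE,  FALSE,
  "v.10", TRUE,  TRUE,  FALSE, FALSE, TRUE,
  "v.11", FALSE, FALSE, FALSE, FALSE, TRUE,
  "v.12", FALSE, FALSE, FALSE, FALSE, FALSE,
  "v.13", FALSE, FALSE, FALSE, FALSE, FALSE,
  "v.14", TRUE,  TRUE,  TRUE,  TRUE,  FALSE,
  "v.16", FALSE, TRUE,  TRUE,  TRUE,  TRUE,
  "v.17", FALSE, TRUE,  TRUE,  TRUE,  TRUE,
  "v.18", FALSE, FALSE, TRUE,  TRUE,  TRUE,
  "v.19", FALSE, TRUE,  FALSE, TRUE,  TRUE,
  "v.20", FALSE, FALSE, FALSE, TRUE,  TRUE,
  "v.21", FALSE, FALSE, TRUE,  TRUE,  FALSE,
  "v.22", FALSE, FALSE, FALSE, TRUE,  TRUE,
  "v.23", FALSE, FALSE, FALSE, FALSE, TRUE,
  "v.24", FALSE, FALSE, TRUE,  TRUE,  TRUE)

# write a minimal single-record SAM for hand-built CIGAR cases
write_test_sam <- function(path, records,
                           contig = fx$model$contig,
                           len = sum(Biostrings::width(fx$genome))) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", contig, "\tLN:", len))
  readr::write_lines(c(header, records), path)
  path
}

sam_record <- function(id, pos, cigar, seq,
                       contig = fx$model$contig, flag = 0L, mapq = 60L) {
  paste(id, flag, contig, pos, mapq, cigar, "*", 0L, 0L, seq,
        strrep("I", nchar(seq)), sep = "\t")
}
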