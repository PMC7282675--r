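# Shared fixtures built in code. Cohort simulations are cached per test run
# because several files exercise the same cohort.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (is.null(.sim_cache[[name]])) .sim_cache[[name]] <- fn()
  .sim_cache[[name]]
}

noise_free_sim <- function() {
  cached("nf", function() {
    simulate_cohort(sim_config(seed = 11, caller_fp_rate = 0,
                               caller_fn_rate = 0,
                               deterministic_counts = TRUE))
  })
}

noise_free_result <- function() {
  cached("nf_res", function() {
    suppressMessages(run_met_pipeline(noise_free_sim()))
  })
}

default_sim <- function() {
  cached("default", function() simulate_cohort(sim_config(seed = 5)))
}

empty_segs <- function() {
  tibble::tibble(sample_id = character(), chrom = character(),
                 start = integer(), end = integer(), state = character(),
                 affected_allele = character())
}

empty_snvs <- function() {
  tibble::tibble(sample_id = character(), chrom = character(),
                 pos = integer())
}

# A single-exon toy gene whose CDS is given explicitly; minus-strand genes
# store the reverse complement on the genomic plus strand.
toy_gene <- function(cds, strand = "+", chrom = "chrT", start = 100L,
                     flank = 6L, gene = "toy", family = NA_character_) {
  stopifnot(nchar(cds) %% 3 == 0)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  genomic_cds <- if (strand == "+") cds else revcomp(cds)
  set.seed(nchar(cds))
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  seq <- paste0(pad(flank), genomic_cds, pad(flank))
  tibble::tibble(
    chrom = chrom, start = start, end = start + nchar(seq),
    gene = gene, family = family, strand = strand,
    transcript = paste0("tx_", gene),
    exon_starts = list(start + flank),
    exon_ends = list(start + flank + nchar(cds)),
    frames = list(0L),
    seq = seq)
}

# Independent brute-force oracle: mutate the full CDS, translate both
# versions with Biostrings, and diff the amino acids.
brute_force_aa_change <- function(cds, strand, genomic_offset, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cds_vec <- strsplit(cds, "")[[1]]
  i <- if (strand == "+") genomic_offset + 1L else nchar(cds) - genomic_offset
  base <- if (strand == "+") alt else unname(comp[alt])
  mut <- cds_vec
  mut[i] <- base
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                               no.init.codon = TRUE))
  aa_mut <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(mut, collapse = "")), no.init.codon = TRUE))
  codon <- (i - 1L) %/% 3L + 1L
  paste0(substr(aa_ref, codon, codon), codon, substr(aa_mut, codon, codon))
}

random_calls <- function(n, seed = 1, samples = "S1",
                         callers = c("mpileup", "mutect2", "strelka"),
                         n_pos = 50) {
  set.seed(seed)
  depth <- rpois(n, 40) + 1L
  alt_n <- rbinom(n, depth, 0.4)
  tibble::tibble(
    sample_id = sample(samples, n, replace = TRUE),
    caller = sample(callers, n, replace = TRUE),
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample.int(n_pos, n, replace = TRUE) * 10L,
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = "N",
    qual = round(runif(n, 0, 90), 1),
    ref_count = depth - alt_n,
    alt_count = alt_n) |>
    dplyr::mutate(alt = ifelse(ref == "A", "G", "A"),
                  vaf = alt_count / (ref_count + alt_count)) |>
    dplyr::distinct(sample_id, caller, chrom, pos, .keep_all = TRUE)
}

# Cheap fingerprint-level cohort generator for clonality replicates: each
# animal gets truncal SNVs (PT + LMs) and subclone-private SNVs (LMs only),
# with subclones separated by >= 10 features.
sim_fingerprint_cohort <- function(seed, n_animals = 5, mets = 4,
                                   truncal = 5, subclone = 12) {
  set.seed(seed)
  sheet <- dplyr::bind_rows(lapply(seq_len(n_animals), function(i) {
    a <- sprintf("M%02d", i)
    tibble::tibble(
      sample_id = c(paste0(a, "_PT"), paste0(a, "_LM", seq_len(mets))),
      animal_id = a,
      tissue = c("PT", rep("LM", mets)),
      strain_cross = "F1", partner_strain = "C57BL/6J",
      platforms = "exome")
  }))
  poly <- runif(n_animals) < 0.5
  pos_counter <- 0L
  new_sites <- function(k) {
    pos_counter <<- pos_counter + k
    seq(pos_counter - k + 1L, pos_counter) * 100L
  }
  snvs <- list()
  for (i in seq_len(n_animals)) {
    a <- sprintf("M%02d", i)
    ids <- sheet$sample_id[sheet$animal_id == a]
    lm <- ids[-1]
    tr <- new_sites(truncal)
    for (s in ids) snvs[[length(snvs) + 1]] <-
      tibble::tibble(sample_id = s, chrom = "chr1", pos = tr)
    if (poly[i]) {
      half <- ceiling(length(lm) / 2)
      for (grp in list(lm[seq_len(half)], lm[-seq_len(half)])) {
        sc <- new_sites(subclone)
        for (s in grp) snvs[[length(snvs) + 1]] <-
          tibble::tibble(sample_id = s, chrom = "chr1", pos = sc)
      }
    } else {
      sc <- new_sites(subclone)
      for (s in lm) snvs[[length(snvs) + 1]] <-
        tibble::tibble(sample_id = s, chrom = "chr1", pos = sc)
    }
  }
  truth <- tibble::tibble(
    animal_id = sprintf("M%02d", seq_len(n_animals)),
    verdict = ifelse(poly, "polyclonal_seeding", "monoclonal_seeding"))
  list(sheet = sheet, snvs = dplyr::bind_rows(snvs), truth = truth)
}
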