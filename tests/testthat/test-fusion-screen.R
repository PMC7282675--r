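rand_candidates <- function(seed, n, sample_ids = c("L1", "L2"),
                            genes = paste0("g", 1:8)) {
  set.seed(seed)
  g1 <- sample(genes, n, replace = TRUE)
  g2 <- sample(genes, n, replace = TRUE)
  swap <- g1 > g2
  tmp <- g1[swap]; g1[swap] <- g2[swap]; g2[swap] <- tmp
  tibble::tibble(
    sample_id = sample(sample_ids, n, replace = TRUE), source = "rna",
    chrom1 = "chr1", pos1 = sample.int(1e6, n), strand1 = "+",
    chrom2 = "chr2", pos2 = sample.int(1e6, n), strand2 = "+",
    sv_type = "fusion", read_count = sample.int(20, n, replace = TRUE),
    gene1 = g1, gene2 = g2, gene_read_total = 1000L,
    candidate_id = seq_len(n))
}

test_that("LM/PT partition matches brute-force unordered-pair matching", {
  for (seed in 1:10) {
    lm <- rand_candidates(seed, 20)
    pt <- rand_candidates(seed + 50, 12, sample_ids = "P1")
    part <- met_specific_set(lm, pt)
    key <- function(x) paste(pmin(x$gene1, x$gene2), pmax(x$gene1, x$gene2))
    in_pt <- key(lm) %in% key(pt)
    expect_equal(part$shared, lm[in_pt, ])
    expect_equal(part$lm_only, lm[!in_pt, ])
    # partition conservation on both sides
    expect_equal(nrow(part$shared) + nrow(part$lm_only), nrow(lm))
    expect_equal(nrow(part$pt_shared) + nrow(part$pt_only), nrow(pt))
  }
  # disjoint gene universes share nothing
  part <- met_specific_set(rand_candidates(1, 10),
                           rand_candidates(2, 10, sample_ids = "P1",
                                           genes = paste0("h", 1:8)))
  expect_equal(nrow(part$shared), 0)
})

test_that("gene-less candidates match on breakpoints within tolerance", {
  bp <- tibble::tibble(
    sample_id = "L1", source = "wgs", chrom1 = "chr1", pos1 = 1000L,
    strand1 = NA, chrom2 = "chr1", pos2 = 50000L, strand2 = NA,
    sv_type = "DEL", read_count = 5L, gene1 = NA_character_,
    gene2 = NA_character_, gene_read_total = NA_integer_,
    candidate_id = 1L)
  near <- dplyr::mutate(bp, sample_id = "P1", pos1 = 1080L, pos2 = 49950L)
  far <- dplyr::mutate(bp, sample_id = "P1", pos1 = 1500L)
  expect_equal(nrow(met_specific_set(bp, near, match_tolerance = 100)$shared), 1)
  expect_equal(nrow(met_specific_set(bp, far, match_tolerance = 100)$shared), 0)
})

test_that("read-through detection requires adjacency, strand and collinearity", {
  sim <- noise_free_sim()
  cand <- as_sv_candidates(rna = sim$fusion_rna, wgs = sim$sv_wgs,
                           genes = sim$genes)
  truth <- sim$truth$fusions
  key <- function(x, g1, g2) paste(x$sample_id, pmin(g1, g2), pmax(g1, g2))
  rt_truth <- unique(key(truth, truth$gene1, truth$gene2)[
    truth$class == "read_through"])
  flag <- is_readthrough(cand, sim$genes)
  expect_setequal(unique(key(cand, cand$gene1, cand$gene2)[flag]), rt_truth)
  # opposite strands break the read-through interpretation
  rt <- cand[flag, ][1, ]
  genes2 <- sim$genes
  genes2$strand[genes2$gene == rt$gene1] <- "-"
  genes2$strand[genes2$gene == rt$gene2] <- "+"
  expect_false(is_readthrough(rt, genes2))
})

test_that("support and distance thresholds are closed at the stated bounds", {
  genes <- noise_free_sim()$genes
  g <- genes[genes$chrom == "chr1", ][1, ]
  base <- tibble::tibble(
    sample_id = "L1", source = "wgs", chrom1 = g$chrom,
    pos1 = g$start + 100L, strand1 = NA, chrom2 = g$chrom,
    pos2 = g$start + 100L + 9999L, strand2 = NA, sv_type = "DEL",
    read_count = 3L, gene1 = g$gene, gene2 = g$gene,
    gene_read_total = NA_integer_, candidate_id = 1L)
  at10k <- dplyr::mutate(base, pos2 = pos1 + 10000L)
  lowread <- dplyr::mutate(at10k, read_count = 2L)
  flags <- support_distance_flags(dplyr::bind_rows(base, at10k, lowread),
                                  genes)
  expect_equal(flags$pass_distance, c(FALSE, TRUE, TRUE))
  expect_equal(flags$pass_support, c(TRUE, TRUE, FALSE))
  # interchromosomal candidates always pass the distance rule
  inter <- dplyr::mutate(base, chrom2 = "chr2", pos2 = pos1)
  expect_true(support_distance_flags(inter, genes)$pass_distance)
  # a breakpoint far from any gene fails gene proximity
  lost <- dplyr::mutate(at10k, pos2 = 4.99e6)
  expect_false(support_distance_flags(lost, genes)$pass_gene_proximity)
  # survivors equal the brute-force predicate conjunction
  set.seed(9)
  rnd <- rand_candidates(9, 40)
  rnd$chrom2 <- "chr1"
  rnd$pos1 <- sample(as.integer(genes$start[genes$chrom == "chr1"]), 40,
                     replace = TRUE) + 500L
  rnd$pos2 <- rnd$pos1 + sample.int(30000L, 40)
  f <- support_distance_flags(rnd, genes)
  ok <- f$pass_support & f$pass_distance & f$pass_gene_proximity
  brute <- vapply(seq_len(40), function(i) {
    near <- function(p) any(genes$chrom == "chr1" &
                              genes$start + 1L - 10000L <= p &
                              genes$end + 10000L >= p)
    rnd$read_count[i] >= 3 && (rnd$pos2[i] - rnd$pos1[i]) >= 10000 &&
      near(rnd$pos1[i]) && near(rnd$pos2[i])
  }, logical(1))
  expect_equal(ok, brute)
})

test_that("repeat classification equals point-in-interval lookup", {
  repeats <- tibble::tibble(chrom = "chr1", start = c(100L, 500L),
                            end = c(200L, 600L), name = c("r1", "r2"))
  mk <- function(p1, p2) {
    tibble::tibble(sample_id = "L1", source = "wgs", chrom1 = "chr1",
                   pos1 = p1, strand1 = NA, chrom2 = "chr1", pos2 = p2,
                   strand2 = NA, sv_type = "DEL", read_count = 5L,
                   gene1 = "a", gene2 = "b",
                   gene_read_total = NA_integer_, candidate_id = 1L)
  }
  expect_identical(classify_repeats(mk(150L, 550L), repeats), "both_repeat")
  expect_identical(classify_repeats(mk(150L, 900L), repeats), "one_repeat")
  expect_identical(classify_repeats(mk(900L, 901L), repeats), "single_copy")
  # half-open boundaries: pos 200 (1-based) is inside [100,200)? pos0 = 199
  expect_identical(classify_repeats(mk(200L, 900L), repeats), "one_repeat")
  expect_identical(classify_repeats(mk(201L, 900L), repeats), "single_copy")
  set.seed(4)
  cand <- dplyr::bind_rows(lapply(sample.int(1000L, 50), function(p)
    mk(p, sample.int(1000L, 1))))
  got <- classify_repeats(cand, repeats)
  inr <- function(p) (p > 100L & p <= 200L) | (p > 500L & p <= 600L)
  want <- ifelse(inr(cand$pos1) & inr(cand$pos2), "both_repeat",
                 ifelse(inr(cand$pos1) | inr(cand$pos2), "one_repeat",
                        "single_copy"))
  expect_identical(got, want)
})

test_that("family classification uses the map with unassigned fallback", {
  fam <- tibble::tibble(gene = c("famA_1", "famA_2", "solo1"),
                        family = c("famA", "famA", "soloF"))
  mk <- function(g1, g2) {
    tibble::tibble(sample_id = "L1", source = "wgs", chrom1 = "chr1",
                   pos1 = 1L, strand1 = NA, chrom2 = "chr2", pos2 = 2L,
                   strand2 = NA, sv_type = "ITX", read_count = 5L,
                   gene1 = g1, gene2 = g2, gene_read_total = NA_integer_,
                   candidate_id = 1L)
  }
  expect_identical(classify_family(mk("famA_1", "famA_2"), fam),
                   "same_family")
  expect_identical(classify_family(mk("famA_1", "solo1"), fam),
                   "different_family")
  expect_identical(classify_family(mk("famA_1", "unknown9"), fam),
                   "unassigned")
  expect_identical(
    classify_family(mk("Ddx1", "Ddx2"), fam, use_prefix_heuristic = TRUE),
    "same_family")
})

test_that("recurrence classes and read fractions are computed per cohort", {
  sheet <- tibble::tibble(sample_id = c("a1_LM", "a2_LM"),
                          animal_id = c("a1", "a2"), tissue = "LM",
                          strain_cross = "F1", partner_strain = "X",
                          platforms = "rna")
  mk <- function(sid, g1, g2, reads = 5L, total = 1000L) {
    tibble::tibble(sample_id = sid, source = "rna", chrom1 = "chr1",
                   pos1 = 1L, strand1 = "+", chrom2 = "chr2", pos2 = 2L,
                   strand2 = "+", sv_type = "fusion",
                   read_count = reads, gene1 = g1, gene2 = g2,
                   gene_read_total = total, candidate_id = 1L)
  }
  cand <- dplyr::bind_rows(
    mk("a1_LM", "gA", "gB"), mk("a2_LM", "gA", "gB"),   # 2 animals
    mk("a1_LM", "gC", "gD"), mk("a1_LM", "gC", "gE"),   # multi-partner
    mk("a2_LM", "gF", "gG", reads = 5L, total = 1000L)) # single, 0.5%
  out <- recurrence_and_fraction(cand, sheet)
  expect_identical(out$recurrence[1:2], c("multi_animal", "multi_animal"))
  expect_identical(out$recurrence[3:4], c("multi_partner", "multi_partner"))
  expect_identical(out$recurrence[5], "single")
  expect_equal(out$read_fraction[5], 0.005)
  expect_true(out$low_fraction[5])
  expect_warning(
    recurrence_and_fraction(dplyr::mutate(cand, gene_read_total = NA_integer_),
                            sheet),
    "gene_read_total")
})

test_that("the audit keeps every candidate and excludes planted artifacts", {
  sim <- noise_free_sim()
  res <- noise_free_result()
  audit <- res$fusion_audit
  # audit completeness: one row per metastasis-specific input candidate
  expect_equal(nrow(audit), nrow(res$fusion_partition$lm_only))
  expect_equal(anyDuplicated(audit$candidate_id), 0)
  truth <- sim$truth$fusions
  tkey <- paste(truth$sample_id, truth$source,
                pmin(truth$gene1, truth$gene2),
                pmax(truth$gene1, truth$gene2))
  akey <- paste(audit$sample_id, audit$source,
                pmin(audit$gene1, audit$gene2),
                pmax(audit$gene1, audit$gene2))
  cls <- truth$class[match(akey, tkey)]
  expect_true(all(!is.na(cls)))
  # planted true events survive; every artifact class is excluded
  expect_true(all(audit$final_keep[cls == "true_event"]))
  expect_true(all(!audit$final_keep[cls != "true_event"]))
  expect_true(all(audit$readthrough[cls == "read_through"]))
  expect_true(all(audit$repeat_class[cls == "repeat_breakpoint"] ==
                    "both_repeat"))
  expect_true(all(audit$family_class[cls == "gene_family"] == "same_family"))
})

test_that("raising support/distance thresholds never adds survivors", {
  sim <- noise_free_sim()
  cand <- as_sv_candidates(rna = sim$fusion_rna, genes = sim$genes)
  n_prev <- Inf
  for (r in c(1, 3, 6, 10)) {
    f <- support_distance_flags(cand, sim$genes, min_reads = r)
    n <- sum(f$pass_support)
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- Inf
  for (d in c(0, 5000, 10000, 50000)) {
    f <- support_distance_flags(cand, sim$genes, min_partner_distance = d)
    n <- sum(f$pass_distance)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})
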