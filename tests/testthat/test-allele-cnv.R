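test_that("bin boundaries follow half-open 4000-bp tiles", {
  counts <- tibble::tibble(chrom = "chr1", pos = c(100L, 3900L, 4100L),
                           count_A = 10L, count_B = 10L)
  bins <- bin_allele_counts(counts, bin_size = 4000, min_snps = 1)
  expect_equal(bins$bin_start, c(0L, 4000L))
  expect_equal(bins$n_snps, c(2L, 1L))
  expect_true(all(abs(bins$baf - 0.5) < 1e-9))
})

test_that("bin aggregates equal brute-force grouping", {
  set.seed(5)
  counts <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 500, replace = TRUE),
    pos = sample.int(100000L, 500),
    count_A = rpois(500, 20), count_B = rpois(500, 20))
  bins <- bin_allele_counts(counts, bin_size = 4000, min_snps = 3)
  key <- paste(counts$chrom, (counts$pos - 1L) %/% 4000L * 4000L)
  for (i in seq_len(nrow(bins))) {
    sel <- key == paste(bins$chrom[i], bins$bin_start[i])
    expect_equal(bins$count_A[i], sum(counts$count_A[sel]))
    expect_equal(bins$count_B[i], sum(counts$count_B[sel]))
    expect_equal(bins$n_snps[i], sum(sel))
    expect_equal(bins$informative[i], sum(sel) >= 3)
  }
  expect_equal(sum(bins$n_snps), 500)
})

make_baf_counts <- function(seed, p, state = "loss", allele = "partner",
                            seg = c(100000L, 300000L), chrom_len = 600000L,
                            depth = 40, snp_per_kb = 1.5) {
  set.seed(seed)
  pos <- sort(sample.int(chrom_len, round(chrom_len / 1000 * snp_per_kb)))
  eb <- expected_baf(p, paste0(state, "_of_B"))
  if (allele == "FVB") eb <- 1 - eb
  ratio <- if (state == "loss") (2 - p) / 2 else (2 + p) / 2
  inside <- pos - 1L >= seg[1] & pos - 1L < seg[2]
  baf <- ifelse(inside, eb, 0.5)
  total <- pmax(1L, rpois(length(pos), depth * ifelse(inside, ratio, 1)))
  cb <- rbinom(length(pos), total, baf)
  tibble::tibble(chrom = "chr1", pos = pos, count_A = total - cb,
                 count_B = cb)
}

test_that("segment calling recovers a planted partner-allele loss", {
  counts <- make_baf_counts(1, p = 0.8)
  bins <- bin_allele_counts(counts)
  segs <- call_segments(bins, purity = 0.8)
  expect_equal(nrow(segs), 1)
  expect_identical(segs$state, "loss")
  expect_identical(segs$affected_allele, "partner")
  expect_gte(segs$n_snps, 200)
  eb <- expected_baf(0.8, "loss_of_B")
  se <- sqrt(eb * (1 - eb) / (segs$n_snps * 40 * 0.6))
  expect_lt(abs(segs$mean_baf - eb), 4 * se + 0.005)
  # boundaries recovered within one bin
  expect_lte(abs(segs$start - 100000L), 4000L)
  expect_lte(abs(segs$end - 300000L), 4000L)
})

test_that("the symmetric FVB-allele gain is called with alleles swapped", {
  counts <- make_baf_counts(2, p = 0.8, state = "gain", allele = "FVB")
  segs <- call_segments(bin_allele_counts(counts), purity = 0.8)
  expect_equal(nrow(segs), 1)
  expect_identical(segs$state, "gain")
  expect_identical(segs$affected_allele, "FVB")
  expect_lt(segs$mean_baf, 0.5)
})

test_that("flat BAF yields no segments and purity is validated", {
  counts <- make_baf_counts(3, p = 0.8, seg = c(0L, 0L))
  bins <- bin_allele_counts(counts)
  expect_equal(nrow(call_segments(bins, purity = 0.9)), 0)
  expect_error(call_segments(bins, purity = 0), "purity")
  expect_error(call_segments(bins, purity = 1.2), "purity")
})

test_that("segment mean BAF converges to the mixture value with SNP density", {
  errs <- vapply(c(1.5, 3, 6), function(dens) {
    counts <- make_baf_counts(7, p = 0.7, snp_per_kb = dens)
    segs <- call_segments(bin_allele_counts(counts), purity = 0.7)
    if (nrow(segs) == 0) return(NA_real_)
    abs(segs$mean_baf[1] - expected_baf(0.7, "loss_of_B"))
  }, numeric(1))
  expect_true(all(!is.na(errs)))
  expect_lt(errs[3], errs[1])
})

test_that("metastasis-specific subtraction equals the brute-force overlap rule", {
  rand_segs <- function(seed, n, sample_id) {
    set.seed(seed)
    start <- sample.int(50L, n) * 1000L
    tibble::tibble(sample_id = sample_id, chrom = sample(c("chr1", "chr2"),
                                                         n, replace = TRUE),
                   start = start, end = start + sample.int(20L, n) * 1000L,
                   state = sample(c("loss", "gain"), n, replace = TRUE),
                   affected_allele = sample(c("partner", "FVB"), n,
                                            replace = TRUE))
  }
  for (seed in 1:15) {
    lm <- rand_segs(seed, 12, "LM1")
    pt <- rand_segs(seed + 100, 12, "PT1")
    out <- met_specific_segments(lm, pt, reciprocal_overlap = 0.5)
    keep <- vapply(seq_len(nrow(lm)), function(i) {
      !any(vapply(seq_len(nrow(pt)), function(j) {
        if (lm$chrom[i] != pt$chrom[j]) return(FALSE)
        if (lm$state[i] != pt$state[j]) return(FALSE)
        if (lm$affected_allele[i] != pt$affected_allele[j]) return(FALSE)
        ov <- min(lm$end[i], pt$end[j]) - max(lm$start[i], pt$start[j])
        ov > 0 && ov / (lm$end[i] - lm$start[i]) >= 0.5 &&
          ov / (pt$end[j] - pt$start[j]) >= 0.5
      }, logical(1)))
    }, logical(1))
    expect_equal(out, lm[keep, ])
  }
  # identical segment removed; LM-only segment kept
  seg <- tibble::tibble(sample_id = "LM1", chrom = "chr1", start = 0L,
                        end = 10000L, state = "loss",
                        affected_allele = "partner")
  expect_equal(nrow(met_specific_segments(seg, dplyr::mutate(
    seg, sample_id = "PT1"))), 0)
  expect_equal(nrow(met_specific_segments(seg, seg[0, ])), 1)
})

test_that("recurrent regions match per-base brute-force counting", {
  sheet <- tibble::tibble(sample_id = paste0("s", 1:4),
                          animal_id = paste0("a", c(1, 1, 2, 3)),
                          tissue = "LM", strain_cross = "F1",
                          partner_strain = "X", platforms = "exome")
  seg <- function(s, start, end, state = "loss") {
    tibble::tibble(sample_id = s, chrom = "chr1", start = start, end = end,
                   state = state, affected_allele = "partner")
  }
  # worked example: [1000,5000) and [3000,8000) from two animals
  two <- dplyr::bind_rows(seg("s1", 1000L, 5000L), seg("s3", 3000L, 8000L))
  out <- recurrent_regions(two, sheet, min_freq = 2)
  expect_equal(out$start, 3000L)
  expect_equal(out$end, 5000L)
  expect_equal(out$overlap_length, 2000L)
  expect_equal(out$freq, 2L)
  expect_identical(out$supporters, "a1,a2")
  # one animal only -> empty (two lesions of one animal do not count twice)
  one <- dplyr::bind_rows(seg("s1", 1000L, 5000L), seg("s2", 3000L, 8000L))
  expect_equal(nrow(recurrent_regions(one, sheet, min_freq = 2)), 0)
  # randomized staggered segments: per-base animal counts agree everywhere
  for (rep in 1:10) {
    set.seed(rep)
    n <- 8
    rnd <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      st <- sample.int(200L, 1) * 10L
      seg(sample(sheet$sample_id, 1), st, st + sample.int(100L, 1) * 10L)
    }))
    out <- recurrent_regions(rnd, sheet, min_freq = 2)
    rnd <- dplyr::left_join(rnd, sheet[, c("sample_id", "animal_id")],
                            by = "sample_id")
    max_end <- max(rnd$end)
    for (b in seq(0L, max_end, by = 10L)) {
      n_animals <- length(unique(
        rnd$animal_id[rnd$start <= b & rnd$end > b]))
      in_region <- out[out$start <= b & out$end > b, ]
      if (n_animals >= 2) {
        expect_equal(nrow(in_region), 1)
        expect_equal(in_region$freq, n_animals)
      } else {
        expect_equal(nrow(in_region), 0)
      }
    }
  }
})

test_that("recurrent regions are invariant to order and segment splitting", {
  sheet <- tibble::tibble(sample_id = paste0("s", 1:3),
                          animal_id = paste0("a", 1:3), tissue = "LM",
                          strain_cross = "F1", partner_strain = "X",
                          platforms = "exome")
  segs <- tibble::tibble(sample_id = c("s1", "s2", "s3"), chrom = "chr1",
                         start = c(0L, 2000L, 5000L),
                         end = c(9000L, 12000L, 14000L), state = "loss",
                         affected_allele = "partner")
  base <- recurrent_regions(segs, sheet)
  shuffled <- recurrent_regions(segs[c(3, 1, 2), ], sheet)
  expect_equal(base, shuffled)
  split1 <- dplyr::bind_rows(
    dplyr::mutate(segs[1, ], end = 4000L),
    dplyr::mutate(segs[1, ], start = 4000L),
    segs[2:3, ])
  expect_equal(recurrent_regions(split1, sheet), base)
})

test_that("genes are assigned to regions by flanked overlap", {
  genes <- tibble::tibble(chrom = "chr1", start = c(1000L, 50000L),
                          end = c(2000L, 51000L),
                          gene = c("inG", "farG"), family = NA,
                          strand = "+", transcript = c("t1", "t2"),
                          exon_starts = list(1000L, 50000L),
                          exon_ends = list(2000L, 51000L),
                          frames = list(0L, 0L), seq = "")
  region <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L,
                           state = "loss", overlap_length = 10000L,
                           freq = 2L, supporters = "a1,a2")
  # gene fully inside the region is assigned; farG ([50000,51000) + 10 kb
  # flank) stays 30 kb away and is not
  hit <- assign_region_genes(region, genes, flank = 10000)
  expect_identical(hit$gene, "inG")
  hit2 <- assign_region_genes(region, genes, flank = 50000)
  expect_setequal(hit2$gene, c("inG", "farG"))
  # boundary: the flank must actually reach the region; one bp short fails
  edge <- tibble::tibble(chrom = "chr1", start = 20000L, end = 21000L,
                         state = "loss", overlap_length = 1000L, freq = 2L,
                         supporters = "a1,a2")
  g <- genes[1, ]  # span [1000,2000)
  expect_equal(nrow(assign_region_genes(edge, g, flank = 18001)), 1)
  expect_equal(nrow(assign_region_genes(edge, g, flank = 18000)), 0)
})

test_that("homozygous-background samples are refused", {
  sheet <- tibble::tibble(sample_id = c("f1", "fvb"),
                          animal_id = c("a1", "a2"), tissue = "LM",
                          strain_cross = c("F1", "FVB_homozygous"),
                          partner_strain = c("C57BL/6J", NA),
                          platforms = "exome")
  counts <- tibble::tibble(sample_id = "fvb", chrom = "chr1",
                           pos = (1:100) * 500L, count_A = 20L,
                           count_B = 20L)
  expect_error(call_cnv_segments(counts, sheet), "homozygous")
})
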