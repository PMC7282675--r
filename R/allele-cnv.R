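#' Bin strain-informative allele counts into fixed genomic tiles
#'
#' Aggregates heterozygous-SNP allele counts into 0-based half-open tiles
#' `[k*bin_size, (k+1)*bin_size)`. Bins with fewer than `min_snps` SNPs are
#' flagged uninformative and are ignored by segmentation.
#'
#' @param counts Tibble with `chrom`, `pos` (1-based), `count_A` (FVB
#'   allele), `count_B` (partner allele); may carry a `sample_id` column,
#'   in which case binning is per sample.
#' @param bin_size Tile width in bp (default 4000).
#' @param min_snps Minimum SNPs for an informative bin (default 3).
#' @return Per-bin tibble with summed counts, `baf`
#'   (`count_B / (count_A + count_B)`), `n_snps`, mean `depth` per SNP and
#'   an `informative` flag.
#' @export
bin_allele_counts <- function(counts, bin_size = 4000, min_snps = 3) {
  counts <- as_tibble(counts)
  grouping <- intersect("sample_id", names(counts))
  counts %>%
    mutate(bin_start = (as.integer(.data$pos) - 1L) %/%
             as.integer(bin_size) * as.integer(bin_size)) %>%
    group_by(across(all_of(c(grouping, "chrom", "bin_start")))) %>%
    summarise(count_A = sum(.data$count_A),
              count_B = sum(.data$count_B),
              n_snps = n(),
              depth = (sum(.data$count_A) + sum(.data$count_B)) / n(),
              .groups = "drop") %>%
    mutate(bin_end = .data$bin_start + as.integer(bin_size),
           baf = .data$count_B / (.data$count_A + .data$count_B),
           informative = .data$n_snps >= min_snps) %>%
    select(all_of(grouping), "chrom", "bin_start", "bin_end", "n_snps",
           "count_A", "count_B", "depth", "baf", "informative") %>%
    arrange(across(all_of(c(grouping, "chrom", "bin_start"))))
}

#' Call allele-specific copy-number segments from binned BAF
#'
#' Runs of at least `min_consecutive_bins` informative bins whose BAF
#' deviates from 0.5 by more than `baf_delta` in the same direction are
#' merged into segments (up to `max_bin_gap` uninformative or missing bins
#' may interrupt a run). The direction of the BAF deviation names the
#' affected parental allele, and the depth ratio (bin depth over the
#' sample's median informative bin depth) decides loss versus gain: ratio
#' below `1 - depth_ratio_eps` is a loss, above `1 + depth_ratio_eps` a
#' gain. When the ratio is inconclusive the segment is reported under the
#' loss interpretation with `confidence = "low"` and the affected allele is
#' the under-represented one.
#'
#' Samples from a homozygous (FVB x FVB) background carry no informative
#' heterozygous SNPs and must not be segmented; use the `sample_sheet`
#' argument of [call_cnv_segments()] to enforce this.
#'
#' @param bins Output of [bin_allele_counts()] for one sample.
#' @param purity Tumor-cell fraction in `(0, 1]`; used to annotate the
#'   expected BAF of each segment.
#' @param baf_delta Minimum `|baf - 0.5|` for a bin to be non-neutral
#'   (default 0.1).
#' @param min_consecutive_bins Minimum run length in informative bins
#'   (default 5).
#' @param depth_ratio_eps Dead band around a depth ratio of 1 (default
#'   0.05).
#' @param max_bin_gap Maximum interrupting (neutral, sparse or missing)
#'   bins inside a run (default 4).
#' @return Tibble of segments: `chrom`, `start`, `end`, `state`,
#'   `affected_allele`, `mean_baf`, `mean_depth_ratio`, `n_snps`, `n_bins`,
#'   `confidence`, `expected_baf`.
#' @export
call_segments <- function(bins, purity, baf_delta = 0.1,
                          min_consecutive_bins = 5, depth_ratio_eps = 0.05,
                          max_bin_gap = 4) {
  if (purity <= 0 || purity > 1) abort("purity must be in (0, 1]")
  bins <- as_tibble(bins) %>% filter(.data$informative)
  if (nrow(bins) == 0) return(empty_segments())
  med_depth <- stats::median(bins$depth)
  bins <- bins %>%
    mutate(direction = case_when(
      .data$baf < 0.5 - baf_delta ~ -1L,  # partner under-represented
      .data$baf > 0.5 + baf_delta ~ 1L,
      TRUE ~ 0L))
  segs <- list()
  for (ch in unique(bins$chrom)) {
    # neutral and uninformative bins both count toward the tolerated gap
    b <- bins %>%
      filter(.data$chrom == ch, .data$direction != 0L) %>%
      arrange(.data$bin_start)
    if (nrow(b) == 0) next
    bin_size <- b$bin_end[1] - b$bin_start[1]
    run <- integer(0)
    flush <- function(run) {
      if (length(run) >= min_consecutive_bins) {
        rb <- b[run, ]
        ratio <- mean(rb$depth) / med_depth
        dir <- rb$direction[1]
        state <- if (ratio < 1 - depth_ratio_eps) "loss"
                 else if (ratio > 1 + depth_ratio_eps) "gain"
                 else "loss"
        confidence <- if (abs(ratio - 1) <= depth_ratio_eps) "low" else "high"
        # under-represented allele is lost; over-represented allele gained
        allele <- if (state == "loss") {
          if (dir < 0) "partner" else "FVB"
        } else {
          if (dir > 0) "partner" else "FVB"
        }
        exp_state <- if (state == "loss") "loss_of_B" else "gain_of_B"
        eb <- expected_baf(purity, exp_state)
        if (allele == "FVB") eb <- 1 - eb
        segs[[length(segs) + 1]] <<- tibble(
          chrom = ch, start = rb$bin_start[1], end = rb$bin_end[nrow(rb)],
          state = state, affected_allele = allele,
          mean_baf = sum(rb$count_B) / sum(rb$count_A + rb$count_B),
          mean_depth_ratio = ratio,
          n_snps = sum(rb$n_snps), n_bins = nrow(rb),
          confidence = confidence, expected_baf = eb)
      }
    }
    for (i in seq_len(nrow(b))) {
      if (length(run) == 0) { run <- i; next }
      gap_bins <- (b$bin_start[i] - b$bin_end[run[length(run)]]) / bin_size
      if (b$direction[i] == b$direction[run[1]] && gap_bins <= max_bin_gap) {
        run <- c(run, i)
      } else {
        flush(run); run <- i
      }
    }
    flush(run)
  }
  if (length(segs) == 0) return(empty_segments())
  bind_rows(segs) %>% arrange(.data$chrom, .data$start)
}

#' @noRd
empty_segments <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         state = character(), affected_allele = character(),
         mean_baf = double(), mean_depth_ratio = double(),
         n_snps = integer(), n_bins = integer(), confidence = character(),
         expected_baf = double())
}

#' Segment every F1 sample of a cohort
#'
#' Convenience wrapper running [bin_allele_counts()] and [call_segments()]
#' per sample. Samples on a homozygous FVB background are refused: CNV
#' calls on a genome without strain-informative heterozygous SNPs are not
#' trustworthy.
#'
#' @param allele_counts Allele-count tibble with `sample_id`.
#' @param sample_sheet Cohort sample sheet.
#' @param purity Named numeric vector of per-sample purities, or a single
#'   value recycled to all samples.
#' @inheritParams call_segments
#' @inheritParams bin_allele_counts
#' @return Segments tibble with a `sample_id` column.
#' @export
call_cnv_segments <- function(allele_counts, sample_sheet, purity = 0.8,
                              bin_size = 4000, min_snps = 3, baf_delta = 0.1,
                              min_consecutive_bins = 5) {
  ids <- unique(allele_counts$sample_id)
  homo <- sample_sheet$sample_id[sample_sheet$strain_cross == "FVB_homozygous"]
  bad <- intersect(ids, homo)
  if (length(bad) > 0) {
    abort(paste0("refusing allele-specific CNV calling on homozygous ",
                 "FVB background sample(s): ", paste(bad, collapse = ", ")))
  }
  if (length(purity) == 1 && is.null(names(purity))) {
    purity <- setNames(rep(purity, length(ids)), ids)
  }
  bind_rows(lapply(ids, function(sid) {
    bins <- bin_allele_counts(
      allele_counts %>% filter(.data$sample_id == sid),
      bin_size = bin_size, min_snps = min_snps)
    call_segments(bins, purity = unname(purity[sid]),
                  baf_delta = baf_delta,
                  min_consecutive_bins = min_consecutive_bins) %>%
      mutate(sample_id = sid, .before = 1)
  }))
}

#' @noRd
segments_granges <- function(segs) {
  GenomicRanges::GRanges(
    seqnames = segs$chrom,
    ranges = IRanges::IRanges(start = segs$start + 1L, end = segs$end))
}

#' Metastasis-specific segments by subtraction of the matched PT
#'
#' Keeps LM non-neutral segments with no PT segment of the same state and
#' affected allele at `>= reciprocal_overlap` mutual overlap fraction.
#'
#' @param lm_segments,pt_segments Segment tibbles for an animal's LM
#'   sample(s) and its PT sample(s).
#' @param reciprocal_overlap Minimum reciprocal overlap fraction for a PT
#'   segment to cancel an LM segment (default 0.5).
#' @return The LM segments that are metastasis-specific.
#' @export
met_specific_segments <- function(lm_segments, pt_segments,
                                  reciprocal_overlap = 0.5) {
  lm <- as_tibble(lm_segments)
  pt <- as_tibble(pt_segments)
  if (nrow(lm) == 0) return(lm)
  if (nrow(pt) == 0) return(lm)
  lg <- segments_granges(lm)
  pg <- segments_granges(pt)
  hits <- GenomicRanges::findOverlaps(lg, pg)
  drop <- rep(FALSE, nrow(lm))
  if (length(hits) > 0) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(lg)[qi],
                                             IRanges::ranges(pg)[si]))
    same <- lm$state[qi] == pt$state[si] &
      lm$affected_allele[qi] == pt$affected_allele[si]
    frac_lm <- ov / (lm$end[qi] - lm$start[qi])
    frac_pt <- ov / (pt$end[si] - pt$start[si])
    cancel <- same & frac_lm >= reciprocal_overlap &
      frac_pt >= reciprocal_overlap
    drop[unique(qi[cancel])] <- TRUE
  }
  lm[!drop, ]
}

#' Metastasis-specific segments for a whole cohort
#'
#' Applies [met_specific_segments()] per animal, comparing each animal's LM
#' segments against the union of its PT segments.
#'
#' @param segments Cohort segments tibble with `sample_id`.
#' @param sample_sheet Cohort sample sheet.
#' @inheritParams met_specific_segments
#' @return Metastasis-specific LM segments.
#' @export
cohort_met_specific_segments <- function(segments, sample_sheet,
                                         reciprocal_overlap = 0.5) {
  segs <- as_tibble(segments) %>%
    left_join(sample_sheet[, c("sample_id", "animal_id", "tissue")],
              by = "sample_id")
  bind_rows(lapply(unique(segs$animal_id), function(a) {
    lm <- segs %>% filter(.data$animal_id == a, .data$tissue == "LM")
    pt <- segs %>% filter(.data$animal_id == a, .data$tissue == "PT")
    met_specific_segments(lm, pt, reciprocal_overlap) %>%
      select(-"tissue")
  }))
}

#' Recurrent copy-number regions across animals
#'
#' For each state (losses and gains analyzed separately), each animal's
#' segments are collapsed to their genomic union, the per-base count of
#' supporting animals is computed, and the genome is decomposed into
#' maximal intervals of constant animal support with support
#' `>= min_freq`. Animals are counted once regardless of how many lesions
#' carry the segment.
#'
#' @param met_segments Metastasis-specific segments with `sample_id` (and
#'   `animal_id`, added from `sample_sheet` if missing).
#' @param sample_sheet Cohort sample sheet.
#' @param min_freq Minimum number of distinct supporting animals
#'   (default 2).
#' @return Tibble of regions: `chrom`, `start`, `end`, `state`,
#'   `overlap_length` (= region length), `freq` (distinct animals),
#'   `supporters` (comma-joined animal ids).
#' @export
recurrent_regions <- function(met_segments, sample_sheet = NULL,
                              min_freq = 2) {
  segs <- as_tibble(met_segments)
  if (!"animal_id" %in% names(segs)) {
    if (is.null(sample_sheet)) abort("supply `sample_sheet` for animal ids")
    segs <- segs %>%
      left_join(sample_sheet[, c("sample_id", "animal_id")], by = "sample_id")
  }
  out <- list()
  for (st in unique(segs$state)) {
    ss <- segs %>% filter(.data$state == st)
    for (ch in unique(ss$chrom)) {
      sc <- ss %>% filter(.data$chrom == ch)
      # per-animal genomic union on this chromosome (1-based IRanges)
      per_animal <- lapply(split(sc, sc$animal_id), function(x)
        IRanges::reduce(IRanges::IRanges(start = x$start + 1L, end = x$end)))
      animals <- names(per_animal)
      width <- max(vapply(per_animal, function(ir) max(IRanges::end(ir)),
                          numeric(1)))
      cov <- Reduce(`+`, lapply(per_animal, IRanges::coverage,
                                width = as.integer(width)))
      views <- IRanges::slice(cov, lower = min_freq)
      for (v in seq_along(views)) {
        # decompose each eligible stretch into runs of constant support
        piece <- views[[v]]
        rle_v <- S4Vectors::runValue(piece)
        len_v <- S4Vectors::runLength(piece)
        starts1 <- IRanges::start(views)[v] +
          cumsum(c(0L, utils::head(len_v, -1)))
        for (r in seq_along(rle_v)) {
          reg_start <- starts1[r] - 1L           # back to 0-based
          reg_end <- reg_start + len_v[r]
          sup <- animals[vapply(per_animal, function(ir) {
            any(IRanges::start(ir) <= reg_end &
                  IRanges::end(ir) >= reg_start + 1L)
          }, logical(1))]
          out[[length(out) + 1]] <- tibble(
            chrom = ch, start = as.integer(reg_start),
            end = as.integer(reg_end), state = st,
            overlap_length = as.integer(reg_end - reg_start),
            freq = as.integer(rle_v[r]),
            supporters = paste(sort(sup), collapse = ","))
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  state = character(), overlap_length = integer(),
                  freq = integer(), supporters = character()))
  }
  bind_rows(out) %>% arrange(.data$state, .data$chrom, .data$start)
}

#' Assign genes to recurrent regions by overlap with a flank
#'
#' A gene is assigned to a region when its span extended by `flank` bp on
#' both sides intersects the region. No enrichment statistic is computed.
#'
#' @param regions Recurrent-region tibble ([recurrent_regions()]).
#' @param genes Gene-model tibble.
#' @param flank Flank in bp added to each gene span (default 10000).
#' @return One row per (region, gene) assignment.
#' @export
assign_region_genes <- function(regions, genes, flank = 10000) {
  regions <- as_tibble(regions)
  if (nrow(regions) == 0 || nrow(genes) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  state = character(), gene = character()))
  }
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(pmax(1L, genes$start + 1L - as.integer(flank)),
                                                genes$end + as.integer(flank)))
  hits <- GenomicRanges::findOverlaps(rg, gg)
  tibble(chrom = regions$chrom[S4Vectors::queryHits(hits)],
         start = regions$start[S4Vectors::queryHits(hits)],
         end = regions$end[S4Vectors::queryHits(hits)],
         state = regions$state[S4Vectors::queryHits(hits)],
         gene = genes$gene[S4Vectors::subjectHits(hits)]) %>%
    distinct()
}
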