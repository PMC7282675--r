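#' Simulation configuration for a synthetic matched PT/LM cohort
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults encode the
#' study conditions the analysis assumes: exome-like mean depth of 40 reads,
#' tumor purity between 0.60 and 0.95, heterozygous metastasis-specific
#' drivers whose lesion VAF is purity/2 (so it lands in the 0.30-0.50
#' seeding-cell window), F1 crosses against four partner strains, and fusion
#' candidate lists mixing true events with three artifact classes
#' (read-through, repeat-breakpoint, gene-family).
#'
#' @param n_animals Number of animals in the cohort.
#' @param mets_per_animal Lung metastases sampled per animal (each animal
#'   additionally contributes one primary tumor sample).
#' @param strains Partner strains cycled across animals for the F1 crosses.
#' @param mean_depth Mean sequencing depth per site (reads).
#' @param purity_range Tumor-cell fraction range, sampled uniformly per
#'   sample.
#' @param driver_vaf_range Allowed lesion VAF window for planted drivers;
#'   the realized VAF is purity/2 clipped into this window.
#' @param caller_fp_rate Per-kilobase probability that a caller emits a
#'   spurious call in a sample (independent across callers).
#' @param caller_fn_rate Per-variant probability that a caller misses a true
#'   variant.
#' @param snp_density Strain-informative heterozygous SNPs per kilobase.
#' @param segment_length_range Length range (bp) for planted copy-number
#'   segments.
#' @param fusion_artifact_mix Named proportions over
#'   `read_through`, `repeat_breakpoint`, `gene_family`, `true_event` for
#'   the per-sample fusion candidate lists.
#' @param n_fusions_per_sample Candidate fusions generated per LM sample.
#' @param chrom_lengths Named integer vector of toy-genome chromosome
#'   lengths.
#' @param subclone_snvs Number of subclone-private fingerprint SNVs planted
#'   per metastatic subclone.
#' @param truncal_snvs Truncal SNVs (present in PT and all LMs) per animal.
#' @param deterministic_counts If `TRUE`, per-site depth is fixed at
#'   `mean_depth` and alt counts are `round(depth * vaf)` instead of
#'   binomial draws; used for noise-free end-to-end checks.
#' @param seed Integer seed; the same config and seed reproduce the output
#'   byte for byte.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_animals = 6,
                       mets_per_animal = 4,
                       strains = c("C57BL/6J", "MOLF/EiJ", "CAST/EiJ",
                                   "C57BL/10J"),
                       mean_depth = 40,
                       purity_range = c(0.6, 0.95),
                       driver_vaf_range = c(0.3, 0.5),
                       caller_fp_rate = 0.001,
                       caller_fn_rate = 0.02,
                       snp_density = 1.5,
                       segment_length_range = c(2e5, 4e5),
                       fusion_artifact_mix = c(read_through = 0.25,
                                               repeat_breakpoint = 0.25,
                                               gene_family = 0.25,
                                               true_event = 0.25),
                       n_fusions_per_sample = 8,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 6e6,
                                         chr3 = 6e6, chr4 = 3e6),
                       subclone_snvs = 8,
                       truncal_snvs = 3,
                       deterministic_counts = FALSE,
                       seed = 1) {
  cfg <- list(n_animals = as.integer(n_animals),
              mets_per_animal = as.integer(mets_per_animal),
              strains = strains, mean_depth = mean_depth,
              purity_range = purity_range,
              driver_vaf_range = driver_vaf_range,
              caller_fp_rate = caller_fp_rate,
              caller_fn_rate = caller_fn_rate,
              snp_density = snp_density,
              segment_length_range = segment_length_range,
              fusion_artifact_mix = fusion_artifact_mix,
              n_fusions_per_sample = as.integer(n_fusions_per_sample),
              chrom_lengths = chrom_lengths,
              subclone_snvs = as.integer(subclone_snvs),
              truncal_snvs = as.integer(truncal_snvs),
              deterministic_counts = isTRUE(deterministic_counts),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  probs <- c(cfg$caller_fp_rate, cfg$caller_fn_rate)
  if (any(probs < 0 | probs > 1)) abort("caller rates must be in [0, 1]")
  if (cfg$mean_depth <= 0) abort("mean_depth must be positive")
  ordered_range <- function(r) length(r) == 2 && r[1] <= r[2]
  if (!ordered_range(cfg$purity_range) ||
      !ordered_range(cfg$driver_vaf_range) ||
      !ordered_range(cfg$segment_length_range)) {
    abort("ranges must be ordered [low, high]")
  }
  if (any(cfg$purity_range < 0 | cfg$purity_range > 1)) {
    abort("purity_range must lie in [0, 1]")
  }
  mix <- cfg$fusion_artifact_mix
  need <- c("read_through", "repeat_breakpoint", "gene_family", "true_event")
  if (!all(need %in% names(mix)) || any(mix < 0)) {
    abort("fusion_artifact_mix must name all four candidate classes")
  }
  if (cfg$n_animals < 1 || cfg$mets_per_animal < 1) {
    abort("cohort must have at least one animal and one metastasis")
  }
  invisible(cfg)
}

CALLERS <- c("mpileup", "mutect2", "strelka")
BASES <- c("A", "C", "G", "T")

#' Expected B-allele frequency under the tumor/normal mixture model
#'
#' In an F1 hybrid, every strain-informative SNP is heterozygous in normal
#' cells (one FVB allele A, one partner allele B). A one-copy loss of allele
#' B in the tumor-cell fraction `purity` leaves `1 - purity` copies of B and
#' `1` copy of A per diploid-equivalent, so the expected fraction of reads
#' supporting B is `(1 - purity) / (2 - purity)`. A one-copy gain of B gives
#' `(1 + purity) / (2 + purity)`; copy-neutral sites stay at 0.5. Losses or
#' gains of the A (FVB) allele are the mirror image, `1 - expected_baf()`.
#'
#' @param purity Tumor-cell fraction in `[0, 1]`.
#' @param state One of `"loss_of_B"`, `"neutral"`, `"gain_of_B"`.
#' @return Expected BAF as a fraction.
#' @examples
#' expected_baf(0.8, "loss_of_B")  # (1 - 0.8) / (2 - 0.8) = 0.1667
#' @export
expected_baf <- function(purity, state = c("neutral", "loss_of_B", "gain_of_B")) {
  state <- match.arg(state)
  stopifnot(purity >= 0, purity <= 1)
  switch(state,
         neutral = 0.5,
         loss_of_B = (1 - purity) / (2 - purity),
         gain_of_B = (1 + purity) / (2 + purity))
}

# ---- toy genome -------------------------------------------------------------

#' Build the toy gene annotation, repeat track and family map
#'
#' Gene placement is deterministic given the RNG state: genes sit on a
#' regular grid on each chromosome with 3 kb spans and two coding exons
#' whose lengths are multiples of three. Special roles (driver pool,
#' read-through pairs, gene-family pairs, repeat-breakpoint targets) are
#' assigned to fixed slots so every fusion artifact class is decidable by
#' construction.
#' @noRd
make_toy_genome <- function(cfg) {
  spacing <- 250e3
  span_len <- 3000L
  rows <- list()
  roles <- list()
  for (chrom in names(cfg$chrom_lengths)) {
    starts <- seq(100e3, cfg$chrom_lengths[[chrom]] - 200e3, by = spacing)
    for (k in seq_along(starts)) {
      s <- as.integer(starts[k])
      strand <- if (k %% 2 == 0) "-" else "+"
      gene <- sprintf("g%s_%02d", sub("chr", "", chrom), k)
      rows[[length(rows) + 1]] <- list(
        chrom = chrom, start = s, end = s + span_len, gene = gene,
        family = NA_character_, strand = strand,
        transcript = paste0("tx_", gene),
        exon_starts = list(c(s + 200L, s + 1200L)),
        exon_ends = list(c(s + 650L, s + 1950L)),
        frames = list(c(0L, 0L)),
        seq = paste(sample(BASES, span_len, replace = TRUE), collapse = ""))
    }
  }
  genes <- bind_rows(lapply(rows, as_tibble))

  # role assignment on chr1 slots
  chr1 <- which(genes$chrom == "chr1")
  genes$role <- "normal"
  genes$role[chr1[1:3]] <- "driver"
  # read-through pair: move a second gene to sit 2 kb downstream of a donor,
  # same strand, nothing in between
  rt_a <- chr1[5]; rt_b <- chr1[6]
  genes$strand[c(rt_a, rt_b)] <- "+"
  shift <- genes$start[rt_a] + span_len + 2000L - genes$start[rt_b]
  genes[rt_b, c("start", "end")] <- as.list(c(genes$start[rt_b],
                                              genes$end[rt_b]) + shift)
  genes$exon_starts[[rt_b]] <- genes$exon_starts[[rt_b]] + shift
  genes$exon_ends[[rt_b]] <- genes$exon_ends[[rt_b]] + shift
  genes$role[c(rt_a, rt_b)] <- c("readthrough_a", "readthrough_b")
  # gene-family pair on chr2 (same chromosome, >10 kb apart)
  chr2 <- which(genes$chrom == "chr2")
  fam <- chr2[c(2, 8)]
  genes$family[fam] <- "famA"
  genes$gene[fam] <- c("famA_1", "famA_2")
  genes$transcript[fam] <- paste0("tx_", genes$gene[fam])
  genes$role[fam] <- "family"
  # repeat-breakpoint targets on chr3
  chr3 <- which(genes$chrom == "chr3")
  rep_t <- chr3[c(3, 9)]
  genes$role[rep_t] <- "repeat_target"

  # repeat track: one intronic repeat inside each repeat-target gene plus
  # background repeats away from genes
  reps <- genes[rep_t, ] %>%
    mutate(start = .data$start + 700L, end = .data$start + 400L,
           name = paste0("rep_", .data$gene)) %>%
    select("chrom", "start", "end", "name")
  bg <- tibble(chrom = "chr4",
               start = as.integer(seq(2.2e6, 2.8e6, by = 1e5)),
               name = paste0("rep_bg", seq_along(start))) %>%
    mutate(end = .data$start + 500L) %>%
    select("chrom", "start", "end", "name")
  repeats <- bind_rows(reps, bg) %>% arrange(.data$chrom, .data$start)

  family_map <- genes %>%
    filter(!is.na(.data$family)) %>%
    select(gene = "gene", family = "family")
  list(genes = genes, repeats = repeats, family_map = family_map)
}

#' Plus-strand reference base at a position, honoring gene-model sequence
#' @noRd
ref_base_at <- function(chrom, pos, genes) {
  hit <- which(genes$chrom == chrom & genes$start <= pos - 1L &
                 genes$end > pos - 1L)
  if (length(hit) > 0) {
    substr(genes$seq[hit[1]], pos - genes$start[hit[1]], pos - genes$start[hit[1]])
  } else {
    sample(BASES, 1)
  }
}

#' A coding site inside a gene at a given codon, plus its aa change
#' @noRd
plant_coding_site <- function(gene_row, codon, alt_shift = 1L) {
  # second base of the requested codon, first (genomic-order) exon assumed
  # long enough; works for the toy two-exon models (exon1 = 450 bp)
  g <- gene_row
  es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
  cds_off <- (codon - 1L) * 3L + 1L  # 0-based offset of codon 2nd base in CDS
  if (g$strand == "+") {
    pos0 <- es[1] + cds_off
  } else {
    n <- length(es)
    pos0 <- ee[n] - 1L - cds_off
  }
  pos <- pos0 + 1L
  ref <- substr(g$seq, pos0 - g$start + 1L, pos0 - g$start + 1L)
  alt <- BASES[(match(ref, BASES) + alt_shift - 1L) %% 4L + 1L]
  cod <- site_to_codon(g$chrom, pos, ref, alt, gene_row)
  tibble(chrom = g$chrom, pos = pos, ref = ref, alt = alt,
         gene = g$gene, codon_index = cod$codon_index,
         aa_change = cod$aa_change)
}

# ---- cohort simulation ------------------------------------------------------

#' Simulate a matched PT/LM cohort with planted ground truth
#'
#' Generates, in memory, everything the analysis stages consume: a sample
#' sheet; per-sample, per-caller SNV call sets from three pseudo-callers;
#' allele-count tracks at strain-informative heterozygous SNPs reflecting
#' planted allele-specific copy-number segments; RNA-fusion and WGS-SV
#' candidate lists mixing true events with the three artifact classes; the
#' toy gene annotation, repeat track, gene-family map, expression flags and
#' cross-platform (RNA) call sets; and a `truth` list recording every
#' planted event. Use [write_cohort()] to serialize the same object to a
#' run directory.
#'
#' A true variant at lesion VAF `v` observed at depth `d` yields
#' `alt ~ Binomial(d, v)` with `d ~ Poisson(mean_depth)`; caller false
#' positives are drawn independently per caller at distinct random sites so
#' that the three-caller intersection removes them, and true calls are
#' dropped per caller at `caller_fn_rate`. With
#' `deterministic_counts = TRUE` depth and counts are exact, which makes
#' noise-free planted-truth recovery an equality, not a high-probability
#' event.
#'
#' @param cfg A [sim_config()].
#' @return A `met_cohort` list; see Details.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genome <- make_toy_genome(cfg)
  genes <- genome$genes

  # ---- sample sheet
  animals <- sprintf("A%03d", seq_len(cfg$n_animals))
  strain_of <- setNames(rep_len(cfg$strains, cfg$n_animals), animals)
  sheet <- bind_rows(lapply(seq_along(animals), function(i) {
    a <- animals[i]
    bind_rows(
      tibble(sample_id = paste0(a, "_PT"), animal_id = a, tissue = "PT"),
      tibble(sample_id = paste0(a, "_LM", seq_len(cfg$mets_per_animal)),
             animal_id = a, tissue = "LM"))
  })) %>%
    mutate(strain_cross = "F1",
           partner_strain = unname(strain_of[.data$animal_id]),
           platforms = "exome,rna,wgs")
  sheet <- validate_sample_sheet(sheet)
  purity <- tibble(sample_id = sheet$sample_id,
                   purity = round(runif(nrow(sheet), cfg$purity_range[1],
                                        cfg$purity_range[2]), 3))

  # clonality plan: every third animal seeds polyclonally (one subclone per
  # met); the rest are monoclonal (all mets share one subclone)
  poly <- seq_along(animals) %% 3 == 0
  clonality_truth <- tibble(
    animal_id = animals,
    verdict = dplyr::case_when(
      cfg$mets_per_animal < 2 ~ "indeterminate",
      poly ~ "polyclonal_seeding",
      TRUE ~ "monoclonal_seeding"))
  subclone_of <- list()  # sample_id -> subclone label
  for (i in seq_along(animals)) {
    a <- animals[i]
    lm_ids <- sheet$sample_id[sheet$animal_id == a & sheet$tissue == "LM"]
    if (poly[i] && length(lm_ids) >= 2) {
      # two subclones, each seeding half of the metastases
      half <- ceiling(length(lm_ids) / 2)
      for (j in seq_along(lm_ids)) {
        subclone_of[[lm_ids[j]]] <- paste0(a, "_sc", if (j <= half) 1L else 2L)
      }
    } else {
      for (j in seq_along(lm_ids)) subclone_of[[lm_ids[j]]] <- paste0(a, "_sc1")
    }
  }

  # ---- planted SNVs ----------------------------------------------------------
  driver_pool <- genes[genes$role == "driver", ]
  normal_pool <- genes[genes$role == "normal" & genes$chrom == "chr1", ]
  lesion_vaf <- function(sample_id) {
    p <- purity$purity[purity$sample_id == sample_id]
    pmin(pmax(p / 2, cfg$driver_vaf_range[1]), cfg$driver_vaf_range[2])
  }
  truth_snvs <- list()
  add_truth <- function(site, sample_ids, category, in_pt) {
    for (sid in sample_ids) {
      truth_snvs[[length(truth_snvs) + 1]] <<- site %>%
        mutate(sample_id = sid,
               animal_id = sheet$animal_id[sheet$sample_id == sid],
               category = category,
               true_vaf = lesion_vaf(sid),
               pt_vaf = if (in_pt) NA_real_ else 0)
    }
  }
  for (i in seq_along(animals)) {
    a <- animals[i]
    lm_ids <- sheet$sample_id[sheet$animal_id == a & sheet$tissue == "LM"]
    pt_ids <- sheet$sample_id[sheet$animal_id == a & sheet$tissue == "PT"]
    # drivers are truncal within the seeding subclone: in polyclonal
    # animals they ride on the first subclone only, so discordant mets
    # (and a recoverable clonality signal) exist by construction
    drv_carriers <- lm_ids[vapply(lm_ids, function(x)
      identical(subclone_of[[x]], paste0(a, "_sc1")), logical(1))]
    # recurrent driver: cycle the pool so each driver gene recurs across
    # animals at the same codon (same site)
    drv <- driver_pool[(i - 1) %% nrow(driver_pool) + 1, ]
    site <- plant_coding_site(drv, codon = 12L)
    add_truth(site, drv_carriers, "driver_recurrent", in_pt = FALSE)
    # private driver: a unique gene per animal, unique codon -> singleton
    priv <- normal_pool[i, ]
    psite <- plant_coding_site(priv, codon = 20L + i)
    add_truth(psite, drv_carriers, "driver_private", in_pt = FALSE)
    # truncal SNVs: present in PT and all LMs; genes are recycled across
    # animals but each animal gets its own codon, so sites stay distinct
    for (t in seq_len(cfg$truncal_snvs)) {
      idx <- (i - 1) * cfg$truncal_snvs + t
      g <- normal_pool[(idx - 1) %% nrow(normal_pool) + 1, ]
      tsite <- plant_coding_site(g, codon = 50L + idx)
      add_truth(tsite, c(pt_ids, lm_ids), "truncal", in_pt = TRUE)
    }
  }
  # subclone fingerprint SNVs: intergenic, LM-only, shared within a subclone
  subclones <- unique(unlist(subclone_of))
  sc_sites <- list()
  for (k in seq_along(subclones)) {
    pos <- sort(sample(seq(3.0e6, 4.8e6), cfg$subclone_snvs))
    refs <- vapply(pos, function(p) ref_base_at("chr1", p, genes), character(1))
    alts <- BASES[(match(refs, BASES)) %% 4L + 1L]
    sc_sites[[subclones[k]]] <- tibble(
      chrom = "chr1", pos = as.integer(pos), ref = refs, alt = alts,
      gene = NA_character_, codon_index = NA_integer_,
      aa_change = NA_character_)
  }
  for (sid in names(subclone_of)) {
    sc <- subclone_of[[sid]]
    st <- sc_sites[[sc]]
    for (r in seq_len(nrow(st))) {
      add_truth(st[r, ], sid, "subclone", in_pt = FALSE)
    }
  }
  truth_snv <- bind_rows(truth_snvs)

  # ---- planted CNV segments --------------------------------------------------
  seg_len <- function() {
    round(runif(1, cfg$segment_length_range[1], cfg$segment_length_range[2]))
  }
  truth_segs <- list()
  add_seg <- function(sample_ids, chrom, start, end, state, allele, category) {
    for (sid in sample_ids) {
      truth_segs[[length(truth_segs) + 1]] <<- tibble(
        sample_id = sid,
        animal_id = sheet$animal_id[sheet$sample_id == sid],
        chrom = chrom, start = as.integer(start), end = as.integer(end),
        state = state, affected_allele = allele, category = category)
    }
  }
  mono_animals <- animals[!poly]
  for (i in seq_along(animals)) {
    a <- animals[i]
    lm_ids <- sheet$sample_id[sheet$animal_id == a & sheet$tissue == "LM"]
    pt_ids <- sheet$sample_id[sheet$animal_id == a & sheet$tissue == "PT"]
    # truncal segment, PT + all LMs, chr2, disjoint across animals
    s <- 2e5 + (i - 1) * 9e5
    add_seg(c(pt_ids, lm_ids), "chr2", s, s + seg_len(), "loss", "partner",
            "truncal")
    # subclone segments, chr3, disjoint across subclones
    lm_sc <- unique(unlist(subclone_of[lm_ids]))
    for (j in seq_along(lm_sc)) {
      carriers <- lm_ids[vapply(lm_ids, function(x)
        identical(subclone_of[[x]], lm_sc[j]), logical(1))]
      s3 <- 2e5 + ((i - 1) * 2 + (j - 1)) * 4.6e5
      state <- if (j %% 2 == 1) "loss" else "gain"
      allele <- if (i %% 2 == 1) "partner" else "FVB"
      add_seg(carriers, "chr3", s3, s3 + seg_len(), state, allele, "subclone")
    }
  }
  # recurrent metastasis-specific segments: staggered losses on chr4 in the
  # first two monoclonal animals (all their LMs)
  rec_animals <- utils::head(mono_animals, 2)
  for (k in seq_along(rec_animals)) {
    a <- rec_animals[k]
    lm_ids <- sheet$sample_id[sheet$animal_id == a & sheet$tissue == "LM"]
    s4 <- 1e6 + (k - 1) * 1.5e5
    add_seg(lm_ids, "chr4", s4, s4 + 4e5, "loss", "partner", "recurrent")
  }
  truth_seg <- bind_rows(truth_segs)

  # ---- allele counts ---------------------------------------------------------
  snp_pos <- lapply(names(cfg$chrom_lengths), function(chrom) {
    n <- round(cfg$chrom_lengths[[chrom]] / 1000 * cfg$snp_density)
    sort(sample.int(cfg$chrom_lengths[[chrom]], n))
  })
  names(snp_pos) <- names(cfg$chrom_lengths)
  allele_counts <- bind_rows(lapply(sheet$sample_id, function(sid) {
    p <- purity$purity[purity$sample_id == sid]
    segs <- truth_seg[truth_seg$sample_id == sid, ]
    bind_rows(lapply(names(snp_pos), function(chrom) {
      pos <- snp_pos[[chrom]]
      baf <- rep(0.5, length(pos))
      ratio <- rep(1, length(pos))
      cs <- segs[segs$chrom == chrom, ]
      if (nrow(cs) > 0) {
        for (r in seq_len(nrow(cs))) {
          inside <- pos - 1L >= cs$start[r] & pos - 1L < cs$end[r]
          st <- if (cs$state[r] == "loss") "loss_of_B" else "gain_of_B"
          b <- expected_baf(p, st)
          if (cs$affected_allele[r] == "FVB") b <- 1 - b
          baf[inside] <- b
          ratio[inside] <- if (cs$state[r] == "loss") (2 - p) / 2 else (2 + p) / 2
        }
      }
      if (cfg$deterministic_counts) {
        total <- pmax(1L, as.integer(round(cfg$mean_depth * ratio)))
        cb <- as.integer(round(total * baf))
      } else {
        total <- pmax(1L, rpois(length(pos), cfg$mean_depth * ratio))
        cb <- rbinom(length(pos), total, baf)
      }
      tibble(sample_id = sid, chrom = chrom, pos = as.integer(pos),
             count_A = total - cb, count_B = cb)
    }))
  }))

  # ---- SNV calls from the three pseudo-callers -------------------------------
  per_sample_truth <- truth_snv %>%
    distinct(.data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt,
             .data$true_vaf)
  genome_kb <- sum(cfg$chrom_lengths) / 1000
  snv_calls <- bind_rows(lapply(sheet$sample_id, function(sid) {
    tv <- per_sample_truth[per_sample_truth$sample_id == sid, ]
    bind_rows(lapply(CALLERS, function(cl) {
      keep <- if (cfg$caller_fn_rate > 0) {
        runif(nrow(tv)) >= cfg$caller_fn_rate
      } else rep(TRUE, nrow(tv))
      tvk <- tv[keep, , drop = FALSE]
      if (nrow(tvk) > 0) {
        if (cfg$deterministic_counts) {
          depth <- rep(as.integer(cfg$mean_depth), nrow(tvk))
          alt_n <- as.integer(round(depth * tvk$true_vaf))
        } else {
          depth <- pmax(1L, rpois(nrow(tvk), cfg$mean_depth))
          alt_n <- rbinom(nrow(tvk), depth, tvk$true_vaf)
        }
        true_calls <- tibble(
          sample_id = sid, caller = cl,
          chrom = tvk$chrom, pos = tvk$pos, ref = tvk$ref, alt = tvk$alt,
          qual = round(runif(nrow(tvk), 45, 90), 1),
          ref_count = depth - alt_n, alt_count = alt_n) %>%
          filter(.data$alt_count > 0)
      } else {
        true_calls <- tibble()
      }
      n_fp <- rpois(1, cfg$caller_fp_rate * genome_kb)
      if (n_fp > 0) {
        fp_chrom <- sample(names(cfg$chrom_lengths), n_fp, replace = TRUE,
                           prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))
        fp_pos <- vapply(fp_chrom, function(ch)
          sample.int(cfg$chrom_lengths[[ch]], 1), integer(1))
        fp_ref <- vapply(seq_len(n_fp), function(j)
          ref_base_at(fp_chrom[j], fp_pos[j], genes), character(1))
        fp_alt <- BASES[(match(fp_ref, BASES)) %% 4L + 1L]
        fp_depth <- pmax(1L, rpois(n_fp, cfg$mean_depth))
        fp_altn <- pmax(1L, rbinom(n_fp, fp_depth, 0.1))
        fps <- tibble(sample_id = sid, caller = cl, chrom = fp_chrom,
                      pos = as.integer(fp_pos), ref = fp_ref, alt = fp_alt,
                      qual = round(runif(n_fp, 10, 70), 1),
                      ref_count = fp_depth - fp_altn, alt_count = fp_altn)
      } else {
        fps <- tibble()
      }
      bind_rows(true_calls, fps)
    }))
  })) %>%
    mutate(vaf = .data$alt_count / (.data$ref_count + .data$alt_count)) %>%
    arrange(.data$sample_id, .data$caller, .data$chrom, .data$pos)

  # ---- fusion / SV candidates ------------------------------------------------
  fus <- simulate_fusions(cfg, sheet, genes, genome$repeats)

  # ---- expression flags and RNA-platform calls -------------------------------
  untx <- utils::tail(normal_pool$gene, 2)
  expression <- genes %>%
    select(gene = "gene") %>%
    mutate(transcribed = as.integer(!.data$gene %in% untx))
  rna_calls <- truth_snv %>%
    filter(!is.na(.data$gene)) %>%
    inner_join(expression, by = "gene") %>%
    filter(.data$transcribed == 1) %>%
    distinct(.data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt)

  truth <- list(snvs = truth_snv, segments = truth_seg,
                fusions = fus$truth, purity = purity,
                clonality = clonality_truth,
                subclones = tibble(sample_id = names(subclone_of),
                                   subclone = unlist(subclone_of)))
  structure(list(sample_sheet = sheet, genes = genes,
                 repeats = genome$repeats, family_map = genome$family_map,
                 snv_calls = snv_calls, allele_counts = allele_counts,
                 fusion_rna = fus$rna, sv_wgs = fus$wgs,
                 expression = expression, rna_calls = rna_calls,
                 truth = truth, config = cfg),
            class = "met_cohort")
}

#' @noRd
simulate_fusions <- function(cfg, sheet, genes, repeats) {
  mix <- cfg$fusion_artifact_mix / sum(cfg$fusion_artifact_mix)
  n_per_class <- round(mix * cfg$n_fusions_per_sample)
  n_per_class[n_per_class < 0] <- 0
  rt_a <- genes[genes$role == "readthrough_a", ][1, ]
  rt_b <- genes[genes$role == "readthrough_b", ][1, ]
  fam <- genes[genes$role == "family", ]
  rep_t <- genes[genes$role == "repeat_target", ]
  rep_iv <- repeats[grepl("^rep_g", repeats$name), ]
  true_pool <- genes[genes$role == "normal", ]

  mid <- function(g) as.integer((g$start + g$end) / 2)
  lm_ids <- sheet$sample_id[sheet$tissue == "LM"]
  pt_ids <- sheet$sample_id[sheet$tissue == "PT"]

  rna <- list(); wgs <- list(); truth <- list()
  emit_rna <- function(sid, g1, g2, p1, p2, reads, total, class, met) {
    rna[[length(rna) + 1]] <<- tibble(
      sample = sid, gene1 = g1$gene, gene2 = g2$gene,
      chrom1 = g1$chrom, pos1 = p1, strand1 = g1$strand,
      chrom2 = g2$chrom, pos2 = p2, strand2 = g2$strand,
      split_reads = reads, gene_read_total = total)
    truth[[length(truth) + 1]] <<- tibble(
      sample_id = sid, source = "rna", gene1 = g1$gene, gene2 = g2$gene,
      class = class, met_specific = met)
  }
  emit_wgs <- function(sid, g1, g2, p1, p2, type, reads, class) {
    wgs[[length(wgs) + 1]] <<- tibble(
      sample = sid, chrom1 = g1$chrom, pos1 = p1,
      chrom2 = g2$chrom, pos2 = p2, type = type, num_reads = reads)
    truth[[length(truth) + 1]] <<- tibble(
      sample_id = sid, source = "wgs", gene1 = g1$gene, gene2 = g2$gene,
      class = class, met_specific = TRUE)
  }

  # one shared (PT + LM) highly expressed true fusion per animal, at <1% of
  # the partner gene's read total -> flagged low-fraction, not met-specific
  shared1 <- true_pool[5, ]; shared2 <- true_pool[17, ]
  for (a in unique(sheet$animal_id)) {
    ids <- sheet$sample_id[sheet$animal_id == a]
    for (sid in ids) {
      emit_rna(sid, shared1, shared2, mid(shared1), mid(shared2),
               reads = 4L + sample.int(3, 1), total = 5000L,
               class = "true_event", met = FALSE)
    }
  }

  for (sid in lm_ids) {
    for (k in seq_len(n_per_class[["read_through"]])) {
      emit_rna(sid, rt_a, rt_b, rt_a$end - 150L + k, rt_b$start + 150L + k,
               reads = 3L + sample.int(8, 1), total = 800L,
               class = "read_through", met = TRUE)
    }
    for (k in seq_len(n_per_class[["repeat_breakpoint"]])) {
      p1 <- as.integer(rep_iv$start[1] + 50L + k)
      p2 <- as.integer(rep_iv$start[2] + 50L + k)
      emit_rna(sid, rep_t[1, ], rep_t[2, ], p1, p2,
               reads = 3L + sample.int(8, 1), total = 900L,
               class = "repeat_breakpoint", met = TRUE)
      emit_wgs(sid, rep_t[1, ], rep_t[2, ], p1, p2,
               type = "ITX", reads = 3L + sample.int(8, 1),
               class = "repeat_breakpoint")
    }
    for (k in seq_len(n_per_class[["gene_family"]])) {
      emit_rna(sid, fam[1, ], fam[2, ], mid(fam[1, ]) + k, mid(fam[2, ]) + k,
               reads = 3L + sample.int(8, 1), total = 1200L,
               class = "gene_family", met = TRUE)
      emit_wgs(sid, fam[1, ], fam[2, ], mid(fam[1, ]) + k, mid(fam[2, ]) + k,
               type = sample(c("DEL", "INV", "ITX"), 1),
               reads = 3L + sample.int(8, 1), class = "gene_family")
    }
    for (k in seq_len(n_per_class[["true_event"]])) {
      i1 <- sample.int(nrow(true_pool) - 1L, 1)
      g1 <- true_pool[i1, ]
      g2 <- true_pool[nrow(true_pool) - i1 + 1L, ]
      if (identical(g1$gene, g2$gene)) g2 <- true_pool[i1 + 1L, ]
      emit_rna(sid, g1, g2, mid(g1), mid(g2),
               reads = 5L + sample.int(15, 1), total = 400L,
               class = "true_event", met = TRUE)
      if (identical(g1$chrom, g2$chrom)) {
        emit_wgs(sid, g1, g2, mid(g1), mid(g2),
                 type = sample(c("DEL", "INV", "ITX"), 1),
                 reads = 5L + sample.int(15, 1), class = "true_event")
      }
    }
  }
  list(rna = bind_rows(rna), wgs = bind_rows(wgs), truth = bind_rows(truth))
}
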