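#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis stages, each tagged
#' with its provenance: `paper_stated` values come from the published
#' screening rules this pipeline implements (Phred >= 30, VAF window
#' 0.30-0.50, 4000-bp bins, >= 2-sample fingerprint filter, >= 3 variant
#' reads, 10-kb partner distance and gene flank, >= 2-animal recurrence);
#' `repo_default` values fill gaps those rules leave open.
#'
#' @param ... Named overrides of any default.
#' @return A `met_config` list; the `provenance` attribute tags each
#'   value.
#' @export
met_config <- function(...) {
  defaults <- list(
    min_qual = 30, vaf_low = 0.3, vaf_high = 0.5, pt_max_alt_reads = 1,
    bin_size = 4000, min_snps = 3, baf_delta = 0.1,
    min_consecutive_bins = 5, purity = 0.8, reciprocal_overlap = 0.5,
    min_freq = 2, region_flank = 10000,
    min_reads = 3, min_partner_distance = 10000, gene_flank = 10000,
    match_tolerance = 100,
    min_samples = 2, linkage = "complete", weights = c(cnv = 0.5, snv = 0.5))
  provenance <- c(
    min_qual = "paper_stated", vaf_low = "paper_stated",
    vaf_high = "paper_stated", pt_max_alt_reads = "repo_default",
    bin_size = "paper_stated", min_snps = "repo_default",
    baf_delta = "repo_default", min_consecutive_bins = "repo_default",
    purity = "repo_default", reciprocal_overlap = "repo_default",
    min_freq = "paper_stated", region_flank = "repo_default",
    min_reads = "paper_stated", min_partner_distance = "paper_stated",
    gene_flank = "paper_stated", match_tolerance = "repo_default",
    min_samples = "paper_stated", linkage = "repo_default",
    weights = "repo_default")
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, provenance = provenance, class = "met_config")
}

#' Run the full metastasis-driver pipeline on a cohort
#'
#' Executes the four analysis stages in order on a `met_cohort` (from
#' [simulate_cohort()] or [read_cohort()]): the consensus SNV screen with
#' the seeding-cell filter, recurrence classification, cross-platform
#' validation and mutual-exclusivity report; allele-specific CNV
#' segmentation with metastasis-specific subtraction and recurrent-region
#' intersection; fusion/SV curation of the metastasis-specific candidate
#' set; and fingerprint clustering with per-animal clonality calls.
#'
#' All stages are deterministic functions of their inputs; with `out_dir`
#' set, per-stage TSVs and a machine-readable `summary.json` are written,
#' and a rerun on the same inputs is byte-identical.
#'
#' @param cohort A `met_cohort` list or a run-directory path.
#' @param config A [met_config()].
#' @param out_dir Optional output directory.
#' @param purity Per-sample purity named vector; defaults to the cohort
#'   truth when present, else `config$purity`.
#' @return A list with per-stage results and a `summary` count list.
#' @export
run_met_pipeline <- function(cohort, config = met_config(), out_dir = NULL,
                             purity = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  sheet <- cohort$sample_sheet
  genes <- cohort$genes
  empty <- nrow(sheet) == 0

  # ---- stage 1: SNV screen
  lm_ids <- sheet$sample_id[sheet$tissue == "LM"]
  pt_ids <- sheet$sample_id[sheet$tissue == "PT"]
  filtered <- filter_calls(cohort$snv_calls, min_qual = config$min_qual)
  lm_consensus <- if (any(filtered$sample_id %in% lm_ids)) {
    intersect_callers(filtered %>% filter(.data$sample_id %in% lm_ids))
  } else filtered[0, ]
  pt_consensus <- if (any(filtered$sample_id %in% pt_ids)) {
    intersect_callers(filtered %>% filter(.data$sample_id %in% pt_ids))
  } else filtered[0, ]
  pt_raw <- cohort$snv_calls %>% filter(.data$sample_id %in% pt_ids)
  met_snvs <- if (nrow(lm_consensus) > 0) {
    met_enrichment_filter(lm_consensus, pt_raw, sheet,
                          vaf_low = config$vaf_low,
                          vaf_high = config$vaf_high,
                          pt_max_alt_reads = config$pt_max_alt_reads) %>%
      annotate_sites(genes)
  } else lm_consensus
  recurrence <- if (nrow(met_snvs) > 0) {
    classify_recurrence(met_snvs, sheet, genes)
  } else list(report = tibble(gene = character(), class = character(),
                              n_animals = integer(), n_events = integer()),
              events = tibble())
  recurrent_genes <- recurrence$report %>%
    filter(.data$class %in% c("same_codon_recurrent",
                              "diff_codon_recurrent")) %>%
    pull("gene")
  validation <- if (nrow(met_snvs) > 0 && !is.null(cohort$rna_calls)) {
    cross_platform_validate(met_snvs, cohort$rna_calls, cohort$expression)
  } else met_snvs
  mutex <- if (nrow(met_snvs) > 0) {
    mutual_exclusivity_report(met_snvs, recurrent_genes)
  } else list(per_sample = tibble(), per_gene_carriers = tibble(),
              n_carrier_animals = 0L, any_cooccurrence = FALSE)

  # ---- stage 2: allele-specific CNV
  if (is.null(purity)) {
    purity <- if (!is.null(cohort$truth$purity)) {
      setNames(cohort$truth$purity$purity, cohort$truth$purity$sample_id)
    } else config$purity
  }
  f1_ids <- sheet$sample_id[sheet$strain_cross == "F1"]
  segments <- if (!is.null(cohort$allele_counts) &&
                  any(cohort$allele_counts$sample_id %in% f1_ids)) {
    call_cnv_segments(
      cohort$allele_counts %>% filter(.data$sample_id %in% f1_ids),
      sheet, purity = purity, bin_size = config$bin_size,
      min_snps = config$min_snps, baf_delta = config$baf_delta,
      min_consecutive_bins = config$min_consecutive_bins)
  } else empty_segments() %>% mutate(sample_id = character())
  met_segments <- if (nrow(segments) > 0) {
    cohort_met_specific_segments(segments, sheet,
                                 reciprocal_overlap = config$reciprocal_overlap)
  } else segments
  regions <- recurrent_regions(met_segments, sheet,
                               min_freq = config$min_freq)
  region_genes <- assign_region_genes(regions, genes,
                                      flank = config$region_flank)

  # ---- stage 3: fusion / SV screen
  cand <- as_sv_candidates(rna = cohort$fusion_rna, wgs = cohort$sv_wgs,
                           genes = genes, gene_flank = config$gene_flank)
  if (nrow(cand) > 0) {
    lm_cand <- cand %>% filter(.data$sample_id %in% lm_ids)
    pt_cand <- cand %>% filter(.data$sample_id %in% pt_ids)
    partition <- met_specific_set(lm_cand, pt_cand,
                                  match_tolerance = config$match_tolerance)
    fusion_audit <- fusion_screen(
      partition$lm_only, genes, cohort$repeats, cohort$family_map, sheet,
      min_reads = config$min_reads,
      min_partner_distance = config$min_partner_distance,
      gene_flank = config$gene_flank)
    fusion_final <- fusion_audit %>% filter(.data$final_keep)
  } else {
    partition <- list(shared = cand, lm_only = cand, pt_shared = cand,
                      pt_only = cand)
    fusion_audit <- cand
    fusion_final <- cand
  }

  # ---- stage 4: clonality
  all_consensus <- bind_rows(lm_consensus, pt_consensus)
  fingerprints <- build_fingerprints(
    segments, all_consensus, samples = sheet$sample_id,
    bin_size = config$bin_size, min_samples = config$min_samples)
  clust <- if (length(sheet$sample_id) >= 2) {
    cluster_fingerprints(fingerprints, weights = config$weights,
                         linkage = config$linkage)
  } else NULL
  clonality <- if (!is.null(clust)) {
    call_clonality(clust, sheet)
  } else tibble(animal_id = character(), verdict = character(),
                n_lm = integer(), clade_size = integer(),
                clade_samples = character())

  summary <- list(
    n_samples = nrow(sheet),
    n_pt_consensus_snvs = nrow(pt_consensus),
    n_lm_consensus_snvs = nrow(lm_consensus),
    n_met_enriched_snvs = nrow(met_snvs),
    n_genes_same_codon = sum(recurrence$report$class == "same_codon_recurrent"),
    n_genes_diff_codon = sum(recurrence$report$class == "diff_codon_recurrent"),
    n_genes_singleton = sum(recurrence$report$class == "singleton"),
    n_carrier_animals = mutex$n_carrier_animals,
    any_cooccurrence = mutex$any_cooccurrence,
    n_segments = nrow(segments),
    n_met_specific_segments = nrow(met_segments),
    n_recurrent_regions = nrow(regions),
    n_fusion_candidates = nrow(cand),
    n_fusion_lm_only = nrow(partition$lm_only),
    n_fusion_shared = nrow(partition$shared),
    n_fusion_final = nrow(fusion_final),
    clonality_verdicts = as.list(setNames(clonality$verdict,
                                          clonality$animal_id)))

  result <- list(config = config, met_snvs = met_snvs,
                 recurrence = recurrence, validation = validation,
                 mutual_exclusivity = mutex,
                 segments = segments, met_segments = met_segments,
                 recurrent_regions = regions, region_genes = region_genes,
                 fusion_partition = partition, fusion_audit = fusion_audit,
                 fusion_final = fusion_final,
                 fingerprints = fingerprints, clustering = clust,
                 clonality = clonality, summary = summary)

  if (!is.null(out_dir)) {
    h <- rlang::hash(unclass(config))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_stamped(met_snvs, file.path(out_dir, "met_snvs.tsv"), h)
    write_tsv_stamped(recurrence$report,
                      file.path(out_dir, "recurrence.tsv"), h)
    write_tsv_stamped(met_segments,
                      file.path(out_dir, "met_segments.tsv"), h)
    write_tsv_stamped(regions,
                      file.path(out_dir, "recurrent_regions.tsv"), h)
    write_tsv_stamped(fusion_audit %>%
                        mutate(across(dplyr::where(is.list), as.character)),
                      file.path(out_dir, "fusion_audit.tsv"), h)
    write_tsv_stamped(clonality, file.path(out_dir, "clonality.tsv"), h)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
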