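#' Quality and polymorphism filtering of raw SNV calls
#'
#' Removes calls below the Phred quality floor and calls at known germline
#' polymorphisms (e.g. the mgp.v5 strain SNP set), keyed by
#' (chrom, pos, ref, alt).
#'
#' @param calls Tibble of per-caller calls with columns `sample_id`,
#'   `caller`, `chrom`, `pos`, `ref`, `alt`, `qual`, `ref_count`,
#'   `alt_count`, `vaf`.
#' @param min_qual Minimum Phred-scaled quality; calls with `qual <
#'   min_qual` are removed (default 30).
#' @param polymorphisms Optional tibble of known polymorphic sites with
#'   columns `chrom`, `pos`, `ref`, `alt`.
#' @return The surviving calls.
#' @export
filter_calls <- function(calls, min_qual = 30, polymorphisms = NULL) {
  calls <- as_tibble(calls)
  out <- calls %>% filter(.data$qual >= min_qual)
  if (!is.null(polymorphisms) && nrow(polymorphisms) > 0) {
    out <- out %>%
      anti_join(as_tibble(polymorphisms)[, c("chrom", "pos", "ref", "alt")],
                by = c("chrom", "pos", "ref", "alt"))
  }
  out
}

#' Consensus of the three variant callers
#'
#' Intersects the per-caller call sets for each sample. In `site` mode
#' (default, the stricter reading) a site survives only when all three
#' callers report the identical (chrom, pos, ref, alt) in that sample. In
#' `gene` mode a site survives when its gene has at least one call from
#' each caller; sites that are not themselves tri-supported are kept but
#' flagged. Pooled counts for a consensus record are taken from the caller
#' with the highest depth at the site (ties broken by caller-label order).
#'
#' @param calls Per-caller calls (see [filter_calls()]).
#' @param mode `"site"` or `"gene"`.
#' @param genes Gene-model tibble, required for `mode = "gene"`.
#' @return A tibble of consensus records with `supporting_callers`,
#'   `n_callers`, `max_qual`, pooled `ref_count`/`alt_count`/`vaf` and a
#'   `tri_supported` flag.
#' @export
intersect_callers <- function(calls, mode = c("site", "gene"), genes = NULL) {
  mode <- match.arg(mode)
  calls <- as_tibble(calls)
  caller_count <- calls %>%
    group_by(.data$sample_id) %>%
    summarise(n = n_distinct(.data$caller), .groups = "drop")
  short <- caller_count$sample_id[caller_count$n < 3]
  if (length(short) > 0) {
    abort(paste0("fewer than 3 caller call sets for sample(s): ",
                 paste(short, collapse = ", ")))
  }
  per_site <- calls %>%
    mutate(depth = .data$ref_count + .data$alt_count,
           caller_rank = match(.data$caller, CALLERS)) %>%
    group_by(.data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt) %>%
    arrange(dplyr::desc(.data$depth), .data$caller_rank, .by_group = TRUE) %>%
    summarise(
      supporting_callers = paste(sort(unique(.data$caller)), collapse = ","),
      n_callers = n_distinct(.data$caller),
      max_qual = max(.data$qual),
      ref_count = first(.data$ref_count),
      alt_count = first(.data$alt_count),
      .groups = "drop") %>%
    mutate(vaf = .data$alt_count / (.data$ref_count + .data$alt_count),
           tri_supported = .data$n_callers == 3)
  if (mode == "site") {
    return(per_site %>% filter(.data$tri_supported))
  }
  if (is.null(genes)) abort("gene mode requires a gene annotation")
  ann <- annotate_sites(per_site[, c("chrom", "pos", "ref", "alt")] %>%
                          distinct(), genes)[, c("chrom", "pos", "ref",
                                                 "alt", "gene")]
  per_site <- per_site %>% left_join(ann, by = c("chrom", "pos", "ref", "alt"))
  # gene-level caller support: which callers hit the gene at all, per sample
  gene_support <- calls %>%
    left_join(ann %>% distinct(.data$chrom, .data$pos, .data$gene),
              by = c("chrom", "pos")) %>%
    filter(!is.na(.data$gene)) %>%
    group_by(.data$sample_id, .data$gene) %>%
    summarise(gene_n_callers = n_distinct(.data$caller), .groups = "drop")
  per_site %>%
    left_join(gene_support, by = c("sample_id", "gene")) %>%
    filter((!is.na(.data$gene) & .data$gene_n_callers == 3) |
             (is.na(.data$gene) & .data$tri_supported)) %>%
    select(-"gene_n_callers")
}

#' Fraction of cells carrying a heterozygous variant
#'
#' Under a diploid heterozygous model, a variant observed at allele
#' fraction `vaf` is carried by `2 * vaf` of the cells, clipped at 1; a VAF
#' of 0.30 therefore implies the variant is present in at least 60% of the
#' lesion.
#'
#' @param vaf Variant allele fraction(s) in `[0, 1]`.
#' @return Cell fraction(s) in `[0, 1]`.
#' @examples
#' cell_fraction(c(0.3, 0.5))  # 0.6, 1.0
#' @export
cell_fraction <- function(vaf) {
  stopifnot(all(vaf >= 0 & vaf <= 1))
  pmin(1, 2 * vaf)
}

#' Metastasis-enrichment (seeding-cell) filter
#'
#' Applies the two driver criteria to LM consensus SNVs: (1) absence from
#' the matched primary tumor, operationalized as at most `pt_max_alt_reads`
#' alt reads at the site in any of the animal's PT call sets (the union of
#' PT samples when an animal has several), and (2) presence in the
#' metastatic seeding cell, i.e. lesion VAF within `[vaf_low, vaf_high]`,
#' which under the heterozygous diploid model corresponds to at least 60%
#' of the cells at the lower bound. LM samples whose animal has no PT
#' sample are excluded with a warning, since criterion (1) cannot be
#' evaluated.
#'
#' @param lm_consensus Consensus records for LM samples
#'   ([intersect_callers()]).
#' @param pt_calls Raw per-caller calls for PT samples (read-level PT
#'   evidence, not PT consensus).
#' @param sample_sheet Cohort sample sheet.
#' @param vaf_low,vaf_high Closed VAF window (defaults 0.3, 0.5).
#' @param pt_max_alt_reads Maximum alt reads tolerated in the matched PT
#'   (default 1).
#' @return Surviving records with `vaf_lm`, `vaf_pt`, `pt_alt_reads` and
#'   `cell_fraction` columns.
#' @export
met_enrichment_filter <- function(lm_consensus, pt_calls, sample_sheet,
                                  vaf_low = 0.3, vaf_high = 0.5,
                                  pt_max_alt_reads = 1) {
  lm <- as_tibble(lm_consensus) %>%
    left_join(sample_sheet[, c("sample_id", "animal_id")], by = "sample_id")
  pt_ids <- sample_sheet %>% filter(.data$tissue == "PT")
  no_pt <- setdiff(lm$animal_id, pt_ids$animal_id)
  if (length(no_pt) > 0) {
    warn(paste0("excluding LM records with no matched PT for animal(s): ",
                paste(no_pt, collapse = ", ")))
    lm <- lm %>% filter(!.data$animal_id %in% no_pt)
  }
  pt_matched <- as_tibble(pt_calls) %>%
    inner_join(pt_ids[, c("sample_id", "animal_id")], by = "sample_id")
  pt_evidence <- if (nrow(pt_matched) > 0) {
    pt_matched %>%
      group_by(.data$animal_id, .data$chrom, .data$pos, .data$ref,
               .data$alt) %>%
      summarise(pt_alt_reads = max(.data$alt_count),
                vaf_pt = {
                  i <- which.max(.data$alt_count)
                  .data$alt_count[i] /
                    max(1L, .data$ref_count[i] + .data$alt_count[i])
                },
                .groups = "drop")
  } else {
    tibble(animal_id = character(), chrom = character(), pos = integer(),
           ref = character(), alt = character(), pt_alt_reads = integer(),
           vaf_pt = double())
  }
  lm %>%
    left_join(pt_evidence,
              by = c("animal_id", "chrom", "pos", "ref", "alt")) %>%
    mutate(pt_alt_reads = dplyr::coalesce(.data$pt_alt_reads, 0L),
           vaf_pt = dplyr::coalesce(.data$vaf_pt, 0),
           vaf_lm = .data$vaf) %>%
    filter(.data$vaf_lm >= vaf_low, .data$vaf_lm <= vaf_high,
           .data$pt_alt_reads <= pt_max_alt_reads) %>%
    mutate(cell_fraction = cell_fraction(.data$vaf_lm))
}

#' Classify recurrence of metastasis-enriched SNVs across animals
#'
#' Genes are partitioned into `same_codon_recurrent` (two or more distinct
#' animals share a mutated codon), `diff_codon_recurrent` (two or more
#' distinct animals, distinct codons) and `singleton`. Two metastases from
#' one animal count as a single animal; differing alternate amino acids at
#' a shared codon still count as same-codon recurrence. Sites with no gene
#' assignment are reported under the `"non-coding/unassigned"` bucket,
#' never dropped.
#'
#' @param met_snvs Metastasis-enriched SNVs; annotated with gene/codon via
#'   [annotate_sites()] if not already.
#' @param sample_sheet Cohort sample sheet (for `animal_id` lookup when the
#'   column is absent).
#' @param genes Gene-model tibble, used when `met_snvs` lacks annotation.
#' @return A list with `report` (one row per gene: `gene`, `class`,
#'   `n_animals`) and `events` (one row per event: gene, animal, sample,
#'   codon, amino-acid change, platform).
#' @export
classify_recurrence <- function(met_snvs, sample_sheet = NULL, genes = NULL) {
  ev <- as_tibble(met_snvs)
  if (!"gene" %in% names(ev)) {
    if (is.null(genes)) abort("met_snvs lack annotation; supply `genes`")
    ev <- annotate_sites(ev, genes)
  }
  if (!"animal_id" %in% names(ev)) {
    if (is.null(sample_sheet)) abort("supply `sample_sheet` for animal ids")
    ev <- ev %>% left_join(sample_sheet[, c("sample_id", "animal_id")],
                           by = "sample_id")
  }
  if (!"platform" %in% names(ev)) ev$platform <- "exome"
  events <- ev %>%
    mutate(gene = if_else(is.na(.data$gene), "non-coding/unassigned",
                          .data$gene)) %>%
    select("gene", "animal_id", "sample_id", "chrom", "pos",
           "codon_index", "aa_change", "platform")
  report <- events %>%
    group_by(.data$gene) %>%
    summarise(
      n_animals = n_distinct(.data$animal_id),
      n_events = n(),
      same_codon = {
        cod <- .data$codon_index
        an <- .data$animal_id
        any(vapply(unique(cod[!is.na(cod)]), function(ci)
          n_distinct(an[!is.na(cod) & cod == ci]) >= 2, logical(1)))
      },
      .groups = "drop") %>%
    mutate(class = case_when(
      .data$gene == "non-coding/unassigned" ~ "unassigned",
      .data$same_codon ~ "same_codon_recurrent",
      .data$n_animals >= 2 ~ "diff_codon_recurrent",
      TRUE ~ "singleton")) %>%
    select("gene", "class", "n_animals", "n_events")
  list(report = report, events = events)
}

#' Cross-platform validation of metastasis-enriched SNVs
#'
#' Each event is checked against the call set of a second platform (e.g.
#' RNA-seq) for the same sample. Events in genes below the expression flag
#' are unevaluable (`not_transcribed`); samples missing from the other
#' platform, and sites with no gene/expression information, yield
#' `no_data`.
#'
#' @param met_snvs Metastasis-enriched SNVs with `sample_id`, site columns
#'   and (ideally) a `gene` column.
#' @param other_calls Other-platform calls: `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param expression Tibble `gene`, `transcribed` (0/1).
#' @return `met_snvs` with a `validation` column in
#'   `validated`/`not_transcribed`/`absent`/`no_data`.
#' @export
cross_platform_validate <- function(met_snvs, other_calls, expression) {
  met <- as_tibble(met_snvs)
  other <- as_tibble(other_calls) %>%
    mutate(present = TRUE) %>%
    distinct(.data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt,
             .data$present)
  have_sample <- unique(other_calls$sample_id)
  met %>%
    left_join(other, by = c("sample_id", "chrom", "pos", "ref", "alt")) %>%
    left_join(as_tibble(expression), by = "gene") %>%
    mutate(validation = case_when(
      !.data$sample_id %in% have_sample ~ "no_data",
      is.na(.data$gene) | is.na(.data$transcribed) ~ "no_data",
      .data$transcribed == 0 ~ "not_transcribed",
      !is.na(.data$present) ~ "validated",
      TRUE ~ "absent")) %>%
    select(-"present", -"transcribed")
}

#' Mutual-exclusivity report for recurrently mutated genes
#'
#' Counts, per LM sample, the number of distinct recurrent genes mutated,
#' and per recurrent gene the number of distinct carrier animals.
#' `any_cooccurrence` is `TRUE` iff some LM carries events in two or more
#' distinct recurrent genes.
#'
#' @param met_snvs Metastasis-enriched SNVs with `sample_id`, `gene` and
#'   `animal_id` columns.
#' @param recurrent_genes Character vector of recurrent gene symbols.
#' @return A list: `per_sample` (sample, count, genes), `per_gene_carriers`
#'   (gene, n_animals), `n_carrier_animals` (distinct animals carrying any
#'   recurrent-gene event), `any_cooccurrence`.
#' @export
mutual_exclusivity_report <- function(met_snvs, recurrent_genes) {
  ev <- as_tibble(met_snvs) %>% filter(.data$gene %in% recurrent_genes)
  per_sample <- as_tibble(met_snvs) %>%
    distinct(.data$sample_id) %>%
    left_join(ev %>%
                group_by(.data$sample_id) %>%
                summarise(n_recurrent_genes = n_distinct(.data$gene),
                          genes = paste(sort(unique(.data$gene)),
                                        collapse = ","),
                          .groups = "drop"),
              by = "sample_id") %>%
    mutate(n_recurrent_genes = dplyr::coalesce(.data$n_recurrent_genes, 0L),
           genes = dplyr::coalesce(.data$genes, ""))
  per_gene <- ev %>%
    group_by(gene = .data$gene) %>%
    summarise(n_animals = n_distinct(.data$animal_id), .groups = "drop")
  list(per_sample = per_sample,
       per_gene_carriers = per_gene,
       n_carrier_animals = n_distinct(ev$animal_id),
       any_cooccurrence = any(per_sample$n_recurrent_genes >= 2))
}
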