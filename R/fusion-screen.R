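#' Normalize RNA-fusion and WGS-SV dialects into one candidate schema
#'
#' RNA candidates (deFuse-like TSV) arrive with gene symbols and strands;
#' WGS candidates (BreakDancer-like TSV) arrive with breakpoints and an SV
#' type only, and their genes are assigned from the annotation (breakpoint
#' inside a gene span, else the nearest gene within `gene_flank`).
#' Breakpoints are ordered canonically (chrom1 <= chrom2, then pos). The
#' two sources are never merged into joint evidence; `source` keeps them
#' apart.
#'
#' @param rna Tibble in the RNA dialect: `sample`, `gene1`, `gene2`,
#'   `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`, `strand2`,
#'   `split_reads`, optional `gene_read_total`.
#' @param wgs Tibble in the WGS dialect: `sample`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2`, `type`, `num_reads`.
#' @param genes Gene-model tibble for WGS gene assignment.
#' @param gene_flank Assignment flank in bp (default 10000).
#' @return A candidate tibble: `sample_id`, `source`, `chrom1`, `pos1`,
#'   `strand1`, `chrom2`, `pos2`, `strand2`, `sv_type`, `read_count`,
#'   `gene1`, `gene2`, `gene_read_total`, `candidate_id`.
#' @export
as_sv_candidates <- function(rna = NULL, wgs = NULL, genes = NULL,
                             gene_flank = 10000) {
  out <- list()
  if (!is.null(rna) && nrow(rna) > 0) {
    out$rna <- as_tibble(rna) %>%
      mutate(sample_id = .data$sample, source = "rna", sv_type = "fusion",
             read_count = as.integer(.data$split_reads),
             gene_read_total = if ("gene_read_total" %in% names(rna))
               as.integer(.data$gene_read_total) else NA_integer_) %>%
      select("sample_id", "source", "chrom1", "pos1", "strand1",
             "chrom2", "pos2", "strand2", "sv_type", "read_count",
             "gene1", "gene2", "gene_read_total")
  }
  if (!is.null(wgs) && nrow(wgs) > 0) {
    w <- as_tibble(wgs) %>%
      mutate(sample_id = .data$sample, source = "wgs",
             sv_type = .data$type, read_count = as.integer(.data$num_reads),
             strand1 = NA_character_, strand2 = NA_character_,
             gene_read_total = NA_integer_)
    if (is.null(genes)) abort("WGS candidates need `genes` for assignment")
    w$gene1 <- breakpoint_gene(w$chrom1, w$pos1, genes, gene_flank)
    w$gene2 <- breakpoint_gene(w$chrom2, w$pos2, genes, gene_flank)
    out$wgs <- w %>%
      select("sample_id", "source", "chrom1", "pos1", "strand1",
             "chrom2", "pos2", "strand2", "sv_type", "read_count",
             "gene1", "gene2", "gene_read_total")
  }
  cand <- bind_rows(out)
  if (nrow(cand) == 0) return(cand)
  # canonical breakpoint order
  flip <- cand$chrom1 > cand$chrom2 |
    (cand$chrom1 == cand$chrom2 & cand$pos1 > cand$pos2)
  swap <- function(a, b, flip) list(if_else(flip, b, a), if_else(flip, a, b))
  c1 <- swap(cand$chrom1, cand$chrom2, flip)
  p1 <- swap(cand$pos1, cand$pos2, flip)
  s1 <- swap(cand$strand1, cand$strand2, flip)
  g1 <- swap(cand$gene1, cand$gene2, flip)
  cand$chrom1 <- c1[[1]]; cand$chrom2 <- c1[[2]]
  cand$pos1 <- p1[[1]]; cand$pos2 <- p1[[2]]
  cand$strand1 <- s1[[1]]; cand$strand2 <- s1[[2]]
  cand$gene1 <- g1[[1]]; cand$gene2 <- g1[[2]]
  cand %>% mutate(candidate_id = row_number())
}

#' @noRd
breakpoint_gene <- function(chrom, pos, genes, flank) {
  vapply(seq_along(chrom), function(i) {
    d <- pmax(genes$start + 1L - pos[i], pos[i] - genes$end, 0)
    hit <- which(genes$chrom == chrom[i] & d <= flank)
    if (length(hit) == 0) return(NA_character_)
    genes$gene[hit[which.min(d[hit])]]
  }, character(1))
}

#' Unordered-pair match key for candidates
#' @noRd
pair_key <- function(cand) {
  has_genes <- !is.na(cand$gene1) & !is.na(cand$gene2)
  key <- character(nrow(cand))
  key[has_genes] <- paste(pmin(cand$gene1[has_genes], cand$gene2[has_genes]),
                          pmax(cand$gene1[has_genes], cand$gene2[has_genes]),
                          sep = "|")
  key[!has_genes] <- NA_character_
  key
}

#' Partition candidates into shared, LM-only and PT-only sets
#'
#' Candidates are matched across tissues on the unordered (gene1, gene2)
#' pair; candidates without gene symbols on both ends are matched on
#' breakpoints, requiring both ends within `match_tolerance` bp (in either
#' orientation).
#'
#' @param lm_candidates,pt_candidates Candidate tibbles
#'   ([as_sv_candidates()]) for metastases and primary tumors.
#' @param match_tolerance Breakpoint tolerance in bp when genes are absent
#'   (default 100).
#' @return A list of tibbles `shared` (LM candidates matched in PT),
#'   `lm_only`, `pt_shared` (PT candidates matched in LM) and `pt_only`;
#'   `nrow(shared) + nrow(lm_only) == nrow(lm_candidates)` and
#'   `nrow(pt_shared) + nrow(pt_only) == nrow(pt_candidates)`.
#' @export
met_specific_set <- function(lm_candidates, pt_candidates,
                             match_tolerance = 100) {
  lm <- as_tibble(lm_candidates)
  pt <- as_tibble(pt_candidates)
  lm_key <- pair_key(lm)
  pt_key <- pair_key(pt)
  bp_match <- function(a, i, b, j) {
    same <- a$chrom1[i] == b$chrom1[j] && a$chrom2[i] == b$chrom2[j] &&
      abs(a$pos1[i] - b$pos1[j]) <= match_tolerance &&
      abs(a$pos2[i] - b$pos2[j]) <= match_tolerance
    swapped <- a$chrom1[i] == b$chrom2[j] && a$chrom2[i] == b$chrom1[j] &&
      abs(a$pos1[i] - b$pos2[j]) <= match_tolerance &&
      abs(a$pos2[i] - b$pos1[j]) <= match_tolerance
    same || swapped
  }
  matched_in <- function(a, akey, b, bkey) {
    vapply(seq_len(nrow(a)), function(i) {
      if (!is.na(akey[i])) return(akey[i] %in% stats::na.omit(bkey))
      any(vapply(seq_len(nrow(b)), function(j) bp_match(a, i, b, j),
                 logical(1)))
    }, logical(1))
  }
  lm_shared <- if (nrow(lm) > 0 && nrow(pt) > 0) {
    matched_in(lm, lm_key, pt, pt_key)
  } else rep(FALSE, nrow(lm))
  pt_shared <- if (nrow(pt) > 0 && nrow(lm) > 0) {
    matched_in(pt, pt_key, lm, lm_key)
  } else rep(FALSE, nrow(pt))
  list(shared = lm[lm_shared, ], lm_only = lm[!lm_shared, ],
       pt_shared = pt[pt_shared, ], pt_only = pt[!pt_shared, ])
}

#' Read-through (adjacent-gene splice) predicate
#'
#' An RNA candidate is a putative transcriptional read-through when its
#' partner genes lie adjacent on the same chromosome and strand with no
#' annotated gene in between, and the breakpoints run 5' to 3' from the
#' upstream into the downstream gene. WGS candidates are never classified
#' as read-through.
#'
#' @param candidates Candidate tibble.
#' @param genes Gene-model tibble.
#' @return Logical vector, `TRUE` for read-through candidates.
#' @export
is_readthrough <- function(candidates, genes) {
  cand <- as_tibble(candidates)
  vapply(seq_len(nrow(cand)), function(i) {
    if (cand$source[i] != "rna") return(FALSE)
    if (is.na(cand$gene1[i]) || is.na(cand$gene2[i])) return(FALSE)
    g1 <- genes[genes$gene == cand$gene1[i], ]
    g2 <- genes[genes$gene == cand$gene2[i], ]
    if (nrow(g1) == 0 || nrow(g2) == 0) return(FALSE)
    if (g1$chrom != g2$chrom || g1$strand != g2$strand) return(FALSE)
    up <- if (g1$start <= g2$start) g1 else g2
    dn <- if (g1$start <= g2$start) g2 else g1
    between <- genes$chrom == up$chrom & genes$start >= up$end &
      genes$end <= dn$start & !genes$gene %in% c(up$gene, dn$gene)
    if (any(between)) return(FALSE)
    # breakpoints must run transcriptionally from upstream into downstream
    p_up <- if (cand$gene1[i] == up$gene) cand$pos1[i] else cand$pos2[i]
    p_dn <- if (cand$gene1[i] == up$gene) cand$pos2[i] else cand$pos1[i]
    if (up$strand == "+") p_up < p_dn else p_up > p_dn
  }, logical(1))
}

#' Support, partner-distance and gene-proximity predicates
#'
#' A candidate passes when it has at least `min_reads` supporting reads,
#' its partners are at least `min_partner_distance` bp apart when on the
#' same chromosome (interchromosomal candidates always pass the distance
#' rule; both thresholds are closed, so exactly 10 kb passes), and each
#' breakpoint lies within `gene_flank` bp of some annotated gene.
#'
#' @param candidates Candidate tibble.
#' @param genes Gene-model tibble.
#' @param min_reads Minimum supporting reads (default 3).
#' @param min_partner_distance Minimum intrachromosomal partner distance in
#'   bp (default 10000).
#' @param gene_flank Maximum breakpoint-to-gene distance in bp (default
#'   10000).
#' @return Tibble of logicals: `pass_support`, `pass_distance`,
#'   `pass_gene_proximity`.
#' @export
support_distance_flags <- function(candidates, genes, min_reads = 3,
                                   min_partner_distance = 10000,
                                   gene_flank = 10000) {
  cand <- as_tibble(candidates)
  near1 <- !is.na(breakpoint_gene(cand$chrom1, cand$pos1, genes, gene_flank))
  near2 <- !is.na(breakpoint_gene(cand$chrom2, cand$pos2, genes, gene_flank))
  tibble(
    pass_support = cand$read_count >= min_reads,
    pass_distance = cand$chrom1 != cand$chrom2 |
      abs(cand$pos2 - cand$pos1) >= min_partner_distance,
    pass_gene_proximity = near1 & near2)
}

#' Classify breakpoints against a repeat-element track
#'
#' @param candidates Candidate tibble.
#' @param repeats Repeat intervals: `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Character vector in `both_repeat`, `one_repeat`, `single_copy`.
#' @export
classify_repeats <- function(candidates, repeats) {
  cand <- as_tibble(candidates)
  in_repeat <- function(chrom, pos) {
    vapply(seq_along(chrom), function(i)
      any(repeats$chrom == chrom[i] & repeats$start <= pos[i] - 1L &
            repeats$end > pos[i] - 1L), logical(1))
  }
  r1 <- in_repeat(cand$chrom1, cand$pos1)
  r2 <- in_repeat(cand$chrom2, cand$pos2)
  case_when(r1 & r2 ~ "both_repeat",
            r1 | r2 ~ "one_repeat",
            TRUE ~ "single_copy")
}

#' Classify candidates by gene-family relationship of the partners
#'
#' Uses an explicit gene-to-family map. With
#' `use_prefix_heuristic = TRUE`, genes absent from the map fall back to a
#' shared-symbol-prefix heuristic (trailing digits stripped); results from
#' the heuristic are still reported as `same_family`/`different_family`,
#' but the fallback is off by default and candidates with unmapped genes
#' are `unassigned`.
#'
#' @param candidates Candidate tibble.
#' @param family_map Tibble `gene`, `family`.
#' @param use_prefix_heuristic Enable the documented fallback heuristic.
#' @return Character vector in `same_family`, `different_family`,
#'   `unassigned`.
#' @export
classify_family <- function(candidates, family_map,
                            use_prefix_heuristic = FALSE) {
  cand <- as_tibble(candidates)
  fam <- setNames(family_map$family, family_map$gene)
  look <- function(g) {
    f <- unname(fam[g])
    if (use_prefix_heuristic) {
      miss <- is.na(f) & !is.na(g)
      f[miss] <- sub("[0-9]+$", "", g[miss])
    }
    f
  }
  f1 <- look(cand$gene1)
  f2 <- look(cand$gene2)
  case_when(is.na(f1) | is.na(f2) ~ "unassigned",
            f1 == f2 ~ "same_family",
            TRUE ~ "different_family")
}

#' Recurrence class and read-fraction per candidate
#'
#' A candidate is `multi_animal` when its unordered gene pair occurs in
#' two or more distinct animals, otherwise `multi_partner` when either
#' partner gene has two or more distinct fusion partners in the cohort,
#' otherwise `single`. For RNA candidates with a `gene_read_total`, the
#' read fraction `read_count / gene_read_total` is reported and flagged
#' when below 1%.
#'
#' @param candidates Candidate tibble.
#' @param sample_sheet Cohort sample sheet (for animal ids).
#' @return `candidates` plus `recurrence`, `read_fraction`, `low_fraction`.
#' @export
recurrence_and_fraction <- function(candidates, sample_sheet) {
  cand <- as_tibble(candidates) %>%
    left_join(sample_sheet[, c("sample_id", "animal_id")], by = "sample_id")
  cand$pair <- pair_key(cand)
  pair_animals <- cand %>%
    filter(!is.na(.data$pair)) %>%
    group_by(.data$pair) %>%
    summarise(n_animals = n_distinct(.data$animal_id), .groups = "drop")
  partners <- bind_rows(
    cand %>% select(gene = "gene1", partner = "gene2"),
    cand %>% select(gene = "gene2", partner = "gene1")) %>%
    filter(!is.na(.data$gene), !is.na(.data$partner)) %>%
    group_by(.data$gene) %>%
    summarise(n_partners = n_distinct(.data$partner), .groups = "drop")
  n_part <- setNames(partners$n_partners, partners$gene)
  pa <- setNames(pair_animals$n_animals, pair_animals$pair)
  if (any(cand$source == "rna" & is.na(cand$gene_read_total))) {
    warn("read fraction unavailable for RNA candidate(s) without gene_read_total")
  }
  cand %>%
    mutate(
      recurrence = case_when(
        !is.na(.data$pair) & pa[.data$pair] >= 2 ~ "multi_animal",
        dplyr::coalesce(n_part[.data$gene1] >= 2, FALSE) |
          dplyr::coalesce(n_part[.data$gene2] >= 2, FALSE) ~ "multi_partner",
        TRUE ~ "single"),
      read_fraction = if_else(is.na(.data$gene_read_total), NA_real_,
                              .data$read_count / .data$gene_read_total),
      low_fraction = !is.na(.data$read_fraction) & .data$read_fraction < 0.01) %>%
    select(-"pair")
}

#' Full fusion/SV curation with an audit trail
#'
#' Runs the complete filter battery on a candidate set and returns every
#' input candidate exactly once with its filter vector (no silent drops).
#' Hard filters deciding `final_keep` are: not a read-through, supporting
#' reads / partner distance / gene proximity, not `both_repeat`, and not
#' `same_family`. `one_repeat` and `low_fraction` are flags only.
#'
#' @param candidates Candidate tibble ([as_sv_candidates()]).
#' @param genes,repeats,family_map Annotation inputs.
#' @param sample_sheet Cohort sample sheet.
#' @param min_reads,min_partner_distance,gene_flank See
#'   [support_distance_flags()].
#' @return The audit tibble with per-filter columns and `final_keep`.
#' @export
fusion_screen <- function(candidates, genes, repeats, family_map,
                          sample_sheet, min_reads = 3,
                          min_partner_distance = 10000, gene_flank = 10000) {
  cand <- as_tibble(candidates)
  if (nrow(cand) == 0) return(cand)
  flags <- support_distance_flags(cand, genes, min_reads,
                                  min_partner_distance, gene_flank)
  audit <- cand %>%
    bind_cols(flags) %>%
    mutate(readthrough = is_readthrough(cand, genes),
           repeat_class = classify_repeats(cand, repeats),
           family_class = classify_family(cand, family_map)) %>%
    recurrence_and_fraction(sample_sheet) %>%
    mutate(final_keep = !.data$readthrough & .data$pass_support &
             .data$pass_distance & .data$pass_gene_proximity &
             .data$repeat_class != "both_repeat" &
             .data$family_class != "same_family")
  audit
}
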