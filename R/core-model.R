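#' Read and validate a cohort sample sheet
#'
#' The sample sheet is the backbone of every analysis stage: it ties samples
#' to animals, declares tissue of origin (primary tumor `PT` or lung
#' metastasis `LM`), records the strain background (`FVB_homozygous` or `F1`
#' with a partner strain), and lists the sequencing platforms available per
#' sample.
#'
#' Matched analyses (metastasis-enrichment filtering, metastasis-specific
#' CNV subtraction) require at least one `PT` sample per animal that has an
#' `LM` sample; an `LM` sample without any matched `PT` triggers a warning
#' but is retained, since unmatched stages (recurrence counting, clustering)
#' can still use it.
#'
#' @param path Path to a UTF-8 TSV with header columns `sample_id`,
#'   `animal_id`, `tissue`, `strain_cross`, `partner_strain`, `platforms`
#'   (comma-joined tokens from `exome`, `rna`, `wgs`).
#' @return A tibble with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           comment = "#", progress = FALSE)
  validate_sample_sheet(as_tibble(sheet))
}

#' Validate an in-memory sample sheet
#'
#' @param sheet A data frame with the columns described in
#'   [read_sample_sheet()].
#' @return The validated tibble (invisibly unchanged apart from column
#'   ordering and type coercion).
#' @export
validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "animal_id", "tissue", "strain_cross",
                "partner_strain", "platforms")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0) {
    abort(paste0("sample sheet is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  sheet <- as_tibble(sheet)[required]
  bad_tissue <- which(!sheet$tissue %in% c("PT", "LM"))
  if (length(bad_tissue) > 0) {
    abort(paste0("unknown tissue '", sheet$tissue[bad_tissue[1]],
                 "' in sample sheet row ", bad_tissue[1],
                 " (expected PT or LM)"))
  }
  bad_cross <- which(!sheet$strain_cross %in% c("FVB_homozygous", "F1"))
  if (length(bad_cross) > 0) {
    abort(paste0("unknown strain_cross '", sheet$strain_cross[bad_cross[1]],
                 "' in sample sheet row ", bad_cross[1]))
  }
  if (anyDuplicated(sheet$sample_id) > 0) {
    dup <- sheet$sample_id[duplicated(sheet$sample_id)][1]
    abort(paste0("duplicated sample_id in sample sheet: ", dup))
  }
  no_partner <- sheet$strain_cross == "F1" &
    (is.na(sheet$partner_strain) | sheet$partner_strain == "")
  if (any(no_partner)) {
    abort(paste0("F1 sample without partner_strain: ",
                 sheet$sample_id[which(no_partner)[1]]))
  }
  pt_animals <- unique(sheet$animal_id[sheet$tissue == "PT"])
  orphan_lm <- sheet$tissue == "LM" & !sheet$animal_id %in% pt_animals
  if (any(orphan_lm)) {
    warn(paste0("LM sample(s) without a matched PT for the animal: ",
                paste(sheet$sample_id[orphan_lm], collapse = ", ")))
  }
  sheet
}

#' Map a sample to its animal's PT sample ids
#' @noRd
matched_pt_samples <- function(sheet, animal) {
  sheet$sample_id[sheet$animal_id == animal & sheet$tissue == "PT"]
}

# ---- coordinate conventions -------------------------------------------------
# Variant sites are 1-based (VCF); interval arithmetic is 0-based half-open
# (BED). A single base at VCF position p is the interval [p-1, p).

#' Convert a 1-based site position to a length-1 half-open interval
#'
#' @param pos Integer vector of 1-based positions.
#' @return A tibble with `start` (0-based) and `end` columns, `end = start + 1`.
#' @export
site_to_interval <- function(pos) {
  stopifnot(all(pos >= 1))
  tibble(start = as.integer(pos) - 1L, end = as.integer(pos))
}

#' Convert a length-1 half-open interval back to a 1-based position
#'
#' @param start Integer vector of 0-based interval starts.
#' @return Integer vector of 1-based positions.
#' @export
interval_to_site <- function(start) {
  as.integer(start) + 1L
}

# ---- gene models ------------------------------------------------------------

#' Read a gene/transcript annotation table
#'
#' The annotation is a BED-like TSV with one row per gene (one canonical
#' transcript per gene) and columns: `chrom`, `start`, `end` (0-based
#' half-open span), `gene`, `family` (gene family id, `.` when unassigned),
#' `strand`, `transcript`, `exon_starts` and `exon_sizes` (comma-joined,
#' absolute 0-based starts), `frames` (comma-joined reading-frame offset per
#' exon, 0/1/2), and `seq` (the plus-strand genomic sequence of the span,
#' embedded so that codon changes can be computed without a reference FASTA).
#'
#' @param path Path to the annotation TSV.
#' @return A tibble with list-columns `exon_starts`, `exon_ends`, `frames`.
#' @export
read_gene_annotation <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "i", end = "i", gene = "c", family = "c",
    strand = "c", transcript = "c", exon_starts = "c", exon_sizes = "c",
    frames = "c", seq = "c"), comment = "#", progress = FALSE)
  parse_int_list <- function(x) map(strsplit(x, ","), as.integer)
  genes <- as_tibble(raw) %>%
    mutate(
      family = if_else(.data$family == ".", NA_character_, .data$family),
      exon_starts = parse_int_list(.data$exon_starts),
      exon_sizes = parse_int_list(.data$exon_sizes),
      frames = parse_int_list(.data$frames)
    ) %>%
    mutate(exon_ends = map2(.data$exon_starts, .data$exon_sizes, `+`)) %>%
    select("chrom", "start", "end", "gene", "family", "strand",
           "transcript", "exon_starts", "exon_ends", "frames", "seq")
  validate_gene_annotation(genes)
}

#' @noRd
validate_gene_annotation <- function(genes) {
  ok <- pmap_lgl_safe(genes, function(row) {
    es <- row$exon_starts; ee <- row$exon_ends
    length(es) == length(ee) &&
      all(es < ee) && all(diff(es) > 0) &&
      all(es >= row$start) && all(ee <= row$end) &&
      all(utils::head(ee, -1) <= utils::tail(es, -1)) &&
      all(row$frames %in% 0:2) &&
      nchar(row$seq) == row$end - row$start
  })
  if (!all(ok)) {
    abort(paste0("malformed gene model: ", genes$gene[which(!ok)[1]]))
  }
  genes
}

#' Row-wise pmap over a tibble returning logical
#' @noRd
pmap_lgl_safe <- function(df, f) {
  vapply(seq_len(nrow(df)), function(i) f(as.list(df[i, ])[] |>
    lapply(function(x) if (is.list(x)) x[[1]] else x)), logical(1))
}

#' Write a gene annotation table (inverse of [read_gene_annotation()])
#'
#' @param genes Gene-model tibble.
#' @param path Output TSV path.
#' @export
write_gene_annotation <- function(genes, path) {
  out <- genes %>%
    mutate(
      family = if_else(is.na(.data$family), ".", .data$family),
      exon_sizes = map2_chr_join(.data$exon_ends, .data$exon_starts),
      exon_starts = map_chr(.data$exon_starts, paste, collapse = ","),
      frames = map_chr(.data$frames, paste, collapse = ",")
    ) %>%
    select("chrom", "start", "end", "gene", "family", "strand",
           "transcript", "exon_starts", "exon_sizes", "frames", "seq")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @noRd
map2_chr_join <- function(ends, starts) {
  map2_chr <- function(x, y, f) vapply(seq_along(x), function(i) f(x[[i]], y[[i]]), character(1))
  map2_chr(ends, starts, function(e, s) paste(e - s, collapse = ","))
}

# ---- codon mapping ----------------------------------------------------------

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Map a variant site to its codon and amino-acid change
#'
#' Projects a single-nucleotide substitution onto the canonical transcript of
#' a gene model and reports the affected codon and the resulting amino-acid
#' change in HGVS-like short form (e.g. `"G12D"`). Sites inside the gene
#' span but outside coding exons (intronic/UTR) return `NA` codon and
#' change. The reading frame is taken from the exon frame offsets, and
#' translation uses the standard genetic code on the coding strand.
#'
#' @param chrom,pos,ref,alt The variant site: chromosome, 1-based position,
#'   reference and alternate bases (single characters in `A`/`C`/`G`/`T`).
#' @param gene A single-row gene-model tibble as produced by
#'   [read_gene_annotation()].
#' @return A one-row tibble with `codon_index` (1-based, `NA` when
#'   non-coding) and `aa_change` (`NA` when non-coding).
#' @examples
#' \dontrun{
#' site_to_codon("chr1", 1035L, "G", "A", gene = my_gene)
#' }
#' @export
site_to_codon <- function(chrom, pos, ref, alt, gene) {
  stopifnot(nrow(gene) == 1)
  g <- as.list(gene)
  g$exon_starts <- g$exon_starts[[1]]
  g$exon_ends <- g$exon_ends[[1]]
  g$frames <- g$frames[[1]]
  pos0 <- pos - 1L  # 0-based coordinate of the site
  if (!identical(chrom, g$chrom) || pos0 < g$start || pos0 >= g$end) {
    abort("site not in gene")
  }
  if (!ref %in% names(COMPLEMENT) || !alt %in% names(COMPLEMENT) || ref == alt) {
    abort("ref/alt must be distinct single bases in A/C/G/T")
  }
  span_seq <- strsplit(g$seq, "")[[1]]
  obs_ref <- span_seq[pos0 - g$start + 1L]
  if (!identical(obs_ref, ref)) {
    abort(paste0("reference mismatch at ", chrom, ":", pos, " (annotation has ",
                 obs_ref, ", call has ", ref, ")"))
  }
  # locate containing exon (exons stored in genomic order)
  exon_i <- which(pos0 >= g$exon_starts & pos0 < g$exon_ends)
  if (length(exon_i) == 0) {
    return(tibble(codon_index = NA_integer_, aa_change = NA_character_))
  }
  exon_lens <- g$exon_ends - g$exon_starts
  if (g$strand == "+") {
    prior <- if (exon_i > 1) sum(exon_lens[seq_len(exon_i - 1)]) else 0L
    cds_pos <- prior + (pos0 - g$exon_starts[exon_i]) + 1L  # 1-based in CDS
  } else {
    n <- length(exon_lens)
    later <- if (exon_i < n) sum(exon_lens[seq(exon_i + 1, n)]) else 0L
    cds_pos <- later + (g$exon_ends[exon_i] - 1L - pos0) + 1L
  }
  # frame offset of the CDS start (transcription-order first exon)
  first_exon <- if (g$strand == "+") 1L else length(exon_lens)
  offset <- g$frames[first_exon]
  frame_pos <- cds_pos + offset
  codon_index <- (frame_pos - 1L) %/% 3L + 1L
  within <- (frame_pos - 1L) %% 3L + 1L
  cds <- cds_sequence(g)
  codon_start <- (codon_index - 1L) * 3L - offset + 1L
  idx <- codon_start:(codon_start + 2L)
  if (any(idx < 1L) || any(idx > length(cds))) {
    # partial codon at a CDS edge: cannot translate
    return(tibble(codon_index = codon_index, aa_change = NA_character_))
  }
  ref_codon <- cds[idx]
  alt_base <- if (g$strand == "+") alt else unname(COMPLEMENT[alt])
  alt_codon <- ref_codon
  alt_codon[within] <- alt_base
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[paste(ref_codon, collapse = "")])
  aa_alt <- unname(code[paste(alt_codon, collapse = "")])
  tibble(codon_index = codon_index,
         aa_change = paste0(aa_ref, codon_index, aa_alt))
}

#' Concatenated coding sequence of a gene model, coding-strand orientation
#' @noRd
cds_sequence <- function(g) {
  span_seq <- strsplit(g$seq, "")[[1]]
  pieces <- lapply(seq_along(g$exon_starts), function(i) {
    span_seq[(g$exon_starts[i] - g$start + 1L):(g$exon_ends[i] - g$start)]
  })
  cds <- unlist(pieces)
  if (g$strand == "-") cds <- rev(unname(COMPLEMENT[cds]))
  cds
}

#' Annotate variant sites with gene, codon and amino-acid change
#'
#' Vectorized companion to [site_to_codon()]: each site is assigned to the
#' gene whose span contains it (first match in annotation order); sites in no
#' gene get `NA` throughout and are reported, never dropped.
#'
#' @param sites A data frame with `chrom`, `pos`, `ref`, `alt`.
#' @param genes Gene-model tibble from [read_gene_annotation()].
#' @return `sites` with added `gene`, `transcript`, `codon_index`,
#'   `aa_change` columns.
#' @export
annotate_sites <- function(sites, genes) {
  sites <- as_tibble(sites)
  ann <- map(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    hit <- which(genes$chrom == s$chrom &
                   genes$start <= s$pos - 1L & genes$end > s$pos - 1L)
    if (length(hit) == 0) {
      return(tibble(gene = NA_character_, transcript = NA_character_,
                    codon_index = NA_integer_, aa_change = NA_character_))
    }
    g <- genes[hit[1], ]
    cod <- site_to_codon(s$chrom, s$pos, s$ref, s$alt, g)
    tibble(gene = g$gene, transcript = g$transcript,
           codon_index = cod$codon_index, aa_change = cod$aa_change)
  })
  bind_cols(sites, bind_rows(ann))
}
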