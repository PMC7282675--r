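PKG_VERSION <- "0.1.0"

#' @noRd
output_header <- function(config_hash = NULL) {
  paste0("# metscreen ", PKG_VERSION,
         if (!is.null(config_hash)) paste0(" config=", config_hash))
}

#' Write a TSV with a tool/config header comment
#' @noRd
write_tsv_stamped <- function(df, path, config_hash = NULL) {
  con <- file(path, open = "wb")  # binary mode: identical bytes everywhere
  on.exit(close(con))
  writeLines(output_header(config_hash), con)
  readr::write_tsv(df, con, progress = FALSE)
  invisible(path)
}

#' @noRd
read_tsv_q <- function(path, col_types) {
  as_tibble(readr::read_tsv(path, col_types = col_types, comment = "#",
                            progress = FALSE))
}

#' Read one caller's VCF into SNV calls
#'
#' Parses a VCF 4.2 with `AD` (and optionally `DP`) in FORMAT into one
#' call per biallelic SNV; multiallelic records are split into one call per
#' alternate allele, and non-SNV records (indels, symbolic alleles) are
#' skipped with a message reporting the count.
#'
#' @param path Path to an uncompressed VCF.
#' @param sample_id,caller Labels attached to every call; default to
#'   values parsed from the filename stem `sample__caller.vcf` when
#'   possible.
#' @return Calls tibble (`sample_id`, `caller`, `chrom`, `pos`, `ref`,
#'   `alt`, `qual`, `ref_count`, `alt_count`, `vaf`).
#' @export
read_snv_vcf <- function(path, sample_id = NULL, caller = NULL) {
  stem <- sub("\\.vcf$", "", basename(path))
  parts <- strsplit(stem, "__", fixed = TRUE)[[1]]
  if (is.null(sample_id)) sample_id <- parts[1]
  if (is.null(caller)) caller <- if (length(parts) > 1) parts[2] else NA_character_
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(sample_id = character(), caller = character(),
                  chrom = character(), pos = integer(), ref = character(),
                  alt = character(), qual = double(),
                  ref_count = integer(), alt_count = integer(),
                  vaf = double()))
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) abort(paste0("VCF has no AD FORMAT field: ", path))
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- fix$REF[i]
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ad_i <- ad[i, 1]
    if (is.na(ad_i)) {
      abort(paste0("missing AD at record ", fix$CHROM[i], ":", fix$POS[i],
                   " in ", path))
    }
    counts <- as.integer(strsplit(ad_i, ",", fixed = TRUE)[[1]])
    for (k in seq_along(alts)) {
      alt <- alts[k]
      if (nchar(ref) != 1 || nchar(alt) != 1 ||
          !ref %in% BASES || !alt %in% BASES) {
        skipped <- skipped + 1L
        next
      }
      out[[length(out) + 1]] <- tibble(
        sample_id = sample_id, caller = caller,
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = ref, alt = alt, qual = as.numeric(fix$QUAL[i]),
        ref_count = counts[1], alt_count = counts[k + 1])
    }
  }
  if (skipped > 0) {
    inform(paste0("skipped ", skipped, " non-SNV allele(s) in ", path))
  }
  calls <- bind_rows(out)
  if (nrow(calls) == 0) {
    return(tibble(sample_id = character(), caller = character(),
                  chrom = character(), pos = integer(), ref = character(),
                  alt = character(), qual = double(),
                  ref_count = integer(), alt_count = integer(),
                  vaf = double()))
  }
  calls %>% mutate(vaf = .data$alt_count /
                     pmax(1L, .data$ref_count + .data$alt_count))
}

#' Write SNV calls of one sample/caller as VCF 4.2
#'
#' Emits `AD` and `DP` in FORMAT and the Phred-scaled quality in QUAL.
#' Output is byte-deterministic (no timestamps).
#'
#' @param calls Calls tibble for a single sample and caller.
#' @param path Output path.
#' @param config_hash Optional configuration hash recorded in the header.
#' @return The path, invisibly.
#' @export
write_snv_vcf <- function(calls, path, config_hash = NULL) {
  calls <- as_tibble(calls) %>% arrange(.data$chrom, .data$pos)
  sample_id <- if (nrow(calls) > 0) calls$sample_id[1] else "sample"
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=metscreen-", PKG_VERSION),
           if (!is.null(config_hash)) paste0("##config_hash=", config_hash),
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_id, sep = "\t"))
  body <- if (nrow(calls) > 0) {
    dp <- calls$ref_count + calls$alt_count
    paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
          formatC(calls$qual, format = "fg"), "PASS", ".", "AD:DP",
          paste0(calls$ref_count, ",", calls$alt_count, ":", dp),
          sep = "\t")
  } else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read / write BED intervals
#'
#' Three required columns (`chrom`, 0-based `start`, `end`) plus an
#' optional `name`; no header, `#` comments allowed.
#'
#' @param path BED path.
#' @return Interval tibble.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  bad <- suppressWarnings(is.na(as.integer(df$X2)) | is.na(as.integer(df$X3)))
  if (any(bad)) {
    abort(paste0("malformed coordinate in ", path, ":", which(bad)[1]))
  }
  out <- tibble(chrom = df$X1, start = as.integer(df$X2),
                end = as.integer(df$X3))
  if (ncol(df) >= 4) out$name <- df$X4
  if (any(out$start < 0 | out$start >= out$end)) {
    abort(paste0("invalid interval in ", path))
  }
  out
}

#' @rdname read_bed
#' @param intervals Interval tibble with `chrom`, `start`, `end` and
#'   optional `name`.
#' @param config_hash Optional configuration hash recorded as a comment.
#' @export
write_bed <- function(intervals, path, config_hash = NULL) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(output_header(config_hash), con)
  readr::write_tsv(intervals[cols], con, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Readers for the cohort TSV dialects
#'
#' `read_allele_counts()`: `chrom`, `pos`, `countA_FVB`, `countB_partner`
#' (mapped to `count_A`/`count_B`); `read_fusion_rna()`: the deFuse-like
#' RNA dialect; `read_sv_wgs()`: the BreakDancer-like WGS dialect with
#' `Type` in DEL/INV/ITX/interchromosomal; `read_family_map()`: `gene`,
#' `family`; `read_expression_flags()`: `gene`, `transcribed` 0/1.
#'
#' @param path File path.
#' @param sample_id Optional sample label for per-sample allele-count
#'   files (defaults to the filename stem).
#' @return A typed tibble.
#' @export
read_allele_counts <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- sub("\\.tsv$", "", basename(path))
  df <- read_tsv_q(path, readr::cols(chrom = "c", pos = "i",
                                     countA_FVB = "i", countB_partner = "i"))
  tibble(sample_id = sample_id, chrom = df$chrom, pos = df$pos,
         count_A = df$countA_FVB, count_B = df$countB_partner)
}

#' @rdname read_allele_counts
#' @export
read_fusion_rna <- function(path) {
  read_tsv_q(path, readr::cols(sample = "c", gene1 = "c", gene2 = "c",
                               chrom1 = "c", pos1 = "i", strand1 = "c",
                               chrom2 = "c", pos2 = "i", strand2 = "c",
                               split_reads = "i", gene_read_total = "i"))
}

#' @rdname read_allele_counts
#' @export
read_sv_wgs <- function(path) {
  df <- read_tsv_q(path, readr::cols(sample = "c", chrom1 = "c", pos1 = "i",
                                     chrom2 = "c", pos2 = "i", type = "c",
                                     num_reads = "i"))
  bad <- !df$type %in% c("DEL", "INV", "ITX", "interchromosomal")
  if (any(bad)) {
    abort(paste0("unknown SV type '", df$type[which(bad)[1]], "' in ",
                 path, " line ", which(bad)[1]))
  }
  df
}

#' @rdname read_allele_counts
#' @export
read_family_map <- function(path) {
  read_tsv_q(path, readr::cols(gene = "c", family = "c"))
}

#' @rdname read_allele_counts
#' @export
read_expression_flags <- function(path) {
  read_tsv_q(path, readr::cols(gene = "c", transcribed = "i"))
}

# ---- cohort serialization ---------------------------------------------------

#' Serialize a simulated cohort to a run directory
#'
#' Writes every external-format file the pipeline consumes, plus the truth
#' JSON and the simulation config. Rerunning with the same config yields
#' byte-identical trees.
#'
#' @param sim A `met_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "met_cohort"))
  h <- rlang::hash(sim$config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "vcf"), showWarnings = FALSE)
  dir.create(file.path(dir, "allele_counts"), showWarnings = FALSE)
  write_tsv_stamped(sim$sample_sheet, file.path(dir, "sample_sheet.tsv"), h)
  write_gene_annotation(sim$genes %>% select(-dplyr::any_of("role")),
                        file.path(dir, "genes.tsv"))
  write_bed(sim$repeats, file.path(dir, "repeats.bed"), h)
  write_tsv_stamped(sim$family_map, file.path(dir, "family_map.tsv"), h)
  write_tsv_stamped(sim$expression, file.path(dir, "expression.tsv"), h)
  write_tsv_stamped(sim$fusion_rna, file.path(dir, "fusions_rna.tsv"), h)
  write_tsv_stamped(sim$sv_wgs, file.path(dir, "sv_wgs.tsv"), h)
  write_tsv_stamped(sim$rna_calls, file.path(dir, "rna_calls.tsv"), h)
  for (sid in unique(sim$snv_calls$sample_id)) {
    for (cl in unique(sim$snv_calls$caller)) {
      calls <- sim$snv_calls %>%
        filter(.data$sample_id == sid, .data$caller == cl)
      write_snv_vcf(calls, file.path(dir, "vcf",
                                     paste0(sid, "__", cl, ".vcf")), h)
    }
  }
  for (sid in unique(sim$allele_counts$sample_id)) {
    ac <- sim$allele_counts %>%
      filter(.data$sample_id == sid) %>%
      select(chrom = "chrom", pos = "pos", countA_FVB = "count_A",
             countB_partner = "count_B")
    write_tsv_stamped(ac, file.path(dir, "allele_counts",
                                    paste0(sid, ".tsv")), h)
  }
  jsonlite::write_json(
    lapply(sim$truth, function(x) if (is.data.frame(x)) x else x),
    file.path(dir, "truth.json"), dataframe = "rows", digits = NA)
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a cohort run directory written by [write_cohort()]
#'
#' @param dir Run directory.
#' @return A `met_cohort`-shaped list (without the simulation config class;
#'   `truth` is included when `truth.json` is present).
#' @export
read_cohort <- function(dir) {
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  genes <- read_gene_annotation(file.path(dir, "genes.tsv"))
  vcfs <- list.files(file.path(dir, "vcf"), pattern = "\\.vcf$",
                     full.names = TRUE)
  snv_calls <- bind_rows(lapply(sort(vcfs), read_snv_vcf))
  acs <- list.files(file.path(dir, "allele_counts"), pattern = "\\.tsv$",
                    full.names = TRUE)
  allele_counts <- bind_rows(lapply(sort(acs), read_allele_counts))
  truth <- NULL
  if (file.exists(file.path(dir, "truth.json"))) {
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
    truth <- lapply(truth, as_tibble)
  }
  list(sample_sheet = sheet, genes = genes,
       repeats = read_bed(file.path(dir, "repeats.bed")),
       family_map = read_family_map(file.path(dir, "family_map.tsv")),
       expression = read_expression_flags(file.path(dir, "expression.tsv")),
       fusion_rna = read_fusion_rna(file.path(dir, "fusions_rna.tsv")),
       sv_wgs = read_sv_wgs(file.path(dir, "sv_wgs.tsv")),
       rna_calls = read_tsv_q(file.path(dir, "rna_calls.tsv"),
                              readr::cols(sample_id = "c", chrom = "c",
                                          pos = "i", ref = "c", alt = "c")),
       snv_calls = snv_calls, allele_counts = allele_counts, truth = truth)
}
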