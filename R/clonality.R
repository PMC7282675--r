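#' Build the binned CNV / SNV fingerprint matrix
#'
#' Codes each sample's genome into 4000-bp copy-number bins (-1 loss, 0
#' neutral, +1 gain; a bin takes the state covering the majority of its
#' bases, ties and neutral majorities give 0) and presence/absence SNV
#' features (0/1). Features that are non-reference in fewer than
#' `min_samples` samples are dropped.
#'
#' @param segments Segment tibble with `sample_id`, `chrom`, `start`,
#'   `end`, `state` (`loss`/`gain`).
#' @param snvs SNV tibble with `sample_id`, `chrom`, `pos`.
#' @param samples Ordered character vector of samples to include (the
#'   sample-sheet order fixes clustering tie-breaks); defaults to the
#'   samples seen in the inputs.
#' @param bin_size CNV bin width in bp (default 4000).
#' @param min_samples Minimum samples sharing a feature (default 2).
#' @return A `met_fingerprints` object: `matrix` (samples x features),
#'   `features` tibble, `samples`, `bin_size`.
#' @export
build_fingerprints <- function(segments, snvs, samples = NULL,
                               bin_size = 4000, min_samples = 2) {
  segments <- as_tibble(segments)
  snvs <- as_tibble(snvs)
  if (is.null(samples)) {
    samples <- unique(c(segments$sample_id, snvs$sample_id))
  }
  bin_size <- as.integer(bin_size)

  # CNV block: per (sample, bin) state coverage in bases
  cnv_codes <- NULL
  if (nrow(segments) > 0) {
    binned <- segments %>%
      filter(.data$state %in% c("loss", "gain")) %>%
      mutate(first_bin = .data$start %/% bin_size,
             last_bin = (.data$end - 1L) %/% bin_size) %>%
      rowwise_expand_bins(bin_size)
    cnv_codes <- binned %>%
      group_by(.data$sample_id, .data$chrom, .data$bin_start) %>%
      summarise(loss_cov = sum(.data$cov[.data$state == "loss"]),
                gain_cov = sum(.data$cov[.data$state == "gain"]),
                .groups = "drop") %>%
      mutate(neutral_cov = bin_size - .data$loss_cov - .data$gain_cov,
             code = case_when(
               .data$loss_cov > .data$gain_cov &
                 .data$loss_cov > .data$neutral_cov ~ -1L,
               .data$gain_cov > .data$loss_cov &
                 .data$gain_cov > .data$neutral_cov ~ 1L,
               TRUE ~ 0L)) %>%
      filter(.data$code != 0L)
  }
  snv_codes <- NULL
  if (nrow(snvs) > 0) {
    snv_codes <- snvs %>%
      distinct(.data$sample_id, .data$chrom, .data$pos) %>%
      mutate(code = 1L)
  }

  feature_block <- function(codes, kind, locus_cols) {
    if (is.null(codes) || nrow(codes) == 0) return(NULL)
    codes <- codes %>%
      mutate(feature = paste0(kind, ":", .data$chrom, ":",
                              .data[[locus_cols]]))
    keep <- codes %>%
      group_by(.data$feature) %>%
      summarise(n = n_distinct(.data$sample_id), .groups = "drop") %>%
      filter(.data$n >= min_samples) %>%
      pull("feature")
    codes %>% filter(.data$feature %in% keep)
  }
  cnv_long <- feature_block(cnv_codes, "cnv_bin", "bin_start")
  snv_long <- feature_block(snv_codes, "snv_site", "pos")
  long <- bind_rows(cnv_long, snv_long)
  features <- if ("feature" %in% names(long)) {
    as.character(sort(unique(long$feature)))
  } else character(0)
  mat <- matrix(0L, nrow = length(samples), ncol = length(features),
                dimnames = list(samples, features))
  if (nrow(long) > 0) {
    long <- long %>% filter(.data$sample_id %in% samples)
    mat[cbind(match(long$sample_id, samples),
              match(long$feature, features))] <- long$code
  }
  feat_tbl <- tibble(
    feature = features,
    kind = if_else(startsWith(features, "cnv_bin"), "cnv_bin", "snv_site"))
  structure(list(matrix = mat, features = feat_tbl, samples = samples,
                 bin_size = bin_size, min_samples = min_samples),
            class = "met_fingerprints")
}

#' Expand segments to (bin, coverage) rows
#' @noRd
rowwise_expand_bins <- function(segs, bin_size) {
  n_bins <- segs$last_bin - segs$first_bin + 1L
  idx <- rep(seq_len(nrow(segs)), n_bins)
  bin <- unlist(lapply(seq_len(nrow(segs)), function(i)
    seq(segs$first_bin[i], segs$last_bin[i])))
  bin_start <- bin * bin_size
  cov <- pmin(segs$end[idx], bin_start + bin_size) -
    pmax(segs$start[idx], bin_start)
  tibble(sample_id = segs$sample_id[idx], chrom = segs$chrom[idx],
         state = segs$state[idx], bin_start = as.integer(bin_start),
         cov = as.integer(cov))
}

#' @export
print.met_fingerprints <- function(x, ...) {
  cat("<met_fingerprints> ", length(x$samples), " samples x ",
      ncol(x$matrix), " features (",
      sum(x$features$kind == "cnv_bin"), " cnv_bin, ",
      sum(x$features$kind == "snv_site"), " snv_site), bin size ",
      x$bin_size, " bp\n", sep = "")
  invisible(x)
}

#' @export
tidy.met_fingerprints <- function(x, ...) {
  as_tibble(as.data.frame.table(x$matrix, responseName = "code",
                                stringsAsFactors = FALSE)) %>%
    rename(sample_id = "Var1", feature = "Var2") %>%
    left_join(x$features, by = "feature") %>%
    mutate(code = as.integer(.data$code))
}

#' @export
autoplot.met_fingerprints <- function(object, ...) {
  tidy(object) %>%
    ggplot(aes(x = .data$feature, y = .data$sample_id,
               fill = .data$code)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0) +
    facet_wrap(~kind, scales = "free_x") +
    labs(x = NULL, y = NULL, fill = "code") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Combined fingerprint distance
#'
#' Jaccard distance on the binary SNV block, Manhattan distance on the
#' -1/0/+1 CNV block scaled to `[0, 1]` by its maximum (2 per feature),
#' combined as a weighted sum (weights renormalized over the blocks
#' present).
#'
#' @param fp A `met_fingerprints` object.
#' @param weights Named weights for the `cnv` and `snv` blocks.
#' @return A `dist` object over the samples, in their given order.
#' @export
fingerprint_dist <- function(fp, weights = c(cnv = 0.5, snv = 0.5)) {
  stopifnot(inherits(fp, "met_fingerprints"))
  cnv <- fp$matrix[, fp$features$kind == "cnv_bin", drop = FALSE]
  snv <- fp$matrix[, fp$features$kind == "snv_site", drop = FALSE]
  n <- length(fp$samples)
  zero <- matrix(0, n, n)
  d_cnv <- if (ncol(cnv) > 0) {
    as.matrix(stats::dist(cnv, method = "manhattan")) / (2 * ncol(cnv))
  } else NULL
  d_snv <- if (ncol(snv) > 0) {
    m <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        a <- snv[i, ] == 1L; b <- snv[j, ] == 1L
        un <- sum(a | b)
        m[i, j] <- if (un == 0) 0 else 1 - sum(a & b) / un
      }
    }
    m
  } else NULL
  w <- c(cnv = if ("cnv" %in% names(weights)) weights[["cnv"]] else 0.5,
         snv = if ("snv" %in% names(weights)) weights[["snv"]] else 0.5)
  used <- c(cnv = !is.null(d_cnv), snv = !is.null(d_snv))
  if (!any(used)) {
    combined <- zero
  } else {
    wsum <- sum(w[used])
    combined <- zero
    if (used["cnv"]) combined <- combined + w["cnv"] / wsum * d_cnv
    if (used["snv"]) combined <- combined + w["snv"] / wsum * d_snv
  }
  rownames(combined) <- colnames(combined) <- fp$samples
  as.dist(combined)
}

#' Hierarchical clustering of fingerprint samples
#'
#' Complete-linkage (configurable) agglomerative clustering on the
#' combined fingerprint distance. The dendrogram is deterministic: ties are
#' broken by the sample order of the fingerprint object (use sample-sheet
#' order when building it).
#'
#' @param fp A `met_fingerprints` object.
#' @param weights Block weights, see [fingerprint_dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return A `met_clust` object wrapping the `hclust` fit, the distance
#'   matrix and the feature count.
#' @export
cluster_fingerprints <- function(fp, weights = c(cnv = 0.5, snv = 0.5),
                                 linkage = "complete") {
  if (length(fp$samples) < 2) abort("clustering needs at least 2 samples")
  d <- fingerprint_dist(fp, weights)
  hc <- hclust(d, method = linkage)
  structure(list(hclust = hc, dist = d, samples = fp$samples,
                 n_features = ncol(fp$matrix), linkage = linkage),
            class = "met_clust")
}

#' @export
print.met_clust <- function(x, ...) {
  cat("<met_clust> ", length(x$samples), " samples, ", x$n_features,
      " features, ", x$linkage, " linkage\n", sep = "")
  invisible(x)
}

#' @export
tidy.met_clust <- function(x, ...) {
  hc <- x$hclust
  tibble(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
         height = hc$height)
}

#' @export
glance.met_clust <- function(x, ...) {
  tibble(n_samples = length(x$samples), n_features = x$n_features,
         linkage = x$linkage, max_height = max(c(0, x$hclust$height)))
}

#' Cophenetic distances of a fingerprint clustering
#' @param x A `met_clust` object.
#' @return A `dist` object of cophenetic distances.
#' @export
cophenetic_dist <- function(x) {
  stats::cophenetic(x$hclust)
}

#' @export
autoplot.met_clust <- function(object, ...) {
  hc <- object$hclust
  n <- length(object$samples)
  leaf_x <- match(seq_len(n), hc$order)
  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  seg <- list()
  x_of <- function(k) if (k < 0) leaf_x[-k] else node_x[k]
  h_of <- function(k) if (k < 0) 0 else node_h[k]
  for (m in seq_len(nrow(hc$merge))) {
    a <- hc$merge[m, 1]; b <- hc$merge[m, 2]
    xa <- x_of(a); xb <- x_of(b)
    node_x[m] <- (xa + xb) / 2
    seg[[length(seg) + 1]] <- tibble(
      x = c(xa, xa, xb), xend = c(xa, xb, xb),
      y = c(h_of(a), node_h[m], node_h[m]),
      yend = c(node_h[m], node_h[m], h_of(b)))
  }
  labels <- tibble(x = leaf_x, label = object$samples)
  ggplot(bind_rows(seg)) +
    geom_segment(aes(x = .data$x, xend = .data$xend, y = .data$y,
                     yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = labels$x, labels = labels$label) +
    labs(x = NULL, y = "distance") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}

#' Leaf sets of every internal node of an hclust tree
#' @noRd
node_leaf_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[m, ]
    leaves <- integer(0)
    for (k in kids) {
      leaves <- c(leaves, if (k < 0) -k else sets[[k]])
    }
    sets[[m]] <- sort(leaves)
  }
  sets
}

#' Mono- versus polyclonal seeding calls per animal
#'
#' An animal with two or more metastases is called
#' `monoclonal_seeding` when its LM samples form a clade of their own: the
#' smallest dendrogram node containing all of them contains nothing else.
#' If any other sample (another animal's, or a primary tumor) falls inside
#' that clade, the metastases are not each other's closest relatives and
#' the seeding is `polyclonal_seeding`. Animals with fewer than two LM
#' samples in the clustering, or a clustering with no informative
#' features, are `indeterminate`.
#'
#' @param clust A `met_clust` object.
#' @param sample_sheet Cohort sample sheet.
#' @return Tibble: `animal_id`, `verdict`, `n_lm`, `clade_size`,
#'   `clade_samples`.
#' @export
call_clonality <- function(clust, sample_sheet) {
  stopifnot(inherits(clust, "met_clust"))
  hc <- clust$hclust
  sets <- node_leaf_sets(hc)
  res <- lapply(unique(sample_sheet$animal_id), function(a) {
    lm_ids <- sample_sheet$sample_id[sample_sheet$animal_id == a &
                                       sample_sheet$tissue == "LM"]
    lm_idx <- match(lm_ids, clust$samples)
    lm_idx <- lm_idx[!is.na(lm_idx)]
    if (length(lm_idx) < 2 || clust$n_features == 0) {
      return(tibble(animal_id = a, verdict = "indeterminate",
                    n_lm = length(lm_idx), clade_size = NA_integer_,
                    clade_samples = NA_character_))
    }
    # MRCA: smallest node whose leaf set contains all the animal's LMs
    containing <- which(vapply(sets, function(s) all(lm_idx %in% s),
                               logical(1)))
    mrca <- containing[which.min(lengths(sets[containing]))]
    clade <- sets[[mrca]]
    pure <- all(clust$samples[clade] %in% lm_ids)
    tibble(animal_id = a,
           verdict = if (pure) "monoclonal_seeding" else "polyclonal_seeding",
           n_lm = length(lm_idx), clade_size = length(clade),
           clade_samples = paste(clust$samples[clade], collapse = ","))
  })
  bind_rows(res)
}
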