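# Community-level CAZyme statistics: per-MAG densities, class comparisons,
# Bray-Curtis composition dissimilarity, per-genus section summaries, and
# pooled enzyme counts per co-abundant group.

#' Per-MAG CAZyme profiles and densities
#'
#' Density is CAZymes per 1000 genes by default, or per Mbp of genome when
#' the configuration says so; the per-gene unit is robust to genome
#' incompleteness.
#'
#' @param calls Consensus calls with `mag_id` and `family`.
#' @param mag_meta MAG metadata (provides `n_genes`, `genome_size` and
#'   taxonomy).
#' @param config A [pipeline_config()].
#' @return A data.frame, one row per MAG: `mag_id`, `class_label`,
#'   `genus_label`, `n_genes`, `n_cazymes`, `density`, plus a
#'   `family_counts` attribute (long data.frame mag_id/family/count).
#' @export
mag_profiles <- function(calls, mag_meta, config = pipeline_config()) {
  if (any(mag_meta$n_genes <= 0L))
    stop("mag_profiles: n_genes must be > 0 for every MAG")
  n_caz <- table(factor(calls$mag_id, levels = mag_meta$mag_id))
  dens <- if (config$density_unit == "per_1000_genes") {
    1000 * as.numeric(n_caz) / mag_meta$n_genes
  } else {
    as.numeric(n_caz) / (mag_meta$genome_size / 1e6)
  }
  prof <- data.frame(
    mag_id = mag_meta$mag_id,
    class_label = mag_meta$class,
    genus_label = mag_meta$genus,
    n_genes = mag_meta$n_genes,
    n_cazymes = as.integer(n_caz),
    density = dens,
    stringsAsFactors = FALSE
  )
  fc <- if (nrow(calls)) {
    x <- as.data.frame(table(calls$mag_id, calls$family),
                       stringsAsFactors = FALSE)
    names(x) <- c("mag_id", "family", "count")
    x[x$count > 0L, , drop = FALSE]
  } else {
    data.frame(mag_id = character(), family = character(),
               count = integer(), stringsAsFactors = FALSE)
  }
  rownames(fc) <- NULL
  attr(prof, "family_counts") <- fc
  prof
}

#' Compare CAZyme density between two taxon classes
#'
#' Two-sided Wilcoxon rank-sum test on per-MAG densities. Small untied
#' samples use the exact distribution; otherwise the tie-corrected normal
#' approximation with continuity correction is used (the
#' [stats::wilcox.test()] default).
#'
#' @param profiles Output of [mag_profiles()].
#' @param class_a,class_b Class labels to compare.
#' @return A list with `statistic` (rank-sum W), `p_value`, `n_a`, `n_b`.
#' @export
compare_density_classes <- function(profiles, class_a, class_b) {
  x <- profiles$density[profiles$class_label == class_a]
  y <- profiles$density[profiles$class_label == class_b]
  if (length(x) < 2L || length(y) < 2L)
    stop("each class needs at least 2 MAGs")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(x), n_b = length(y))
}

#' Bray-Curtis dissimilarity between MAG CAZyme compositions
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i) over family features. The
#' default feature is the per-family count vector scaled by gene count
#' (a density composition); raw counts are available. Pairs where both
#' profiles are all-zero are undefined and returned as NA with a warning,
#' never silently 0.
#'
#' @param profiles Output of [mag_profiles()] (the `family_counts`
#'   attribute provides the feature vectors).
#' @param feature "density" (default) or "counts".
#' @return A symmetric numeric matrix with zero diagonal, entries in
#'   \[0, 1\] (or NA for undefined pairs).
#' @export
bray_curtis_matrix <- function(profiles, feature = c("density", "counts")) {
  feature <- match.arg(feature)
  if (nrow(profiles) < 2L) stop("need at least 2 profiles")
  fc <- attr(profiles, "family_counts")
  fams <- sort(unique(fc$family))
  mat <- matrix(0, nrow = nrow(profiles), ncol = length(fams),
                dimnames = list(profiles$mag_id, fams))
  if (nrow(fc))
    mat[cbind(match(fc$mag_id, profiles$mag_id),
              match(fc$family, fams))] <- fc$count
  if (feature == "density")
    mat <- 1000 * mat / profiles$n_genes
  zero <- rowSums(mat) == 0
  d <- as.matrix(suppressWarnings(vegan::vegdist(mat, method = "bray")))
  if (any(zero)) {
    und <- outer(zero, zero, "&")
    diag(und) <- FALSE
    if (any(und)) {
      warning("Bray-Curtis undefined for all-zero profile pair(s); set to NA")
      d[und] <- NA_real_
    }
  }
  diag(d) <- 0
  d
}

#' Per-taxon section abundance summaries with Kruskal-Wallis tests
#'
#' Aggregates MAG relative abundances to a taxonomy rank per sample, then
#' summarizes per section (mean and sd over fish) and tests for differences
#' across sections with the tie-corrected Kruskal-Wallis chi-square
#' approximation. Raw p-values are reported (as is conventional for these
#' per-genus screens) with a Benjamini-Hochberg column alongside.
#'
#' @param abundance Abundance table (samples x MAGs, percent).
#' @param sample_meta Sample metadata; only metagenome samples are used.
#' @param mag_meta MAG metadata (taxonomy).
#' @param level Taxonomy rank to aggregate at (default "genus").
#' @return A data.frame with one row per taxon x section: `mean`, `sd`,
#'   `n_fish`, plus per-taxon `kw_p` and `kw_p_bh` (NA with a warning when
#'   any section has fewer than 2 fish).
#' @export
genus_section_summary <- function(abundance, sample_meta, mag_meta,
                                  level = "genus") {
  if (!level %in% TAXONOMY_RANKS) stop("unknown taxonomy rank: ", level)
  meta <- sample_meta[sample_meta$assay == "metagenome", , drop = FALSE]
  ab <- abundance[match(meta$sample_id, abundance$sample_id), , drop = FALSE]
  mags <- setdiff(names(ab), "sample_id")
  taxon <- mag_meta[[level]][match(mags, mag_meta$mag_id)]
  taxon[is.na(taxon) | taxon == ""] <- "unclassified"
  vals <- as.matrix(ab[, mags, drop = FALSE])
  taxa <- sort(unique(taxon))
  agg <- sapply(taxa, function(tx)
    rowSums(vals[, taxon == tx, drop = FALSE]))
  agg <- matrix(agg, nrow = nrow(vals), dimnames = list(NULL, taxa))
  sections <- sort(unique(meta$section))
  rows <- list(); kw <- numeric(length(taxa)); names(kw) <- taxa
  small <- any(table(meta$section) < 2L)
  if (small)
    warning("a section has fewer than 2 fish; Kruskal-Wallis p omitted")
  for (tx in taxa) {
    for (sec in sections) {
      v <- agg[meta$section == sec, tx]
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = tx, section = sec, mean = mean(v), sd = stats::sd(v),
        n_fish = length(v), stringsAsFactors = FALSE)
    }
    kw[tx] <- if (small || length(sections) < 2L) NA_real_
      else if (length(unique(agg[, tx])) == 1L) 1  # all tied: H = 0
      else stats::kruskal.test(agg[, tx], factor(meta$section))$p.value
  }
  res <- do.call(rbind, rows)
  res$kw_p <- kw[res$taxon]
  bh <- stats::p.adjust(kw, method = "BH")
  res$kw_p_bh <- bh[res$taxon]
  rownames(res) <- NULL
  res
}

#' Pooled enzyme counts per co-abundant group
#'
#' Sums consensus-call gene counts per (group, class, enzyme label); each
#' gene contributes to exactly one enzyme label (its consensus call). Calls
#' in MAGs outside every group are pooled under "ungrouped". Per enzyme the
#' number of encoding MAGs and the HMW/LMW capacity flag are reported.
#'
#' @param calls Consensus calls with `mag_id`.
#' @param groups Co-abundant groups ([delineate_groups()] output).
#' @param mag_meta MAG metadata (class labels).
#' @param catalog Substrate catalog (enzyme labels, weight classes).
#' @return A data.frame: `group_id`, `class_label`, `enzyme_label`,
#'   `n_genes`, `n_mags`, `weight_class`, `substrates`.
#' @export
pool_enzyme_counts <- function(calls, groups, mag_meta, catalog) {
  group_of <- rep("ungrouped", nrow(mag_meta))
  names(group_of) <- mag_meta$mag_id
  if (nrow(groups$members))
    group_of[groups$members$mag_id] <- groups$members$group_id
  empty <- data.frame(group_id = character(), class_label = character(),
                      enzyme_label = character(), n_genes = integer(),
                      n_mags = integer(), weight_class = character(),
                      substrates = character(), stringsAsFactors = FALSE)
  if (!nrow(calls)) return(empty)
  rules <- classify_family(calls$family, catalog)
  wc <- call_weight_class(calls, catalog)
  df <- data.frame(
    group_id = unname(group_of[calls$mag_id]),
    class_label = mag_meta$class[match(calls$mag_id, mag_meta$mag_id)],
    enzyme_label = ifelse(rules$mapped, rules$enzyme_label,
                          paste0("unmapped ", calls$family)),
    mag_id = calls$mag_id,
    weight_class = ifelse(is.na(wc), "NA", wc),
    substrates = vapply(rules$substrates, function(s)
      paste(sort(s), collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  key <- interaction(df$group_id, df$class_label, df$enzyme_label, drop = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    data.frame(group_id = g$group_id[1], class_label = g$class_label[1],
               enzyme_label = g$enzyme_label[1], n_genes = nrow(g),
               n_mags = length(unique(g$mag_id)),
               weight_class = g$weight_class[1],
               substrates = g$substrates[1], stringsAsFactors = FALSE)
  }))
  out <- out[order(out$group_id, out$class_label, out$enzyme_label), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
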