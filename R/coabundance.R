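# Co-abundance analysis: pairwise Pearson correlation of MAG relative
# abundances across samples, significance masking, delineation of
# co-abundant groups, and section IV -> V fold changes. Correlations are
# computed on closed (relative) data exactly as practitioners report them;
# no log-ratio transform is applied (a compositional caveat, not a bug).

#' Pairwise Pearson correlations of MAG relative abundances
#'
#' r is the product-moment coefficient; the two-sided p-value comes from
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom, with p = 0
#' for |r| = 1. Constant-abundance MAGs cannot be correlated and are
#' excluded with a warning.
#'
#' @param abundance Abundance table (samples x MAGs, percent).
#' @return An object of class `correlation_matrix`: list with `r`, `p`
#'   (symmetric matrices) and `n` (samples used).
#' @export
correlate_abundances <- function(abundance) {
  mags <- setdiff(names(abundance), "sample_id")
  x <- as.matrix(abundance[, mags, drop = FALSE])
  n <- nrow(x)
  if (n < 3L) stop("correlation requires at least 3 samples")
  const <- apply(x, 2L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("excluding constant-abundance MAG(s): ",
            paste(mags[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  r <- stats::cor(x)
  r[r > 1] <- 1; r[r < -1] <- -1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-15] <- 0
  diag(r) <- 1
  diag(p) <- 0
  structure(list(r = r, p = p, n = n), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d MAGs over %d samples\n",
              ncol(x$r), x$n))
  invisible(x)
}

#' Delineate co-abundant MAG groups
#'
#' Average-linkage hierarchical clustering on 1 - r is cut at
#' `config$group_cut_height`; within each cut cluster, MAGs are linked by
#' significant positive edges (p <= alpha and r >= min_r) and connected
#' components of at least `group_min_size` members become groups. Groups
#' are labelled A1, A2, ... when enriched in section IV and B1, B2, ...
#' when stable or enriched in section V, ordered by summed relative
#' abundance; the result is invariant to MAG input order.
#'
#' @param corr A [correlate_abundances()] result.
#' @param abundance Abundance table (for ordering and section trends).
#' @param sample_meta Sample metadata (sections); when absent all groups are
#'   labelled G1, G2, ...
#' @param config A [pipeline_config()] (alpha, min_r, cut height, min size,
#'   fold-change pseudocount).
#' @return A list with `groups` (group_id, n_members, mean_within_r,
#'   section_trend) and `members` (group_id, mag_id).
#' @export
delineate_groups <- function(corr, abundance, sample_meta = NULL,
                             config = pipeline_config()) {
  r <- corr$r
  p <- corr$p
  mags <- colnames(r)
  comp_id <- rep(NA_integer_, length(mags))
  names(comp_id) <- mags
  if (length(mags) >= 2L) {
    hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
    cut <- stats::cutree(hc, h = config$group_cut_height)
    edge <- p <= config$corr_alpha & r >= config$corr_min_r
    edge[outer(cut, cut, "!=")] <- FALSE
    diag(edge) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(edge, mode = "undirected")
    comp <- igraph::components(g)$membership
    comp_id[] <- comp[mags]
  }
  sizes <- table(comp_id)
  valid <- names(sizes)[sizes >= config$group_min_size]
  keep <- !is.na(comp_id) & comp_id %in% as.integer(valid)
  empty <- list(groups = data.frame(group_id = character(),
                                    n_members = integer(),
                                    mean_within_r = numeric(),
                                    section_trend = character(),
                                    stringsAsFactors = FALSE),
                members = data.frame(group_id = character(),
                                     mag_id = character(),
                                     stringsAsFactors = FALSE))
  if (!any(keep)) return(empty)
  comp_kept <- comp_id[keep]
  mags_kept <- mags[keep]
  tot_ab <- colSums(as.matrix(
    abundance[, setdiff(names(abundance), "sample_id"), drop = FALSE]))
  fc <- if (!is.null(sample_meta))
    section_fold_change(abundance, sample_meta,
                        eps = config$fc_pseudocount, quiet = TRUE) else NULL
  stats_per <- lapply(unique(comp_kept), function(cid) {
    mm <- sort(mags_kept[comp_kept == cid])
    rr <- r[mm, mm, drop = FALSE]
    mean_r <- mean(rr[upper.tri(rr)])
    trend <- "stable"
    if (!is.null(fc)) {
      mfc <- mean(fc$log10_fc[match(mm, fc$mag_id)], na.rm = TRUE)
      if (is.finite(mfc)) {
        if (mfc > 0.1) trend <- "V-enriched"
        else if (mfc < -0.1) trend <- "IV-enriched"
      }
    }
    list(members = mm, mean_r = mean_r, trend = trend,
         abundance = sum(tot_ab[mm]))
  })
  ab_order <- order(-vapply(stats_per, `[[`, numeric(1), "abundance"),
                    vapply(stats_per, function(s) s$members[1], character(1)))
  stats_per <- stats_per[ab_order]
  prefix <- vapply(stats_per, function(s)
    if (s$trend == "IV-enriched") "A" else
      if (s$trend %in% c("V-enriched", "stable")) "B" else "G",
    character(1))
  if (is.null(sample_meta)) prefix[] <- "G"
  idx <- stats::ave(seq_along(prefix), prefix, FUN = seq_along)
  gid <- paste0(prefix, idx)
  groups <- data.frame(
    group_id = gid,
    n_members = vapply(stats_per, function(s) length(s$members), integer(1)),
    mean_within_r = vapply(stats_per, `[[`, numeric(1), "mean_r"),
    section_trend = vapply(stats_per, `[[`, character(1), "trend"),
    stringsAsFactors = FALSE
  )
  members <- do.call(rbind, lapply(seq_along(gid), function(i)
    data.frame(group_id = gid[i], mag_id = stats_per[[i]]$members,
               stringsAsFactors = FALSE)))
  rownames(groups) <- rownames(members) <- NULL
  list(groups = groups, members = members)
}

#' Section IV to V log10 fold changes
#'
#' Per MAG: log10((mean_V + eps) / (mean_IV + eps)), means taken over the
#' metagenome samples of each section. MAGs absent (all-zero) from both
#' sections carry no information and are omitted with a note.
#'
#' @param abundance Abundance table (percent).
#' @param sample_meta Sample metadata; sections IV and V are used.
#' @param eps Pseudocount in percentage points (default 0.01).
#' @param quiet Suppress the omission message.
#' @return A data.frame: `mag_id`, `mean_IV`, `mean_V`, `log10_fc`.
#' @export
section_fold_change <- function(abundance, sample_meta, eps = 0.01,
                                quiet = FALSE) {
  meta <- sample_meta[sample_meta$assay == "metagenome" &
                        sample_meta$section %in% c("IV", "V"), , drop = FALSE]
  if (!all(c("IV", "V") %in% meta$section))
    stop("fold change requires samples from both sections IV and V")
  ab <- abundance[match(meta$sample_id, abundance$sample_id), , drop = FALSE]
  mags <- setdiff(names(ab), "sample_id")
  x <- as.matrix(ab[, mags, drop = FALSE])
  m_iv <- colMeans(x[meta$section == "IV", , drop = FALSE])
  m_v <- colMeans(x[meta$section == "V", , drop = FALSE])
  absent <- m_iv == 0 & m_v == 0
  if (any(absent) && !quiet)
    message("omitting MAG(s) absent from both sections: ",
            paste(mags[absent], collapse = ", "))
  keep <- !absent
  data.frame(mag_id = mags[keep], mean_IV = unname(m_iv[keep]),
             mean_V = unname(m_v[keep]),
             log10_fc = unname(log10((m_v[keep] + eps) / (m_iv[keep] + eps))),
             stringsAsFactors = FALSE)
}

#' Per-group HMW/LMW capability panel
#'
#' For each co-abundant group, substrate and weight class: the pooled gene
#' count over member MAGs and the fraction of member MAGs with at least one
#' such call. Mirrors the per-group substrate enrichment panels used to
#' interpret complementary degradative capacity.
#'
#' @param groups [delineate_groups()] output.
#' @param calls Consensus calls with `mag_id`.
#' @param catalog Substrate catalog.
#' @return A data.frame: `group_id`, `substrate`, `weight_class`,
#'   `n_genes`, `mag_fraction`.
#' @export
group_capability_panel <- function(groups, calls, catalog) {
  poly <- setdiff(SUBSTRATE_PANELS, c("sulfatase", "mannitol"))
  out <- list()
  rules <- if (nrow(calls)) classify_family(calls$family, catalog) else NULL
  wc_call <- if (nrow(calls)) call_weight_class(calls, catalog) else character()
  for (gi in seq_len(nrow(groups$groups))) {
    gid <- groups$groups$group_id[gi]
    mm <- groups$members$mag_id[groups$members$group_id == gid]
    for (s in poly) {
      for (w in c("HMW", "LMW")) {
        if (nrow(calls)) {
          sel <- calls$mag_id %in% mm & !is.na(wc_call) & wc_call == w &
            vapply(rules$substrates, function(z) s %in% z, logical(1))
        } else sel <- logical(0)
        out[[length(out) + 1L]] <- data.frame(
          group_id = gid, substrate = s, weight_class = w,
          n_genes = sum(sel),
          mag_fraction = if (length(mm))
            length(unique(calls$mag_id[sel])) / length(mm) else 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(group_id = character(), substrate = character(),
               weight_class = character(), n_genes = integer(),
               mag_fraction = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
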