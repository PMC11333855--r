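# Relative transcript expression of CAZymes, sulfatases and CGC-member
# CAZymes per gut section and taxon class, and selection of the most
# expressed substrate-assigned clusters.

EXPRESSION_CATEGORIES <- c("CAZyme", "sulfatase", "CGC_CAZyme")

#' Relative expression by taxon class
#'
#' For each gut section and category (CAZyme, sulfatase, CAZyme within a
#' CGC), transcript counts are summed per taxon class and normalized within
#' the (section, category) pair to fractions summing to 1. CGC-member
#' CAZymes are a subset of the CAZyme category, so a gene can contribute to
#' both. Sections with zero total counts in a category are emitted as
#' missing (NA fractions).
#'
#' @param expr Transcript-count table (genes x samples).
#' @param sample_meta Sample metadata; metatranscriptome samples are used.
#' @param calls Consensus CAZyme calls (with `mag_id`).
#' @param sulf_calls Accepted sulfatase calls (with `mag_id`).
#' @param cgcs A `cgc_set` (members define CGC CAZymes); may be NULL.
#' @param mag_meta MAG metadata (class labels).
#' @return A data.frame: `section`, `category`, `class_label`, `count`,
#'   `fraction`.
#' @export
relative_expression_by_class <- function(expr, sample_meta, calls,
                                         sulf_calls, cgcs, mag_meta) {
  meta <- sample_meta[sample_meta$assay == "metatranscriptome", ,
                      drop = FALSE]
  samples <- intersect(meta$sample_id, setdiff(names(expr), "gene_id"))
  if (!length(samples)) stop("no metatranscriptome samples in expression table")
  meta <- meta[meta$sample_id %in% samples, , drop = FALSE]
  cgc_genes <- if (!is.null(cgcs))
    cgcs$members$gene_id[cgcs$members$role == "CAZyme"] else character()
  cat_genes <- list(
    CAZyme = calls$protein_id,
    sulfatase = sulf_calls$protein_id,
    CGC_CAZyme = intersect(cgc_genes, calls$protein_id)
  )
  gene2mag <- c(stats::setNames(calls$mag_id, calls$protein_id),
                stats::setNames(sulf_calls$mag_id, sulf_calls$protein_id))
  classes <- sort(unique(mag_meta$class))
  out <- list()
  for (sec in sort(unique(meta$section))) {
    ssel <- meta$sample_id[meta$section == sec]
    for (cat_nm in EXPRESSION_CATEGORIES) {
      genes <- cat_genes[[cat_nm]]
      idx <- match(genes, expr$gene_id)
      genes <- genes[!is.na(idx)]
      idx <- idx[!is.na(idx)]
      counts <- if (length(idx))
        rowSums(as.matrix(expr[idx, ssel, drop = FALSE])) else numeric()
      mag <- gene2mag[genes]
      cls <- mag_meta$class[match(mag, mag_meta$mag_id)]
      per_class <- vapply(classes, function(k)
        sum(counts[!is.na(cls) & cls == k]), numeric(1))
      total <- sum(per_class)
      frac <- if (total > 0) per_class / total else rep(NA_real_,
                                                        length(classes))
      out[[length(out) + 1L]] <- data.frame(
        section = sec, category = cat_nm, class_label = classes,
        count = unname(per_class), fraction = unname(frac),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select the most expressed substrate-assigned clusters
#'
#' Cluster expression in a sample is the sum of member-gene transcript
#' counts; its share is relative to all substrate-assigned clusters in that
#' sample. A cluster is selected when it belongs to the minimal set of
#' top-share clusters whose cumulative share reaches the upper `quantile`
#' (default 0.25) of total cluster expression in ANY sample of the section.
#' Ties at the selection boundary are all included, making the choice
#' invariant to input order and to count scaling.
#'
#' @param expr Transcript-count table.
#' @param sample_meta Sample metadata (metatranscriptome samples).
#' @param cgcs A substrate-assigned `cgc_set`.
#' @param section Gut section ("III", "IV" or "V").
#' @param quantile Upper expression share to cover (default 0.25).
#' @return A data.frame of selected clusters with `cgc_id`, `substrates`
#'   and `max_share` (largest per-sample share observed).
#' @export
top_cgc_by_expression <- function(expr, sample_meta, cgcs, section,
                                  quantile = 0.25) {
  meta <- sample_meta[sample_meta$assay == "metatranscriptome" &
                        sample_meta$section == section, , drop = FALSE]
  samples <- intersect(meta$sample_id, setdiff(names(expr), "gene_id"))
  cl <- cgcs$clusters[cgcs$clusters$substrates != "", , drop = FALSE]
  empty <- data.frame(cgc_id = character(), substrates = character(),
                      max_share = numeric(), stringsAsFactors = FALSE)
  if (!nrow(cl) || !length(samples)) return(empty)
  mem <- cgcs$members[cgcs$members$cgc_id %in% cl$cgc_id, , drop = FALSE]
  idx <- match(mem$gene_id, expr$gene_id)
  selected <- character()
  max_share <- stats::setNames(rep(0, nrow(cl)), cl$cgc_id)
  for (smp in samples) {
    counts <- rep(0, nrow(mem))
    counts[!is.na(idx)] <- as.numeric(expr[[smp]][idx[!is.na(idx)]])
    ce <- tapply(counts, factor(mem$cgc_id, levels = cl$cgc_id), sum)
    ce[is.na(ce)] <- 0
    total <- sum(ce)
    if (total <= 0) next
    share <- ce / total
    max_share <- pmax(max_share, share)
    o <- order(-share)
    cum <- cumsum(share[o])
    k <- which(cum >= quantile - 1e-12)[1]
    thr <- share[o][k]
    selected <- union(selected, names(share)[share >= thr & share > 0])
  }
  sel <- cl[cl$cgc_id %in% selected, , drop = FALSE]
  res <- data.frame(cgc_id = sel$cgc_id, substrates = sel$substrates,
                    max_share = unname(max_share[sel$cgc_id]),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
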