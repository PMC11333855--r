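# End-to-end pipeline over an on-disk input bundle. Analysis is seed-free:
# re-running on identical inputs and configuration yields byte-identical
# primary TSV outputs. Partial outputs are removed on failure.

REQUIRED_INPUTS <- c(
  genes = "genes.gff3",
  cazyme_hits = "cazyme_hits.tsv",
  sulfatase_hits = "sulfatase_hits.tsv",
  domain_hits = "domain_hits.tsv",
  mag_metadata = "mag_metadata.tsv",
  abundance = "abundance.tsv",
  sample_metadata = "sample_metadata.tsv",
  transcript_counts = "transcript_counts.tsv")

#' Run the full profiling pipeline
#'
#' Reads an input bundle (gene table, annotation evidence, MAG metadata,
#' abundance and transcript tables), applies MAG quality filtering,
#' consensus CAZyme and sulfatase annotation, capability-matrix
#' construction, CGC detection and substrate inference, community
#' statistics, co-abundance grouping and expression summaries, and writes
#' every result as TSV together with a run log echoing the configuration.
#'
#' @param config A [pipeline_config()].
#' @param input_dir Directory holding the input bundle (see
#'   [generate_community()] for the layout).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory results.
#' @export
run_pipeline <- function(config, input_dir, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- file.path(input_dir, REQUIRED_INPUTS)
  names(paths) <- names(REQUIRED_INPUTS)
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]]))
      stop(gsub("_", " ", nm), " not found: ", paths[[nm]])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    res <- pipeline_compute(config, paths)
    written <<- pipeline_write(res, config, out_dir)
    invisible(res)
  }, error = on_fail)
}

pipeline_compute <- function(config, paths) {
  genes <- read_gene_table(paths[["genes"]])
  hits <- read_annotation_hits(paths[["cazyme_hits"]])
  sulf_hits <- read_annotation_hits(paths[["sulfatase_hits"]])
  dom_hits <- read_tsv_exact(paths[["domain_hits"]])
  mag_meta_all <- read_mag_metadata(paths[["mag_metadata"]])
  abundance <- read_abundance_table(paths[["abundance"]])
  sample_meta <- read_sample_metadata(paths[["sample_metadata"]])
  expr <- read_transcript_counts(paths[["transcript_counts"]])
  catalog <- load_substrate_catalog()

  mag_meta <- filter_mags(mag_meta_all, config$min_completeness,
                          config$max_contamination)
  retained <- mag_meta$mag_id
  genes <- genes[genes$mag_id %in% retained, , drop = FALSE]

  calls <- consensus_annotate(hits, config, gene_map = genes)
  sulf_calls <- accept_sulfatase(sulf_hits, config, domain_hits = dom_hits,
                                 gene_map = genes)
  sulf_calls <- sulf_calls[sulf_calls$mag_id %in% retained, , drop = FALSE]
  mannitol <- mannitol_genotypes(genes, mag_ids = retained)
  capability <- build_capability_matrix(calls, sulf_calls, mannitol,
                                        mag_meta, catalog)
  weight_classes <- count_weight_classes(calls, catalog)

  roles <- assign_gene_roles(genes, calls)
  cgcs <- detect_cgcs(genes, roles, config)
  cgcs <- flag_degradative(cgcs, config)
  cgcs <- infer_substrates(cgcs, catalog)
  cgc_summary <- summarize_cgcs_by_taxon(cgcs, mag_meta, level = "class")
  cgc_summary_genus <- summarize_cgcs_by_taxon(cgcs, mag_meta,
                                               level = "genus")

  profiles <- mag_profiles(calls, mag_meta, config)
  bray <- if (nrow(profiles) >= 2L) bray_curtis_matrix(profiles) else NULL
  density_tests <- density_test_table(profiles)
  section_summary <- genus_section_summary(abundance, sample_meta, mag_meta)

  corr <- correlate_abundances(abundance)
  groups <- delineate_groups(corr, abundance, sample_meta, config)
  fold_changes <- section_fold_change(abundance, sample_meta,
                                      eps = config$fc_pseudocount,
                                      quiet = TRUE)
  panel <- group_capability_panel(groups, calls, catalog)
  pooled <- pool_enzyme_counts(calls, groups, mag_meta, catalog)

  expression <- relative_expression_by_class(expr, sample_meta, calls,
                                             sulf_calls, cgcs, mag_meta)
  rna_sections <- sort(unique(
    sample_meta$section[sample_meta$assay == "metatranscriptome"]))
  top_cgcs <- do.call(rbind, lapply(rna_sections, function(sec) {
    sel <- top_cgc_by_expression(expr, sample_meta, cgcs, sec)
    if (nrow(sel)) sel$section <- sec else sel$section <- character()
    sel
  }))
  if (is.null(top_cgcs))
    top_cgcs <- data.frame(cgc_id = character(), substrates = character(),
                           max_share = numeric(), section = character(),
                           stringsAsFactors = FALSE)

  list(mag_meta = mag_meta, calls = calls, sulf_calls = sulf_calls,
       mannitol = mannitol, capability = capability,
       weight_classes = weight_classes, cgcs = cgcs,
       cgc_summary = cgc_summary, cgc_summary_genus = cgc_summary_genus,
       profiles = profiles, bray = bray, density_tests = density_tests,
       section_summary = section_summary, corr = corr, groups = groups,
       fold_changes = fold_changes, panel = panel, pooled = pooled,
       expression = expression, top_cgcs = top_cgcs)
}

density_test_table <- function(profiles) {
  cls <- names(which(table(profiles$class_label) >= 2L))
  out <- list()
  if (length(cls) >= 2L) {
    pairs <- utils::combn(sort(cls), 2L)
    for (j in seq_len(ncol(pairs))) {
      cmp <- compare_density_classes(profiles, pairs[1, j], pairs[2, j])
      out[[j]] <- data.frame(class_a = pairs[1, j], class_b = pairs[2, j],
                             statistic = cmp$statistic,
                             p_value = cmp$p_value, n_a = cmp$n_a,
                             n_b = cmp$n_b, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(class_a = character(), class_b = character(),
               statistic = numeric(), p_value = numeric(),
               n_a = integer(), n_b = integer(), stringsAsFactors = FALSE)
}

pipeline_write <- function(res, config, out_dir) {
  f <- function(name) file.path(out_dir, name)
  written <- character()
  w <- function(x, name) {
    write_tsv_exact(x, f(name))
    written <<- c(written, f(name))
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written)) # partial outputs removed on failure
  w(res$calls, "consensus_calls.tsv")
  w(res$sulf_calls, "sulfatase_calls.tsv")
  cap <- data.frame(mag_id = rownames(res$capability),
                    as.data.frame(unclass(res$capability)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  w(cap, "capability_matrix.tsv")
  w(attr(res$capability, "evidence"), "capability_evidence.tsv")
  w(res$weight_classes, "weight_classes.tsv")
  w(res$cgcs$clusters, "cgc_clusters.tsv")
  w(res$cgcs$members, "cgc_members.tsv")
  w(res$cgc_summary, "cgc_summary_class.tsv")
  w(res$cgc_summary_genus, "cgc_summary_genus.tsv")
  w(res$profiles, "mag_profiles.tsv")
  if (!is.null(res$bray)) {
    bc <- data.frame(mag_id = rownames(res$bray),
                     as.data.frame(res$bray), check.names = FALSE,
                     stringsAsFactors = FALSE)
    w(bc, "bray_curtis.tsv")
  }
  w(res$density_tests, "density_tests.tsv")
  w(res$section_summary, "genus_section_summary.tsv")
  corr_long <- correlation_long(res$corr)
  w(corr_long, "correlation.tsv")
  w(res$groups$groups, "coabund_groups.tsv")
  w(res$groups$members, "coabund_members.tsv")
  w(res$fold_changes, "fold_changes.tsv")
  w(res$panel, "group_capability_panel.tsv")
  w(res$pooled, "pooled_enzyme_counts.tsv")
  w(res$expression, "expression_by_class.tsv")
  w(res$top_cgcs, "top_cgcs.tsv")
  log_path <- f("run_log.txt")
  lines <- c("cazyprofiler run log", "configuration:",
             vapply(names(unclass(config)), function(nm)
               sprintf("  %s: %s", nm, format(config[[nm]])), character(1)),
             sprintf("retained MAGs: %d", nrow(res$mag_meta)),
             sprintf("consensus CAZyme calls: %d", nrow(res$calls)),
             sprintf("sulfatase calls: %d", nrow(res$sulf_calls)),
             sprintf("CGCs: %d (degradative %d, substrate-assigned %d)",
                     nrow(res$cgcs$clusters),
                     sum(res$cgcs$clusters$degradative),
                     sum(res$cgcs$clusters$substrates != "")))
  writeLines(lines, log_path)
  ok <- TRUE
  c(written, log_path)
}

correlation_long <- function(corr) {
  mags <- colnames(corr$r)
  idx <- which(upper.tri(corr$r), arr.ind = TRUE)
  out <- data.frame(mag_a = mags[idx[, 1]], mag_b = mags[idx[, 2]],
                    r = corr$r[idx], p = corr$p[idx], n = corr$n,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mag_a, out$mag_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
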