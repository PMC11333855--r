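# CAZyme gene cluster (CGC) detection and substrate inference. A cluster is
# a maximal run of signature genes (CAZyme, transporter TC, transcription
# factor TF, signal transduction protein STP) in which consecutive signature
# genes are separated by at most `cgc_max_gap` non-signature genes, holding
# at least one CAZyme and at least one non-CAZyme signature gene. Strand is
# ignored: polysaccharide-utilization loci are frequently mixed-strand.

SIGNATURE_ROLES <- c("CAZyme", "TC", "TF", "STP")

#' Assign gene roles for cluster detection
#'
#' A gene's role is CAZyme iff an accepted consensus call exists for its
#' protein; otherwise the role is read from the gene's product label when it
#' is one of TC/TF/STP (transporter, transcription factor, signal
#' transduction), and "other" in every remaining case.
#'
#' @param genes Gene table (see [read_gene_table()]).
#' @param calls Consensus CAZyme calls.
#' @return A data.frame `gene_id`, `role`, `family` (NA unless CAZyme).
#' @export
assign_gene_roles <- function(genes, calls) {
  idx <- match(genes$gene_id, calls$protein_id)
  role <- ifelse(!is.na(idx), "CAZyme",
                 ifelse(genes$product_label %in% c("TC", "TF", "STP"),
                        genes$product_label, "other"))
  role[is.na(role)] <- "other"
  data.frame(gene_id = genes$gene_id, role = role,
             family = ifelse(is.na(idx), NA_character_, calls$family[idx]),
             stringsAsFactors = FALSE)
}

#' Detect CAZyme gene clusters
#'
#' Finds maximal runs of signature genes under the gap rule, per contig.
#' Input genes must already be sorted by (mag_id, contig_id, start);
#' clusters never span contigs. Detection is fully deterministic.
#'
#' @param genes Sorted gene table.
#' @param roles Role assignment from [assign_gene_roles()].
#' @param config A [pipeline_config()]; `cgc_max_gap` controls the gap rule.
#' @return An object of class `cgc_set`: a list with `clusters` (one row per
#'   cluster) and `members` (one row per member gene, intervening
#'   non-signature genes included).
#' @export
detect_cgcs <- function(genes, roles, config = pipeline_config()) {
  n <- nrow(genes)
  ck <- paste(genes$mag_id, genes$contig_id, sep = "\r")
  if (n > 1L) {
    same <- ck[-1L] == ck[-n]
    if (is.unsorted(order(genes$mag_id, genes$contig_id, genes$start)) ||
        any(same & diff(genes$start) < 0L))
      stop("detect_cgcs: genes must be sorted by (mag_id, contig_id, start)")
  }
  role <- roles$role[match(genes$gene_id, roles$gene_id)]
  if (anyNA(role)) stop("detect_cgcs: roles must cover every gene")
  fam <- roles$family[match(genes$gene_id, roles$gene_id)]
  sig <- role %in% SIGNATURE_ROLES
  empty <- empty_cgc_set()
  if (!any(sig)) return(empty)
  si <- which(sig)                       # global row indices of signature genes
  sk <- ck[si]
  m <- length(si)
  new_run <- c(TRUE, sk[-1L] != sk[-m] |
                 (si[-1L] - si[-m] - 1L) > config$cgc_max_gap)
  run_id <- cumsum(new_run)
  first <- tapply(si, run_id, min)
  last <- tapply(si, run_id, max)
  has_caz <- tapply(role[si] == "CAZyme", run_id, any)
  has_other_sig <- tapply(role[si] != "CAZyme", run_id, any)
  keep <- which(has_caz & has_other_sig)
  if (!length(keep)) return(empty)
  first <- first[keep]; last <- last[keep]
  ordc <- order(first)
  first <- first[ordc]; last <- last[ordc]
  cgc_id <- sprintf("CGC_%05d", seq_along(first))
  clusters <- data.frame(
    cgc_id = cgc_id,
    mag_id = genes$mag_id[first],
    contig_id = genes$contig_id[first],
    start = genes$start[first],
    end = genes$end[last],
    first_gene = genes$gene_id[first],
    last_gene = genes$gene_id[last],
    n_members = last - first + 1L,
    stringsAsFactors = FALSE
  )
  midx <- unlist(mapply(seq, first, last, SIMPLIFY = FALSE))
  members <- data.frame(
    cgc_id = rep(cgc_id, clusters$n_members),
    gene_id = genes$gene_id[midx],
    role = role[midx],
    family = fam[midx],
    start = genes$start[midx],
    stringsAsFactors = FALSE
  )
  rownames(clusters) <- rownames(members) <- NULL
  structure(list(clusters = clusters, members = members), class = "cgc_set")
}

empty_cgc_set <- function() {
  structure(list(
    clusters = data.frame(cgc_id = character(), mag_id = character(),
                          contig_id = character(), start = integer(),
                          end = integer(), first_gene = character(),
                          last_gene = character(), n_members = integer(),
                          stringsAsFactors = FALSE),
    members = data.frame(cgc_id = character(), gene_id = character(),
                         role = character(), family = character(),
                         start = integer(), stringsAsFactors = FALSE)),
    class = "cgc_set")
}

#' Flag degradative clusters
#'
#' Counts member genes whose consensus family mechanism is GH, PL or CE
#' (carbohydrate-binding modules, glycosyltransferases and auxiliary
#' activities bind or build, they do not cleave) and flags clusters with at
#' least `cgc_min_degradative` such genes.
#'
#' @param cgcs A `cgc_set` from [detect_cgcs()].
#' @param config A [pipeline_config()].
#' @return The `cgc_set` with `n_degradative` and `degradative` columns
#'   added to `clusters`.
#' @export
flag_degradative <- function(cgcs, config = pipeline_config()) {
  mech <- cazy_mechanism(cgcs$members$family)
  isdeg <- !is.na(mech) & mech %in% DEGRADATIVE_MECHANISMS
  cnt <- tapply(isdeg, cgcs$members$cgc_id, sum)
  cgcs$clusters$n_degradative <-
    as.integer(cnt[match(cgcs$clusters$cgc_id, names(cnt))])
  cgcs$clusters$n_degradative[is.na(cgcs$clusters$n_degradative)] <- 0L
  cgcs$clusters$degradative <-
    cgcs$clusters$n_degradative >= config$cgc_min_degradative
  cgcs
}

#' Infer cluster substrates
#'
#' Substrates are assigned from the cluster's degradative member families
#' (GH/PL/CE): (a) every dedicated family's substrate is included with
#' evidence "dedicated"; (b) an ambiguous family's candidate substrate is
#' included with evidence "colocalization" iff at least one other member
#' family supports the same substrate. Clusters with no resolvable substrate
#' keep an empty set and are counted as unclassified; only degradative
#' clusters are assigned. Surviving ties are reported multi-label.
#'
#' @param cgcs A degradative-flagged `cgc_set`.
#' @param catalog Substrate catalog.
#' @return The `cgc_set` with `substrates` (semicolon-joined), `evidence`
#'   (substrate:kind pairs) and `multi` columns added to `clusters`.
#' @export
infer_substrates <- function(cgcs, catalog) {
  if (is.null(cgcs$clusters$degradative))
    stop("run flag_degradative() before infer_substrates()")
  poly <- setdiff(SUBSTRATE_PANELS, c("sulfatase", "mannitol"))
  cl <- cgcs$clusters
  cl$substrates <- ""
  cl$evidence <- ""
  cl$multi <- FALSE
  for (i in seq_len(nrow(cl))) {
    if (!cl$degradative[i]) next
    mem <- cgcs$members[cgcs$members$cgc_id == cl$cgc_id[i], , drop = FALSE]
    mech <- cazy_mechanism(mem$family)
    fams <- unique(mem$family[!is.na(mech) & mech %in% DEGRADATIVE_MECHANISMS])
    if (!length(fams)) next
    rules <- classify_family(fams, catalog)
    ded <- character(); col <- character()
    for (j in seq_along(fams)) {
      subs <- intersect(rules$substrates[[j]], poly)
      if (rules$dedicated[j]) ded <- union(ded, subs)
    }
    for (j in seq_along(fams)) {
      if (rules$dedicated[j]) next
      subs <- intersect(rules$substrates[[j]], poly)
      for (s in subs) {
        others <- vapply(seq_along(fams), function(k)
          k != j && s %in% rules$substrates[[k]], logical(1))
        if (any(others)) col <- union(col, s)
      }
    }
    col <- setdiff(col, ded)
    subs_all <- c(sort(ded), sort(col))
    if (!length(subs_all)) next
    ev <- c(if (length(ded)) paste0(sort(ded), ":dedicated"),
            if (length(col)) paste0(sort(col), ":colocalization"))
    cl$substrates[i] <- paste(subs_all, collapse = ";")
    cl$evidence[i] <- paste(ev, collapse = ";")
    cl$multi[i] <- length(subs_all) > 1L
  }
  cgcs$clusters <- cl
  cgcs
}

#' Summarize clusters by taxon
#'
#' Totals and per-MAG means of clusters per taxon at a chosen rank. Means
#' and standard deviations are computed over all MAGs of the taxon,
#' including MAGs with zero clusters.
#'
#' @param cgcs A substrate-assigned `cgc_set`.
#' @param mag_meta MAG metadata of the MAGs to summarize.
#' @param level Taxonomy rank ("domain" ... "species").
#' @return A data.frame with one row per taxon: MAG count, totals of all /
#'   degradative / substrate-assigned clusters, and mean +/- sd per MAG of
#'   each.
#' @export
summarize_cgcs_by_taxon <- function(cgcs, mag_meta, level = "class") {
  if (!level %in% TAXONOMY_RANKS)
    stop("unknown taxonomy rank: ", level)
  taxon <- mag_meta[[level]]
  taxon[is.na(taxon) | taxon == ""] <- "unclassified"
  cl <- cgcs$clusters
  per_mag <- function(flag) {
    cnt <- table(factor(cl$mag_id[flag], levels = mag_meta$mag_id))
    as.numeric(cnt)
  }
  tot <- per_mag(rep(TRUE, nrow(cl)))
  deg <- per_mag(if (nrow(cl)) cl$degradative else logical(0))
  sub <- per_mag(if (nrow(cl)) cl$substrates != "" else logical(0))
  taxa <- sort(unique(taxon))
  res <- data.frame(
    taxon = taxa,
    n_mags = as.integer(tapply(rep(1L, length(taxon)), taxon, sum)[taxa]),
    total = as.integer(tapply(tot, taxon, sum)[taxa]),
    degradative = as.integer(tapply(deg, taxon, sum)[taxa]),
    substrate_assigned = as.integer(tapply(sub, taxon, sum)[taxa]),
    mean_total = as.numeric(tapply(tot, taxon, mean)[taxa]),
    sd_total = as.numeric(tapply(tot, taxon, stats::sd)[taxa]),
    mean_substrate_assigned = as.numeric(tapply(sub, taxon, mean)[taxa]),
    sd_substrate_assigned = as.numeric(tapply(sub, taxon, stats::sd)[taxa]),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' @export
print.cgc_set <- function(x, ...) {
  cat(sprintf("<cgc_set> %d clusters over %d member genes\n",
              nrow(x$clusters), nrow(x$members)))
  if (!is.null(x$clusters$degradative))
    cat(sprintf("  degradative: %d; substrate-assigned: %d\n",
                sum(x$clusters$degradative),
                if (is.null(x$clusters$substrates)) NA_integer_
                else sum(x$clusters$substrates != "")))
  invisible(x)
}
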