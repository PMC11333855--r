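# Consensus CAZyme annotation: three independent evidence streams (profile
# HMM, k-mer classifier, similarity search) are merged per protein; a family
# is called only when at least two streams agree, with the reported label
# taken from the highest-priority agreeing stream (HMMER, then eCAMI, then
# DIAMOND).

SOURCE_PRIORITY <- c(HMMER = 1L, eCAMI = 2L, DIAMOND = 3L)

#' Collapse a subfamily label to its CAZy family
#'
#' Annotation streams report at different granularity (e.g., "GH13_10"
#' versus "GH13"); agreement is tested at family level. Sulfatase S1
#' subfamilies are not CAZy labels and are left untouched.
#'
#' @param label Character vector of family labels.
#' @return Labels with CAZy subfamily suffixes removed.
#' @export
collapse_subfamily <- function(label) {
  sub("^((GH|PL|CE|CBM|GT|AA)[0-9]+)_[0-9]+$", "\\1", label)
}

cazy_mechanism <- function(family) {
  hit <- regexpr("^(GH|PL|CE|CBM|GT|AA)", family)
  ifelse(hit > 0L, substr(family, 1L, attr(hit, "match.length")),
         NA_character_)
}

#' Merge multi-stream evidence into a consensus CAZyme call
#'
#' A call is made iff at least two annotation sources agree on a family
#' (after subfamily collapse). The reported family is taken from the
#' highest-priority agreeing source (HMMER, then eCAMI, then DIAMOND); when
#' a source reports several agreeing families, its best e-value wins. An
#' attached EC number is reported only when an EC-carrying hit for the
#' called family passes the EC acceptance filter.
#'
#' @param hits Annotation hits for a single protein
#'   (see [read_annotation_hits()]).
#' @param config A [pipeline_config()]. The e-value cutoff is assumed to
#'   have been applied at load time; it is not re-applied here.
#' @param collapse Collapse subfamily labels before testing agreement
#'   (default TRUE).
#' @return A one-row data.frame (`protein_id`, `family`, `mechanism`, `ec`,
#'   `sources`) or NULL when no two sources agree.
#' @export
merge_calls <- function(hits, config = pipeline_config(), collapse = TRUE) {
  if (!nrow(hits)) return(NULL)
  if (length(unique(hits$protein_id)) != 1L)
    stop("merge_calls expects hits for a single protein")
  fam <- if (collapse) collapse_subfamily(hits$label) else hits$label
  # one candidate row per (source, family), best e-value
  key <- paste(hits$source, fam, sep = "\r")
  ord <- order(hits$evalue)
  keep <- ord[!duplicated(key[ord])]
  h <- hits[keep, , drop = FALSE]
  h$family <- fam[keep]
  support <- tapply(h$source, h$family, function(s) length(unique(s)))
  candidates <- names(support)[support >= 2L]
  if (!length(candidates)) return(NULL)
  cand <- h[h$family %in% candidates, , drop = FALSE]
  cand <- cand[order(SOURCE_PRIORITY[cand$source], cand$evalue), , drop = FALSE]
  family <- cand$family[1L]
  supporting <- sort(unique(h$source[h$family == family]))
  ec <- NA_character_
  ec_hits <- hits[!is.na(hits$ec) & fam == family, , drop = FALSE]
  if (nrow(ec_hits)) {
    ok <- accept_ec(ec_hits$coverage, ec_hits$identity, config)
    if (any(ok)) {
      ec_hits <- ec_hits[ok, , drop = FALSE]
      ec <- ec_hits$ec[which.min(ec_hits$evalue)]
    }
  }
  data.frame(protein_id = hits$protein_id[1L], family = family,
             mechanism = cazy_mechanism(family), ec = ec,
             sources = paste(supporting, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Consensus-annotate a full hit table
#'
#' Applies the load-time e-value cutoff, then merges evidence per protein
#' with [merge_calls()].
#'
#' @param hits Annotation hits for any number of proteins.
#' @param config A [pipeline_config()].
#' @param gene_map Optional gene table used to attach `mag_id` to each call
#'   (proteins and genes share identifiers).
#' @return A data.frame of consensus calls (possibly 0 rows), one per
#'   protein with an accepted call.
#' @export
consensus_annotate <- function(hits, config = pipeline_config(),
                               gene_map = NULL) {
  hits <- hits[hits$evalue <= config$evalue_cutoff, , drop = FALSE]
  empty <- data.frame(protein_id = character(), family = character(),
                      mechanism = character(), ec = character(),
                      sources = character(), stringsAsFactors = FALSE)
  calls <- if (nrow(hits)) {
    parts <- split(hits, hits$protein_id)
    res <- lapply(parts, merge_calls, config = config)
    res <- res[!vapply(res, is.null, logical(1))]
    if (length(res)) do.call(rbind, res) else empty
  } else empty
  rownames(calls) <- NULL
  if (!is.null(gene_map)) {
    calls$mag_id <- gene_map$mag_id[match(calls$protein_id, gene_map$gene_id)]
    if (anyNA(calls$mag_id))
      stop("consensus call for protein absent from the gene table: ",
           calls$protein_id[which(is.na(calls$mag_id))[1]])
  }
  calls
}

#' EC-number acceptance filter
#'
#' An EC annotation is accepted iff database target coverage >= 0.40 and
#' identity >= 0.30 (both inclusive, thresholds from the configuration).
#'
#' @param coverage,identity Fractions in \[0, 1\] (vectorized).
#' @param config A [pipeline_config()].
#' @return Logical vector.
#' @export
accept_ec <- function(coverage, identity, config = pipeline_config()) {
  coverage >= config$ec_min_coverage & identity >= config$ec_min_identity
}

#' Sulfatase acceptance filter
#'
#' A sulfatase hit (SulfAtlas S1 subfamily label) is accepted iff target
#' coverage >= 0.50, identity >= 0.30, and the protein carries the
#' formylglycine-dependent sulfatase domain PF00884. When several hits for
#' one protein pass, the best e-value is kept.
#'
#' @param hits Sulfatase hit table (see [read_annotation_hits()]); labels
#'   are S1 subfamilies.
#' @param config A [pipeline_config()].
#' @param domain_hits Optional data.frame (`protein_id`, `domain`) from an
#'   independent protein-domain search; domains listed in the hits table's
#'   own `domains` column are also honoured.
#' @param gene_map Optional gene table used to attach `mag_id`.
#' @return A data.frame of accepted calls: `protein_id`, `s1_family`,
#'   `coverage`, `identity` (0 rows when none pass).
#' @export
accept_sulfatase <- function(hits, config = pipeline_config(),
                             domain_hits = NULL, gene_map = NULL) {
  hits <- hits[hits$evalue <= config$evalue_cutoff, , drop = FALSE]
  has_domain <- vapply(seq_len(nrow(hits)), function(i) {
    doms <- parse_domains(hits$domains[i])
    if (!is.null(domain_hits))
      doms <- c(doms,
                domain_hits$domain[domain_hits$protein_id == hits$protein_id[i]])
    config$required_sulf_domain %in% doms
  }, logical(1))
  ok <- hits$coverage >= config$sulf_min_coverage &
    hits$identity >= config$sulf_min_identity & has_domain
  acc <- hits[ok, , drop = FALSE]
  acc <- acc[order(acc$protein_id, acc$evalue), , drop = FALSE]
  acc <- acc[!duplicated(acc$protein_id), , drop = FALSE]
  out <- data.frame(protein_id = acc$protein_id, s1_family = acc$label,
                    coverage = acc$coverage, identity = acc$identity,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(gene_map) && nrow(out))
    out$mag_id <- gene_map$mag_id[match(out$protein_id, gene_map$gene_id)]
  else out$mag_id <- character(nrow(out))
  out
}

#' Filter MAGs on assembly quality
#'
#' Retains MAGs meeting completeness >= `min_completeness` (inclusive) and
#' contamination < `max_contamination` (strict, following the MIMAG
#' "less than" phrasing). Defaults are the MIMAG medium-quality bounds.
#'
#' @param mag_meta MAG metadata (see [read_mag_metadata()]).
#' @param min_completeness Percent, default 50.
#' @param max_contamination Percent, default 10.
#' @return The retained rows of `mag_meta`.
#' @export
filter_mags <- function(mag_meta, min_completeness = 50,
                        max_contamination = 10) {
  keep <- mag_meta$completeness >= min_completeness &
    mag_meta$contamination < max_contamination
  out <- mag_meta[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
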