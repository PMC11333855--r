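# Substrate catalog: curated mapping from CAZy families, EC numbers,
# sulfatase S1 subfamilies, and mannitol-pathway gene symbols to dietary
# substrates and molecular-weight classes. The mapping is data, not code:
# it ships as a versioned TSV under inst/extdata and can be edited and
# diffed independently of the package logic.

#' Load the substrate catalog
#'
#' @param path Path to a catalog TSV; defaults to the catalog shipped with
#'   the package. Columns: `key`, `key_type` (family/ec/s1/gene),
#'   `substrates` (comma-separated), `weight_class` (HMW/LMW/NA),
#'   `dedicated`, `enzyme_label`.
#' @return A data.frame of class `substrate_catalog` with a `substrates`
#'   list-column.
#' @export
load_substrate_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "substrate_catalog.tsv",
                        package = "cazyprofiler")
  if (!file.exists(path)) stop("substrate catalog not found: ", path)
  cat_df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                              stringsAsFactors = FALSE)
  cat_df$key <- as.character(cat_df$key)
  cat_df$substrates <- as.character(cat_df$substrates)
  cat_df$substrates[is.na(cat_df$substrates)] <- ""
  need <- c("key", "key_type", "substrates", "weight_class", "dedicated",
            "enzyme_label")
  miss <- setdiff(need, names(cat_df))
  if (length(miss))
    stop("substrate catalog missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cat_df$key)) stop("duplicated catalog key")
  if (!all(cat_df$key_type %in% c("family", "ec", "s1", "gene")))
    stop("catalog key_type must be one of family/ec/s1/gene")
  cat_df$weight_class <- as.character(cat_df$weight_class)
  cat_df$weight_class[is.na(cat_df$weight_class)] <- "NA"
  if (!all(cat_df$weight_class %in% c("HMW", "LMW", "NA")))
    stop("catalog weight_class must be HMW, LMW or NA")
  cat_df$dedicated <- as.logical(cat_df$dedicated)
  subs <- strsplit(cat_df$substrates, ",", fixed = TRUE)
  subs <- lapply(subs, function(s) s[nzchar(s)])
  known <- c(setdiff(SUBSTRATE_PANELS, c("sulfatase", "mannitol")),
             "sulfate_removal", "mannitol")
  bad <- setdiff(unique(unlist(subs)), known)
  if (length(bad))
    stop("unknown substrate(s) in catalog: ", paste(bad, collapse = ", "))
  # dedicated => exactly one substrate
  n_sub <- lengths(subs)
  if (any(cat_df$dedicated & n_sub != 1L))
    stop("catalog invariant violated: dedicated entries must map to exactly",
         " one substrate")
  cat_df$substrates <- subs
  class(cat_df) <- c("substrate_catalog", "data.frame")
  cat_df
}

catalog_lookup <- function(key, catalog) {
  match(key, catalog$key)
}

#' Classify a CAZy family or EC number
#'
#' Deterministic lookup of a key in the substrate catalog. Keys absent from
#' the catalog yield an explicit unmapped result rather than an error.
#'
#' @param key A CAZy family (e.g., "PL6"), EC number, S1 subfamily or gene
#'   symbol. Vectorized.
#' @param catalog A loaded [load_substrate_catalog()] table.
#' @return A data.frame with one row per key: `key`, `mapped`, `substrates`
#'   (list-column), `weight_class`, `dedicated`, `enzyme_label`.
#' @export
classify_family <- function(key, catalog) {
  idx <- catalog_lookup(key, catalog)
  subs <- vector("list", length(key))
  subs[is.na(idx)] <- list(character())
  subs[!is.na(idx)] <- catalog$substrates[idx[!is.na(idx)]]
  data.frame(
    key = key,
    mapped = !is.na(idx),
    substrates = I(subs),
    weight_class = ifelse(is.na(idx), "NA", catalog$weight_class[idx]),
    dedicated = ifelse(is.na(idx), FALSE, catalog$dedicated[idx]),
    enzyme_label = ifelse(is.na(idx), NA_character_,
                          catalog$enzyme_label[idx]),
    stringsAsFactors = FALSE
  )
}

#' Classify a sulfatase S1 subfamily
#'
#' Maps an S1 subfamily to the sulfated polysaccharide it desulfates.
#' S1_15/S1_16/S1_25 are fucoidan (FCSP) sulfatases, S1_7/S1_19/S1_8
#' carrageenan sulfatases, and S1_17 acts on both FCSP and iota-carrageenan.
#' All entries carry the `sulfate_removal` tag and no weight class.
#'
#' @param s1_family S1 subfamily string(s), e.g. "S1_19".
#' @param catalog A loaded substrate catalog.
#' @return As [classify_family()]; unknown subfamilies are unmapped.
#' @export
classify_sulfatase <- function(s1_family, catalog) {
  res <- classify_family(s1_family, catalog)
  idx <- catalog_lookup(s1_family, catalog)
  wrong <- !is.na(idx) & catalog$key_type[idx] != "s1"
  if (any(wrong))
    stop("not an S1 sulfatase subfamily: ",
         paste(s1_family[wrong], collapse = ", "))
  res
}

#' Call mannitol-utilization routes for a MAG
#'
#' Two routes convert D-mannitol to D-fructose-6-phosphate: oxidation by
#' mannitol 2-dehydrogenase (M2DH) followed by fructokinase, or uptake via a
#' mannitol phosphotransferase system (PTS) followed by mannitol-1-phosphate
#' 5-dehydrogenase (M1PDH). A route is called only when both of its
#' components are present; a MAG may carry both routes.
#'
#' @param has_m2dh,has_fructokinase,has_pts_component,has_m1pdh Logical
#'   presence flags (vectorized over MAGs).
#' @param mag_id Optional MAG identifiers.
#' @return A data.frame with the flags, `m2dh_route`, `pts_m1pdh_route` and
#'   a semicolon-joined `routes` column.
#' @export
call_mannitol_routes <- function(has_m2dh, has_fructokinase,
                                 has_pts_component, has_m1pdh,
                                 mag_id = NULL) {
  n <- length(has_m2dh)
  stopifnot(length(has_fructokinase) == n, length(has_pts_component) == n,
            length(has_m1pdh) == n)
  m2dh_route <- has_m2dh & has_fructokinase
  pts_route <- has_pts_component & has_m1pdh
  routes <- character(n)
  routes[m2dh_route & !pts_route] <- "M2DH_route"
  routes[!m2dh_route & pts_route] <- "PTS_M1PDH_route"
  routes[m2dh_route & pts_route] <- "M2DH_route;PTS_M1PDH_route"
  data.frame(
    mag_id = if (is.null(mag_id)) rep(NA_character_, n) else mag_id,
    has_m2dh = has_m2dh, has_fructokinase = has_fructokinase,
    has_pts_component = has_pts_component, has_m1pdh = has_m1pdh,
    m2dh_route = m2dh_route, pts_m1pdh_route = pts_route,
    routes = routes, stringsAsFactors = FALSE
  )
}

#' Derive mannitol genotypes from a gene table
#'
#' Mannitol-pathway genes arrive as curated gene symbols in the gene table's
#' product labels (`m2dh`, `fructokinase`, `pts_mtl`, `m1pdh`).
#'
#' @param genes Gene table (see [read_gene_table()]).
#' @param mag_ids MAGs to report (default: all in `genes`).
#' @return A [call_mannitol_routes()] data.frame, one row per MAG.
#' @export
mannitol_genotypes <- function(genes, mag_ids = NULL) {
  if (is.null(mag_ids)) mag_ids <- sort(unique(genes$mag_id))
  lab <- ifelse(is.na(genes$product_label), "", genes$product_label)
  flag <- function(sym)
    vapply(mag_ids, function(m) any(genes$mag_id == m & lab == sym),
           logical(1))
  call_mannitol_routes(flag("m2dh"), flag("fructokinase"),
                       flag("pts_mtl"), flag("m1pdh"), mag_id = mag_ids)
}

#' Build the per-MAG substrate capability matrix
#'
#' One row per retained MAG, one column per substrate/enzyme panel:
#' seven polysaccharide panels (alginate, laminarin, FCSP, carrageenan,
#' agarose, galactan, starch) driven by consensus CAZyme calls, a sulfatase
#' panel driven by accepted sulfatase calls, and a mannitol panel driven by
#' complete utilization routes. A polysaccharide cell is TRUE iff at least
#' one call maps (possibly ambiguously) to that substrate; a MAG row is the
#' union of its calls' substrate sets.
#'
#' @param calls Consensus CAZyme calls with `mag_id` and `family` columns.
#' @param sulf_calls Accepted sulfatase calls with `mag_id` (may be empty).
#' @param mannitol Mannitol genotypes ([call_mannitol_routes()] output).
#' @param mag_meta MAG metadata of the retained MAGs.
#' @param catalog Substrate catalog.
#' @return An object of class `capability_matrix`: a logical matrix
#'   (MAGs x 9 panels) with an `evidence` attribute, a long data.frame of
#'   per-cell supporting enzyme labels.
#' @export
build_capability_matrix <- function(calls, sulf_calls, mannitol, mag_meta,
                                    catalog) {
  mags <- mag_meta$mag_id
  bad <- setdiff(unique(c(calls$mag_id, sulf_calls$mag_id)), mags)
  if (length(bad))
    stop("call references unknown MAG: ", paste(bad, collapse = ", "))
  mat <- matrix(FALSE, nrow = length(mags), ncol = length(SUBSTRATE_PANELS),
                dimnames = list(mags, SUBSTRATE_PANELS))
  ev <- list()
  poly <- setdiff(SUBSTRATE_PANELS, c("sulfatase", "mannitol"))
  if (nrow(calls)) {
    cls <- classify_family(calls$family, catalog)
    for (i in seq_len(nrow(calls))) {
      subs <- intersect(cls$substrates[[i]], poly)
      if (!length(subs)) next
      mat[calls$mag_id[i], subs] <- TRUE
      ev[[length(ev) + 1L]] <- data.frame(
        mag_id = calls$mag_id[i], panel = subs,
        key = calls$family[i],
        enzyme_label = cls$enzyme_label[i], stringsAsFactors = FALSE)
    }
  }
  if (nrow(sulf_calls)) {
    scls <- classify_sulfatase(sulf_calls$s1_family, catalog)
    mat[unique(sulf_calls$mag_id), "sulfatase"] <- TRUE
    ev[[length(ev) + 1L]] <- data.frame(
      mag_id = sulf_calls$mag_id, panel = "sulfatase",
      key = sulf_calls$s1_family,
      enzyme_label = scls$enzyme_label, stringsAsFactors = FALSE)
  }
  if (nrow(mannitol)) {
    man <- mannitol[mannitol$routes != "" & mannitol$mag_id %in% mags, ,
                    drop = FALSE]
    if (nrow(man)) {
      mat[man$mag_id, "mannitol"] <- TRUE
      ev[[length(ev) + 1L]] <- data.frame(
        mag_id = man$mag_id, panel = "mannitol", key = man$routes,
        enzyme_label = "mannitol utilization route",
        stringsAsFactors = FALSE)
    }
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else
    data.frame(mag_id = character(), panel = character(), key = character(),
               enzyme_label = character(), stringsAsFactors = FALSE)
  evidence <- evidence[order(evidence$mag_id, evidence$panel, evidence$key), ,
                       drop = FALSE]
  rownames(evidence) <- NULL
  structure(mat, evidence = evidence, class = c("capability_matrix", "matrix"))
}

#' Count genes and MAGs per molecular-weight class
#'
#' Gene count = number of accepted degradative CAZyme calls (GH/PL/CE) whose
#' weight class is HMW or LMW; MAG count = number of MAGs with at least one
#' such call. The weight class of a call is taken from its accepted EC number
#' when available (EC-based endo/exo assignment), falling back to the family
#' rule.
#'
#' @param calls Consensus calls with `mag_id`, `family`, `mechanism`, `ec`.
#' @param catalog Substrate catalog.
#' @return A data.frame with rows HMW and LMW and columns `n_genes`,
#'   `n_mags`.
#' @export
count_weight_classes <- function(calls, catalog) {
  res <- data.frame(weight_class = c("HMW", "LMW"), n_genes = 0L,
                    n_mags = 0L, stringsAsFactors = FALSE)
  if (!nrow(calls)) return(res)
  deg <- calls[calls$mechanism %in% DEGRADATIVE_MECHANISMS, , drop = FALSE]
  if (!nrow(deg)) return(res)
  wc <- call_weight_class(deg, catalog)
  for (k in c("HMW", "LMW")) {
    sel <- !is.na(wc) & wc == k
    res$n_genes[res$weight_class == k] <- sum(sel)
    res$n_mags[res$weight_class == k] <- length(unique(deg$mag_id[sel]))
  }
  res
}

# EC-first, family-fallback weight class per call; NA when neither maps
call_weight_class <- function(calls, catalog) {
  fam <- classify_family(calls$family, catalog)
  wc <- fam$weight_class
  has_ec <- !is.na(calls$ec)
  if (any(has_ec)) {
    ec <- classify_family(calls$ec[has_ec], catalog)
    use <- ec$mapped & ec$weight_class != "NA"
    wc[has_ec][use] <- ec$weight_class[use]
  }
  wc[wc == "NA"] <- NA_character_
  wc
}
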