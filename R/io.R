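# On-disk contract shared by all pipeline stages. All coordinates are 1-based
# inclusive (GFF3 convention); TSVs are written with a fixed format so that
# re-running the pipeline on identical inputs is byte-identical.

ANNOTATION_SOURCES <- c("HMMER", "eCAMI", "DIAMOND")
GUT_SECTIONS <- c("III", "IV", "V")
SUBSTRATE_PANELS <- c("alginate", "laminarin", "FCSP", "carrageenan",
                      "agarose", "galactan", "starch", "sulfatase", "mannitol")
CAZY_MECHANISMS <- c("GH", "PL", "CE", "CBM", "GT", "AA")
DEGRADATIVE_MECHANISMS <- c("GH", "PL", "CE")
TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

write_tsv_exact <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}

read_tsv_exact <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Read a gene table (GFF3 subset)
#'
#' Parses a GFF3 file carrying predicted genes. Only a subset of GFF3 is
#' used: seqid (contig), start, end, strand, and the attributes `ID`
#' (gene id), `mag` (MAG id) and `product` (optional free-text label).
#' Coordinates are 1-based inclusive.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `mag_id`, `contig_id`,
#'   `start`, `end`, `strand`, `product_label`, sorted by
#'   (mag_id, contig_id, start).
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_data <- !grepl("^\\s*(#|$)", lines)
  if (!any(is_data)) {
    return(data.frame(gene_id = character(), mag_id = character(),
                      contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      product_label = character(),
                      stringsAsFactors = FALSE))
  }
  for (i in which(is_data)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9L)
      stop(sprintf("gene table parse error at line %d: expected 9 columns", i))
    if (!grepl("^[0-9]+$", fields[4]) || !grepl("^[0-9]+$", fields[5]))
      stop(sprintf("gene table parse error at line %d: malformed coordinate", i))
  }
  gff <- rtracklayer::readGFF(path)
  gff <- as.data.frame(gff, stringsAsFactors = FALSE)
  need_attr <- c("ID", "mag")
  missing_attr <- setdiff(need_attr, names(gff))
  if (length(missing_attr))
    stop("gene table missing required attributes: ",
         paste(missing_attr, collapse = ", "))
  genes <- data.frame(
    gene_id = as.character(gff$ID),
    mag_id = as.character(gff$mag),
    contig_id = as.character(gff$seqid),
    start = as.integer(gff$start),
    end = as.integer(gff$end),
    strand = as.character(gff$strand),
    product_label = if ("product" %in% names(gff))
      as.character(gff$product) else NA_character_,
    stringsAsFactors = FALSE
  )
  validate_gene_table(genes)
  genes <- genes[order(genes$mag_id, genes$contig_id, genes$start), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  genes
}

validate_gene_table <- function(genes) {
  if (any(genes$start < 1L))
    stop("gene table validation error: start must be >= 1")
  bad <- genes$end < genes$start
  if (any(bad))
    stop("gene table validation error: end < start for gene ",
         genes$gene_id[which(bad)[1]])
  dup <- duplicated(genes$gene_id)
  if (any(dup))
    stop("gene table validation error: duplicated gene_id ",
         genes$gene_id[which(dup)[1]])
  key <- paste(genes$mag_id, genes$contig_id, genes$start, genes$end)
  if (anyDuplicated(key))
    stop("gene table validation error: duplicated (contig, start, end) within a MAG")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene table validation error: strand must be '+' or '-'")
  invisible(genes)
}

#' Write a gene table as GFF3
#'
#' Inverse of [read_gene_table()]; a write followed by a read reproduces the
#' records exactly.
#'
#' @param genes Gene table data.frame (see [read_gene_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  validate_gene_table(genes)
  genes <- genes[order(genes$mag_id, genes$contig_id, genes$start), ,
                 drop = FALSE]
  prod <- ifelse(is.na(genes$product_label), "",
                 paste0(";product=", genes$product_label))
  lines <- c("##gff-version 3",
             sprintf("%s\tcazyprofiler\tgene\t%d\t%d\t.\t%s\t.\tID=%s;mag=%s%s",
                     genes$contig_id, genes$start, genes$end, genes$strand,
                     genes$gene_id, genes$mag_id, prod))
  writeLines(lines, path)
  invisible(path)
}

#' Read an annotation-evidence table
#'
#' Reads tabular annotation evidence as produced by profile-HMM, k-mer and
#' similarity-search annotators. One row is one evidence record for one
#' protein. Coverage and identity are fractions of the database target.
#'
#' @param path Path to a TSV with columns `protein_id`, `source`, `label`,
#'   `coverage`, `identity`, `evalue`, `ec`, `domains` (the last two may be
#'   empty / "-").
#' @return A data.frame of hits; `ec` is NA when absent, `domains` is a
#'   comma-separated string (possibly empty).
#' @export
read_annotation_hits <- function(path) {
  if (!file.exists(path)) stop("annotation hits file not found: ", path)
  hits <- read_tsv_exact(path)
  need <- c("protein_id", "source", "label", "coverage", "identity",
            "evalue", "ec", "domains")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("annotation hits missing columns: ", paste(miss, collapse = ", "))
  hits$protein_id <- as.character(hits$protein_id)
  hits$source <- as.character(hits$source)
  hits$label <- as.character(hits$label)
  for (f in c("coverage", "identity", "evalue"))
    hits[[f]] <- as.numeric(hits[[f]])
  hits$ec <- as.character(hits$ec)
  hits$ec[hits$ec %in% c("", "-")] <- NA_character_
  hits$domains <- as.character(hits$domains)
  hits$domains[is.na(hits$domains) | hits$domains == "-"] <- ""
  validate_annotation_hits(hits)
  hits
}

validate_annotation_hits <- function(hits) {
  bad_src <- setdiff(unique(hits$source), ANNOTATION_SOURCES)
  if (length(bad_src))
    stop("unknown annotation source(s): ", paste(bad_src, collapse = ", "),
         " (allowed: ", paste(ANNOTATION_SOURCES, collapse = ", "), ")")
  for (f in c("coverage", "identity")) {
    v <- hits[[f]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v > 1))
      stop("annotation hits validation error: ", f,
           " must be a fraction in [0, 1]")
  }
  if (any(is.na(hits$label) | hits$label == ""))
    stop("annotation hits validation error: empty label")
  invisible(hits)
}

#' Write an annotation-evidence table
#' @param hits Hits data.frame (see [read_annotation_hits()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_hits <- function(hits, path) {
  validate_annotation_hits(hits)
  out <- hits
  out$ec[is.na(out$ec)] <- "-"
  out$domains[out$domains == ""] <- "-"
  write_tsv_exact(out, path)
  invisible(path)
}

#' Read MAG metadata
#'
#' @param path TSV with columns `mag_id`, the seven taxonomy ranks
#'   (`domain` ... `species`; empty below the classified rank),
#'   `completeness`, `contamination`, `n_genes`, `genome_size`.
#' @return Validated data.frame.
#' @export
read_mag_metadata <- function(path) {
  if (!file.exists(path)) stop("MAG metadata file not found: ", path)
  meta <- read_tsv_exact(path)
  need <- c("mag_id", TAXONOMY_RANKS, "completeness", "contamination",
            "n_genes", "genome_size")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("MAG metadata missing columns: ", paste(miss, collapse = ", "))
  for (r in TAXONOMY_RANKS) {
    meta[[r]] <- as.character(meta[[r]])
    meta[[r]][is.na(meta[[r]])] <- ""
  }
  if (anyDuplicated(meta$mag_id)) stop("duplicated mag_id in MAG metadata")
  if (any(meta$completeness < 0 | meta$completeness > 100))
    stop("completeness must be in [0, 100]")
  if (any(meta$contamination < 0)) stop("contamination must be >= 0")
  meta
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `fish_id`, `section`
#'   (III/IV/V), `year`, `assay` (metagenome/metatranscriptome).
#' @return Validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("sample metadata file not found: ", path)
  meta <- read_tsv_exact(path)
  need <- c("sample_id", "fish_id", "section", "year", "assay")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("sample metadata missing columns: ", paste(miss, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$section <- as.character(meta$section)
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id")
  bad <- setdiff(unique(meta$section), GUT_SECTIONS)
  if (length(bad))
    stop("unknown gut section(s): ", paste(bad, collapse = ", "))
  if (!all(meta$assay %in% c("metagenome", "metatranscriptome")))
    stop("assay must be 'metagenome' or 'metatranscriptome'")
  meta
}

#' Read a relative-abundance table
#'
#' @param path TSV with a `sample_id` column and one column per MAG; rows are
#'   per-sample relative abundances in percent (each row sums to 100).
#' @return A data.frame (samples x MAGs).
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("abundance table not found: ", path)
  ab <- read_tsv_exact(path)
  if (!"sample_id" %in% names(ab))
    stop("abundance table must have a sample_id column")
  ab$sample_id <- as.character(ab$sample_id)
  mags <- setdiff(names(ab), "sample_id")
  vals <- as.matrix(ab[, mags, drop = FALSE])
  if (any(vals < 0)) stop("abundances must be >= 0")
  sums <- rowSums(vals)
  if (any(abs(sums - 100) > 1e-6))
    stop("abundance rows must sum to 100%")
  ab
}

#' Read a transcript-count table
#'
#' @param path TSV with a `gene_id` column and one column per
#'   metatranscriptome sample; entries are non-negative counts.
#' @return A data.frame (genes x samples).
#' @export
read_transcript_counts <- function(path) {
  if (!file.exists(path)) stop("transcript count table not found: ", path)
  tc <- read_tsv_exact(path)
  if (!"gene_id" %in% names(tc))
    stop("transcript counts must have a gene_id column")
  tc$gene_id <- as.character(tc$gene_id)
  vals <- as.matrix(tc[, setdiff(names(tc), "gene_id"), drop = FALSE])
  if (any(vals < 0)) stop("transcript counts must be >= 0")
  tc
}

# split a comma-separated domains string into a character vector
parse_domains <- function(domains) {
  if (is.na(domains) || domains == "") return(character())
  strsplit(domains, ",", fixed = TRUE)[[1]]
}
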