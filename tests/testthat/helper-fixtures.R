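# Small programmatic fixtures shared across test files.

make_hit <- function(protein_id, source, label, coverage = 0.8,
                     identity = 0.5, evalue = 1e-20, ec = NA_character_,
                     domains = "") {
  data.frame(protein_id = protein_id, source = source, label = label,
             coverage = coverage, identity = identity, evalue = evalue,
             ec = ec, domains = domains, stringsAsFactors = FALSE)
}

make_hits <- function(...) do.call(rbind, list(...))

# gene table from a role string on one contig; roles feed product labels so
# that assign_gene_roles() reproduces them (CAZyme roles come from calls)
genes_from_roles <- function(roles, mag = "MAGX", contig = "MAGX_c01",
                             families = NULL) {
  n <- length(roles)
  start <- (seq_len(n) - 1L) * 1000L + 1L
  genes <- data.frame(
    gene_id = sprintf("%s_g%03d", mag, seq_len(n)),
    mag_id = mag, contig_id = contig, start = start, end = start + 899L,
    strand = "+",
    product_label = ifelse(roles %in% c("TC", "TF", "STP"), roles,
                           "hypothetical protein"),
    stringsAsFactors = FALSE)
  caz <- which(roles == "CAZyme")
  fam <- if (is.null(families)) rep("GH16", length(caz)) else families
  calls <- data.frame(protein_id = genes$gene_id[caz],
                      family = fam,
                      mechanism = substr(fam, 1, 2),
                      ec = rep(NA_character_, length(caz)),
                      sources = rep("HMMER;eCAMI", length(caz)),
                      stringsAsFactors = FALSE)
  list(genes = genes, calls = calls,
       roles = assign_gene_roles(genes, calls))
}

make_mag_meta <- function(mag_id, class = "Bacteroidia", genus = "Alistipes",
                          completeness = 90, contamination = 1,
                          n_genes = 2000L, genome_size = 2500000L) {
  k <- length(mag_id)
  data.frame(mag_id = mag_id, domain = "Bacteria", phylum = "Bacteroidota",
             class = rep_len(class, k), order = "", family = "",
             genus = rep_len(genus, k), species = "",
             completeness = rep_len(completeness, k),
             contamination = rep_len(contamination, k),
             n_genes = rep_len(n_genes, k),
             genome_size = rep_len(genome_size, k),
             stringsAsFactors = FALSE)
}

make_call <- function(protein_id, family, mag_id, ec = NA_character_) {
  data.frame(protein_id = protein_id, family = family,
             mechanism = sub("^((GH|PL|CE|CBM|GT|AA)).*", "\\1", family),
             ec = ec, sources = "HMMER;eCAMI", mag_id = mag_id,
             stringsAsFactors = FALSE)
}

empty_sulf_calls <- function() {
  data.frame(protein_id = character(), s1_family = character(),
             coverage = numeric(), identity = numeric(),
             mag_id = character(), stringsAsFactors = FALSE)
}

empty_mannitol <- function() {
  call_mannitol_routes(logical(), logical(), logical(), logical(),
                       mag_id = character())
}

# a small community plan that runs in well under a second
small_plan <- function(seed = 1L, ...) {
  community_plan(
    n_mags_per_class = c(Bacteroidia = 4L, Clostridia = 3L, Bacilli = 2L,
                         Desulfobacteria = 1L),
    genes_per_mag = 300L, contigs_per_mag = 2L,
    cgc_rate = 1, weak_cgc_rate = 1, singleton_scale = 0.3,
    coabund_blocks = FALSE,
    rng_seed = seed, ...)
}

test_catalog <- function() load_substrate_catalog()
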