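#' Pipeline configuration
#'
#' Collects every tunable threshold of the profiling pipeline in one object.
#' Coverage and identity thresholds are stored as fractions in \[0, 1\];
#' percentage inputs from configuration files are converted once at load time
#' and nowhere else.
#'
#' @param ec_min_coverage Minimum database target coverage for accepting an
#'   EC-number annotation (fraction, default 0.40).
#' @param ec_min_identity Minimum sequence identity for accepting an EC-number
#'   annotation (fraction, default 0.30).
#' @param sulf_min_coverage Minimum target coverage for accepting a sulfatase
#'   call (fraction, default 0.50).
#' @param sulf_min_identity Minimum identity for accepting a sulfatase call
#'   (fraction, default 0.30).
#' @param required_sulf_domain Protein domain accession that must be present
#'   for a sulfatase call (default "PF00884", the formylglycine-dependent
#'   sulfatase domain).
#' @param evalue_cutoff E-value cutoff applied to every annotation hit at load
#'   time (default 0.001).
#' @param cgc_max_gap Maximum number of non-signature genes allowed between
#'   consecutive signature genes within a CAZyme gene cluster (default 2).
#' @param cgc_min_degradative Minimum number of degradative CAZymes (GH/PL/CE)
#'   for a cluster to be flagged degradative (default 2).
#' @param min_completeness Minimum MAG completeness retained, in percent
#'   (default 50, the MIMAG medium-quality bound; inclusive).
#' @param max_contamination Maximum MAG contamination retained, in percent
#'   (default 10; strict "less than").
#' @param density_unit Either "per_1000_genes" (default) or "per_mbp" for
#'   CAZyme density.
#' @param corr_alpha Significance level for co-abundance edges (default 0.05).
#' @param corr_min_r Minimum Pearson r for a co-abundance edge (default 0.3).
#' @param group_cut_height Average-linkage cut height on 1 - r when
#'   delineating co-abundant groups (default 0.7).
#' @param group_min_size Minimum members per co-abundant group (default 2).
#' @param fc_pseudocount Pseudocount (percentage points) added to section mean
#'   abundances before log10 fold change (default 0.01).
#' @param rng_seed Seed forwarded to the synthetic generator; analysis stages
#'   are deterministic and never draw random numbers.
#' @return An object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config(cgc_max_gap = 1)
#' cfg$ec_min_coverage
#' @export
pipeline_config <- function(ec_min_coverage = 0.40,
                            ec_min_identity = 0.30,
                            sulf_min_coverage = 0.50,
                            sulf_min_identity = 0.30,
                            required_sulf_domain = "PF00884",
                            evalue_cutoff = 0.001,
                            cgc_max_gap = 2L,
                            cgc_min_degradative = 2L,
                            min_completeness = 50,
                            max_contamination = 10,
                            density_unit = c("per_1000_genes", "per_mbp"),
                            corr_alpha = 0.05,
                            corr_min_r = 0.3,
                            group_cut_height = 0.7,
                            group_min_size = 2L,
                            fc_pseudocount = 0.01,
                            rng_seed = 1L) {
  density_unit <- match.arg(density_unit)
  cfg <- list(
    ec_min_coverage = as.numeric(ec_min_coverage),
    ec_min_identity = as.numeric(ec_min_identity),
    sulf_min_coverage = as.numeric(sulf_min_coverage),
    sulf_min_identity = as.numeric(sulf_min_identity),
    required_sulf_domain = as.character(required_sulf_domain),
    evalue_cutoff = as.numeric(evalue_cutoff),
    cgc_max_gap = as.integer(cgc_max_gap),
    cgc_min_degradative = as.integer(cgc_min_degradative),
    min_completeness = as.numeric(min_completeness),
    max_contamination = as.numeric(max_contamination),
    density_unit = density_unit,
    corr_alpha = as.numeric(corr_alpha),
    corr_min_r = as.numeric(corr_min_r),
    group_cut_height = as.numeric(group_cut_height),
    group_min_size = as.integer(group_min_size),
    fc_pseudocount = as.numeric(fc_pseudocount),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  fracs <- c("ec_min_coverage", "ec_min_identity", "sulf_min_coverage",
             "sulf_min_identity", "corr_alpha")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("config field '%s' must be a fraction in [0, 1]", f))
  }
  if (cfg$cgc_min_degradative < 1L)
    stop("cgc_min_degradative must be >= 1")
  if (cfg$cgc_max_gap < 0L)
    stop("cgc_max_gap must be >= 0")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; keys ending in `_pct` are accepted as
#' percentages and converted to fractions here (the only place such a
#' conversion happens).
#'
#' @param path Path to a YAML file whose keys match [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  pct <- grepl("_pct$", names(raw))
  if (any(pct)) {
    conv <- lapply(raw[pct], function(v) v / 100)
    names(conv) <- sub("_pct$", "", names(raw)[pct])
    raw <- c(raw[!pct], conv)
  }
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
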