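# Synthetic multi-MAG communities with planted ground truth: taxon-class
# substrate guilds, CAZyme gene clusters with transporter/regulator
# co-members, three-stream annotator evidence with controllable
# disagreement noise, blocked co-abundance structure across two hindgut
# sections, and negative-binomial transcript counts. Every downstream stage
# of the pipeline can be validated against the emitted ground truth.
#
# All randomness in the package lives here; analysis stages are seed-free.

CLASS_PHYLUM <- c(
  Bacteroidia = "Bacteroidota", Clostridia = "Bacillota_A",
  Bacilli = "Bacillota", Gammaproteobacteria = "Pseudomonadota",
  Verrucomicrobiae = "Verrucomicrobiota", Cyanobacteriia = "Cyanobacteriota",
  Spirochaetia = "Spirochaetota", Desulfobacteria = "Desulfobacterota")

CGC_SUBSTRATES <- c("alginate", "laminarin", "FCSP", "carrageenan",
                    "agarose", "starch")

FAMILY_EC <- c(PL6 = "4.2.2.25", PL34 = "4.2.2.3", PL38 = "4.2.2.3",
               PL17 = "4.2.2.26", GH16 = "3.2.1.6", GH30 = "3.2.1.75",
               GH3 = "3.2.1.21", GH1 = "3.2.1.21", GH29 = "3.2.1.51",
               GH141 = "3.2.1.51", GH151 = "3.2.1.51", GH150 = "3.2.1.162",
               GH86 = "3.2.1.81", GH50 = "3.2.1.81", GH13 = "3.2.1.1",
               GH57 = "3.2.1.1", GH77 = "3.2.1.1", GH31 = "3.2.1.20",
               GH133 = "3.2.1.10", GH2 = "3.2.1.23", GH42 = "3.2.1.23",
               GH36 = "3.2.1.22", GH110 = "3.2.1.22")

default_class_guilds <- function() {
  list(
    Bacteroidia = c("alginate", "laminarin", "FCSP", "carrageenan",
                    "agarose", "galactan", "starch", "sulfate_removal",
                    "mannitol"),
    Clostridia = c("alginate", "laminarin", "FCSP", "galactan", "starch",
                   "sulfate_removal", "mannitol"),
    Bacilli = c("alginate", "starch", "mannitol"),
    Gammaproteobacteria = c("alginate", "laminarin", "galactan", "starch"),
    Verrucomicrobiae = c("FCSP", "sulfate_removal", "mannitol"),
    Cyanobacteriia = "starch",
    Spirochaetia = c("galactan", "starch"),
    Desulfobacteria = character()
  )
}

default_mag_split <- function() {
  c(Bacteroidia = 31L, Clostridia = 23L, Bacilli = 5L,
    Gammaproteobacteria = 4L, Verrucomicrobiae = 2L, Cyanobacteriia = 1L,
    Spirochaetia = 1L, Desulfobacteria = 1L)
}

# expected singleton CAZyme genes per guild substrate, by class
CLASS_SINGLETON_RATE <- c(
  Bacteroidia = 6, Clostridia = 3, Bacilli = 1, Gammaproteobacteria = 1.5,
  Verrucomicrobiae = 1, Cyanobacteriia = 0.5, Spirochaetia = 0.5,
  Desulfobacteria = 0)

default_expression_multipliers <- function() {
  list(
    III = c(Bacilli = 1.5, Clostridia = 1.0, Bacteroidia = 0.4),
    IV = c(Clostridia = 2.0, Bacteroidia = 1.0, Bacilli = 0.7),
    V = c(Bacteroidia = 3.0, Clostridia = 1.5)
  )
}

#' Define a synthetic community plan
#'
#' The plan fixes the study conditions the generator emulates: the class
#' split of the community, per-class substrate guilds, genome and sampling
#' scale, annotator noise, and the blocked co-abundance structure across
#' hindgut sections IV and V.
#'
#' @param n_mags_per_class Named integer vector of MAGs per taxon class.
#'   The default is the 31/23/5/9 split of a 68-MAG hindgut community.
#' @param class_guilds Named list mapping class to its substrate guild.
#' @param genes_per_mag Genes per MAG (default 2000).
#' @param contigs_per_mag Contigs per MAG (default 5).
#' @param n_fish Fish with metagenome samples (default 4).
#' @param sections Gut sections sampled for metagenomes (default IV, V).
#' @param n_fish_rna Fish with metatranscriptome samples (default 6).
#' @param rna_sections Sections sampled for metatranscriptomes.
#' @param cgc_rate Expected planted degradative CGCs per guild MAG (Poisson
#'   mean, default 2).
#' @param weak_cgc_rate Expected planted non-degradative clusters (one
#'   CAZyme plus a transporter) per guild MAG (default 2); these mimic the
#'   large background of clusters that never meet the two-degradative-CAZyme
#'   bar.
#' @param annotator_agreement Probability that each evidence stream emits a
#'   hit for an annotated protein (default 1).
#' @param label_noise Probability that an emitted stream reports a uniformly
#'   random other family instead of the truth (default 0).
#' @param coabund_blocks List of blocks, each
#'   `list(members = <mag ids>, sd = <latent factor sd>, trend = "IV"/"V"/"none")`;
#'   NULL selects a default six-block structure (two IV-enriched A-style
#'   blocks, four B-style blocks). `FALSE` disables blocks.
#' @param block_factor_sd Default latent-factor sd for blocks that omit one
#'   (default 0.8).
#' @param abund_noise_sd Residual lognormal noise sd on abundances
#'   (default 0.3).
#' @param section_effect Natural-log abundance shift applied to a block's
#'   enriched section (default 0.8).
#' @param completeness_range,contamination_range Uniform draw ranges (in
#'   percent) for MAG quality; defaults 75-99.5 and 0-6.4, the retained
#'   quality window emulated by the generator.
#' @param ec_fail_rate Probability that an EC-carrying similarity hit is
#'   drawn below the EC acceptance thresholds (default 0.2).
#' @param singleton_scale Global multiplier on the per-class singleton
#'   CAZyme rates (default 1); small test fixtures scale this down to fit
#'   short genomes.
#' @param expression_multipliers Named list (section -> named class
#'   multipliers) shaping transcript output; missing classes default to 0.2.
#' @param nb_size Negative-binomial dispersion for transcript counts.
#' @param rng_seed Integer seed; everything the generator emits is a
#'   deterministic function of the plan.
#' @return A validated object of class `community_plan`.
#' @export
community_plan <- function(n_mags_per_class = default_mag_split(),
                           class_guilds = default_class_guilds(),
                           genes_per_mag = 2000L,
                           contigs_per_mag = 5L,
                           n_fish = 4L,
                           sections = c("IV", "V"),
                           n_fish_rna = 6L,
                           rna_sections = c("III", "IV", "V"),
                           cgc_rate = 2,
                           weak_cgc_rate = 2,
                           annotator_agreement = 1,
                           label_noise = 0,
                           coabund_blocks = NULL,
                           block_factor_sd = 0.8,
                           abund_noise_sd = 0.3,
                           section_effect = 0.8,
                           completeness_range = c(75, 99.5),
                           contamination_range = c(0, 6.4),
                           ec_fail_rate = 0.2,
                           singleton_scale = 1,
                           expression_multipliers =
                             default_expression_multipliers(),
                           nb_size = 5,
                           rng_seed = 1L) {
  plan <- list(n_mags_per_class = n_mags_per_class,
               class_guilds = class_guilds,
               genes_per_mag = as.integer(genes_per_mag),
               contigs_per_mag = as.integer(contigs_per_mag),
               n_fish = as.integer(n_fish), sections = sections,
               n_fish_rna = as.integer(n_fish_rna),
               rna_sections = rna_sections,
               cgc_rate = cgc_rate,
               weak_cgc_rate = weak_cgc_rate,
               annotator_agreement = annotator_agreement,
               label_noise = label_noise,
               coabund_blocks = coabund_blocks,
               block_factor_sd = block_factor_sd,
               abund_noise_sd = abund_noise_sd,
               section_effect = section_effect,
               completeness_range = completeness_range,
               contamination_range = contamination_range,
               ec_fail_rate = ec_fail_rate,
               singleton_scale = singleton_scale,
               expression_multipliers = expression_multipliers,
               nb_size = nb_size,
               rng_seed = as.integer(rng_seed))
  class(plan) <- "community_plan"
  plan$mag_table <- plan_mag_table(plan)
  if (is.null(plan$coabund_blocks))
    plan$coabund_blocks <- default_blocks(plan)
  if (identical(plan$coabund_blocks, FALSE)) plan$coabund_blocks <- list()
  validate_plan(plan)
  plan
}

validate_plan <- function(plan) {
  for (f in c("annotator_agreement", "label_noise", "ec_fail_rate")) {
    v <- plan[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("plan field '", f, "' must be a probability in [0, 1]")
  }
  bad <- setdiff(names(plan$class_guilds), names(CLASS_PHYLUM))
  if (length(bad)) stop("unknown class in guilds: ", paste(bad, collapse = ", "))
  if (is.null(names(plan$n_mags_per_class)) ||
      !all(names(plan$n_mags_per_class) %in% names(CLASS_PHYLUM)))
    stop("n_mags_per_class must be named by taxon class")
  if (plan$cgc_rate * 12 + 20 > plan$genes_per_mag)
    stop("infeasible plan: cgc_rate too high for genes_per_mag")
  members <- unlist(lapply(plan$coabund_blocks, `[[`, "members"))
  if (anyDuplicated(members))
    stop("coabundance block memberships must be disjoint")
  if (length(members) && !all(members %in% plan$mag_table$mag_id))
    stop("coabundance block references unknown MAG")
  if (!all(plan$sections %in% GUT_SECTIONS) ||
      !all(plan$rna_sections %in% GUT_SECTIONS))
    stop("sections must be in ", paste(GUT_SECTIONS, collapse = "/"))
  invisible(plan)
}

plan_mag_table <- function(plan) {
  cls <- rep(names(plan$n_mags_per_class), plan$n_mags_per_class)
  n <- length(cls)
  genus_pool <- list(
    Bacteroidia = c(rep("Alistipes", 20), "Mucinivorans", "Mucinivorans",
                    rep("", 6), rep("Rikenella", 3)),
    Clostridia = c("Anaerotignum", "Faecalibacterium", "Lawsonibacter",
                   "UBA6857", "SIG603", rep("", 18)),
    Bacilli = c("Tannockella", rep("", 4)),
    Gammaproteobacteria = c("Vibrio", "Ferrimonas", "", ""),
    Verrucomicrobiae = c("Akkermansia", "CAKUIA01"))
  family_pool <- list(Bacteroidia = "Rikenellaceae",
                      Clostridia = "Lachnospiraceae",
                      Bacilli = "Erysipelotrichaceae")
  genus <- character(n)
  for (k in unique(cls)) {
    idx <- which(cls == k)
    pool <- genus_pool[[k]]
    if (is.null(pool)) pool <- ""
    genus[idx] <- rep_len(pool, length(idx))
  }
  data.frame(
    mag_id = sprintf("MAG_%03d", seq_len(n)),
    domain = "Bacteria",
    phylum = unname(CLASS_PHYLUM[cls]),
    class = cls,
    order = "",
    family = unname(vapply(cls, function(k)
      if (!is.null(family_pool[[k]])) family_pool[[k]] else "",
      character(1))),
    genus = genus,
    species = "",
    stringsAsFactors = FALSE)
}

default_blocks <- function(plan) {
  mt <- plan$mag_table
  pick <- function(class, k, skip = 0L) {
    ids <- mt$mag_id[mt$class == class]
    ids[seq_len(min(k, max(0L, length(ids) - skip))) + skip]
  }
  blocks <- list(
    list(members = c(pick("Bacilli", 2), pick("Clostridia", 2)),
         trend = "IV"),
    list(members = pick("Clostridia", 5, skip = 2L), trend = "IV"),
    list(members = c(pick("Clostridia", 3, skip = 7L),
                     pick("Bacteroidia", 3, skip = 20L)), trend = "none"),
    list(members = pick("Bacteroidia", 8), trend = "V"),
    list(members = c(pick("Bacteroidia", 3, skip = 8L),
                     pick("Clostridia", 1, skip = 10L)), trend = "V"),
    list(members = c(pick("Bacteroidia", 3, skip = 11L),
                     pick("Clostridia", 2, skip = 11L)), trend = "none"))
  blocks <- Filter(function(b) length(b$members) >= 2L, blocks)
  lapply(blocks, function(b) {
    b$sd <- plan$block_factor_sd
    b
  })
}

# family pools constrained so a planted family's substrate set never leaves
# the MAG's guild (ambiguous families only where the guild covers them)
# repeated entries weight the draw toward the widely distributed exo-acting
# (LMW) enzymes; endo-acting (HMW) capacity stays rarer, as in real guts
singleton_pool <- function(substrate, guild) {
  pool <- switch(substrate,
    alginate = c("PL17", "PL17", "PL6", "PL34", "PL38"),
    laminarin = c("GH3", "GH3", "GH1", "GH1", "GH149",
                  if ("agarose" %in% guild) "GH16",
                  if ("FCSP" %in% guild) "GH30"),
    FCSP = c("GH29", "GH141", "GH151",
             if ("laminarin" %in% guild) "GH30"),
    carrageenan = "GH150",
    agarose = c("GH86", "GH50", if ("laminarin" %in% guild) "GH16"),
    galactan = c("GH2", "GH2", "GH42", "GH36", "GH110"),
    starch = c("GH31", "GH31", "GH133", "GH13", "GH57", "GH77"),
    stop("unknown substrate: ", substrate))
  pool
}

cgc_family_pair <- function(substrate, guild) {
  opts <- switch(substrate,
    alginate = list(c("PL6", "PL17"), c("PL34", "PL17"), c("PL6", "PL34")),
    laminarin = c(list(c("GH149", "GH3"), c("GH149", "GH1")),
                  if ("agarose" %in% guild) list(c("GH16", "GH3"))),
    FCSP = list(c("GH29", "GH141"), c("GH29", "GH151")),
    carrageenan = list(c("GH150", "GH150")),
    agarose = c(list(c("GH86", "GH50")),
                if ("laminarin" %in% guild) list(c("GH86", "GH16"))),
    starch = list(c("GH13", "GH57"), c("GH57", "GH77"), c("GH13", "GH31")),
    stop("unknown substrate: ", substrate))
  opts[[sample.int(length(opts), 1L)]]
}

#' Plant one CAZyme gene cluster template
#'
#' Draws a contiguous gene-run template for one substrate: at least two
#' degradative CAZymes from the substrate's family set plus at least one
#' transporter (and sometimes a regulator), with internal gaps of at most
#' two non-signature genes. Offsets are relative gene slots; the generator
#' translates them onto a contig. Uses the current RNG state.
#'
#' @param mag_id MAG identifier stamped on the template.
#' @param substrate One of alginate, laminarin, FCSP, carrageenan, agarose,
#'   starch.
#' @param guild Substrate guild of the MAG (constrains ambiguous families);
#'   NULL allows every family of the substrate.
#' @return A data.frame: `mag_id`, `offset`, `role`, `family`, `substrate`.
#' @export
plant_cgc <- function(mag_id, substrate, guild = NULL) {
  if (!substrate %in% CGC_SUBSTRATES)
    stop("unknown substrate: ", substrate)
  if (is.null(guild))
    guild <- setdiff(SUBSTRATE_PANELS, c("sulfatase", "mannitol"))
  fams <- cgc_family_pair(substrate, guild)
  patterns <- list(c("CAZ", "TC", "CAZ"),
                   c("TC", "CAZ", "CAZ", "TF"),
                   c("CAZ", "other", "CAZ", "TC"),
                   c("CAZ", "CAZ", "other", "other", "TC"))
  pat <- patterns[[sample.int(length(patterns), 1L)]]
  role <- ifelse(pat == "CAZ", "CAZyme", pat)
  family <- rep(NA_character_, length(pat))
  family[role == "CAZyme"] <- sample(fams)
  data.frame(mag_id = mag_id, offset = seq_along(pat), role = role,
             family = family, substrate = substrate,
             stringsAsFactors = FALSE)
}

# place a feature of `len` consecutive slots on a contig: a start position
# is feasible iff no already-placed slot lies within `buffer` slots of the
# new span (so planted features are always separated by more than the CGC
# gap limit and can never merge). Sampled uniformly over the exact feasible
# set; NULL when the contig is full.
place_feature <- function(state, len, buffer = 3L) {
  n <- state$n
  if (len > n) return(NULL)
  starts <- seq_len(n - len + 1L)
  feasible <- vapply(starts, function(s) {
    w <- max(1L, s - buffer):min(n, s + len - 1L + buffer)
    !any(state$occ[w])
  }, logical(1))
  if (!any(feasible)) return(NULL)
  s <- starts[feasible][sample.int(sum(feasible), 1L)]
  s:(s + len - 1L)
}

#' Generate a synthetic community bundle
#'
#' Writes the full on-disk input bundle (gene table, three-stream CAZyme
#' hits, sulfatase and domain hits, MAG metadata, abundance and sample
#' tables, transcript counts) plus a ground-truth sidecar, deterministically
#' from the plan's seed. The previous RNG state of the session is restored
#' on exit.
#'
#' @param plan A [community_plan()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `paths`, `truth` (in-memory ground
#'   truth tables) and `plan`.
#' @export
generate_community <- function(plan, dir) {
  stopifnot(inherits(plan, "community_plan"))
  validate_plan(plan)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(plan$rng_seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "ground_truth"), showWarnings = FALSE)

  mt <- plan$mag_table
  n_mag <- nrow(mt)
  per_contig <- plan$genes_per_mag %/% plan$contigs_per_mag
  genes_list <- list(); hits_list <- list(); sulf_list <- list()
  dom_list <- list(); truth_fam <- list(); truth_cgc <- list()
  fam_pool <- names(FAMILY_EC)
  all_fams_catalog <- unique(c(fam_pool, "CE1", "CE6", "CBM32", "CBM48",
                               "GT2", "AA3"))

  for (mi in seq_len(n_mag)) {
    mag <- mt$mag_id[mi]
    klass <- mt$class[mi]
    guild <- plan$class_guilds[[klass]]
    if (is.null(guild)) guild <- character()
    contigs <- sprintf("%s_c%02d", mag, seq_len(plan$contigs_per_mag))
    n_genes_mag <- per_contig * plan$contigs_per_mag
    roles <- rep("other", n_genes_mag)
    fams <- rep(NA_character_, n_genes_mag)
    sub_of <- rep(NA_character_, n_genes_mag)
    contig_of <- rep(contigs, each = per_contig)
    slot_in_contig <- rep(seq_len(per_contig), times = plan$contigs_per_mag)
    states <- lapply(contigs, function(cc) list(occ = rep(FALSE, per_contig),
                                                n = per_contig))
    names(states) <- contigs
    mark <- function(cc, span) {
      st <- states[[cc]]
      st$occ[span] <- TRUE
      states[[cc]] <<- st
      (match(cc, contigs) - 1L) * per_contig + span
    }
    place <- function(len) {
      for (cc in sample(contigs)) {
        span <- place_feature(states[[cc]], len)
        if (!is.null(span)) return(list(contig = cc, span = span))
      }
      stop("infeasible plan: no room left on MAG ", mag)
    }

    # planted CGCs
    cgc_subs <- intersect(guild, CGC_SUBSTRATES)
    n_cgc <- if (length(cgc_subs)) stats::rpois(1L, plan$cgc_rate) else 0L
    for (ci in seq_len(n_cgc)) {
      substrate <- if (length(cgc_subs) == 1L) cgc_subs else
        sample(cgc_subs, 1L)
      tpl <- plant_cgc(mag, substrate, guild)
      loc <- place(nrow(tpl))
      gidx <- mark(loc$contig, loc$span)
      roles[gidx] <- tpl$role
      fams[gidx] <- tpl$family
      sub_of[gidx] <- substrate
      truth_cgc[[length(truth_cgc) + 1L]] <- data.frame(
        mag_id = mag, contig_id = loc$contig,
        first_slot = min(loc$span), last_slot = max(loc$span),
        substrate = substrate, degradative = TRUE,
        stringsAsFactors = FALSE)
    }

    # weak clusters: one CAZyme + one transporter, never degradative
    poly_guild <- intersect(guild, setdiff(SUBSTRATE_PANELS,
                                           c("sulfatase", "mannitol")))
    n_weak <- if (length(poly_guild)) stats::rpois(1L, plan$weak_cgc_rate)
      else 0L
    for (wi in seq_len(n_weak)) {
      substrate <- if (length(poly_guild) == 1L) poly_guild else
        sample(poly_guild, 1L)
      pool <- singleton_pool(substrate, guild)
      pat <- if (stats::runif(1) < 0.5) c("CAZyme", "TC") else
        c("TC", "CAZyme")
      loc <- place(2L)
      gidx <- mark(loc$contig, loc$span)
      roles[gidx] <- pat
      fams[gidx[pat == "CAZyme"]] <- pool[sample.int(length(pool), 1L)]
      sub_of[gidx[pat == "CAZyme"]] <- substrate
      truth_cgc[[length(truth_cgc) + 1L]] <- data.frame(
        mag_id = mag, contig_id = loc$contig,
        first_slot = min(loc$span), last_slot = max(loc$span),
        substrate = NA_character_, degradative = FALSE,
        stringsAsFactors = FALSE)
    }

    # scattered singleton CAZymes covering every guild substrate; LMW-rich
    # substrates (downstream oligomer consumption) are planted more densely
    # than the rarer endo-acting HMW capacity
    rate <- CLASS_SINGLETON_RATE[[klass]] * plan$singleton_scale
    sub_mult <- c(alginate = 1, laminarin = 2, FCSP = 0.5, carrageenan = 0.5,
                  agarose = 0.5, galactan = 3, starch = 2)
    for (substrate in intersect(guild, setdiff(SUBSTRATE_PANELS,
                                               c("sulfatase", "mannitol")))) {
      k <- 1L + stats::rpois(1L, rate * sub_mult[[substrate]])
      pool <- singleton_pool(substrate, guild)
      for (j in seq_len(k)) {
        loc <- place(1L)
        gidx <- mark(loc$contig, loc$span)
        roles[gidx] <- "CAZyme"
        fams[gidx] <- pool[sample.int(length(pool), 1L)]
        sub_of[gidx] <- substrate
      }
    }

    # sulfatases
    if ("sulfate_removal" %in% guild) {
      s_pool <- if ("carrageenan" %in% guild)
        c("S1_7", "S1_19", "S1_8", "S1_15", "S1_16", "S1_17", "S1_25") else
          c("S1_15", "S1_16", "S1_17", "S1_25", "S1_8")
      k <- 1L + stats::rpois(1L, if (klass %in% c("Bacteroidia",
                                                  "Verrucomicrobiae")) 4 else 1)
      for (j in seq_len(k)) {
        loc <- place(1L)
        gidx <- mark(loc$contig, loc$span)
        roles[gidx] <- "sulfatase"
        fams[gidx] <- s_pool[sample.int(length(s_pool), 1L)]
      }
    }

    # mannitol route genes (complete routes only)
    if ("mannitol" %in% guild) {
      syms <- if (klass %in% c("Bacteroidia", "Verrucomicrobiae"))
        c("m2dh", "fructokinase") else c("pts_mtl", "m1pdh")
      if (klass == "Clostridia" && stats::runif(1) < 0.3)
        syms <- c(syms, "m2dh", "fructokinase")
      for (sym in syms) {
        loc <- place(1L)
        gidx <- mark(loc$contig, loc$span)
        roles[gidx] <- paste0("gene:", sym)
      }
    }

    # background transporters/regulators away from any CAZyme
    n_bg <- max(2L, n_genes_mag %/% 100L)
    for (j in seq_len(n_bg)) {
      placed <- tryCatch(place(1L), error = function(e) NULL)
      if (is.null(placed)) break
      gidx <- mark(placed$contig, placed$span)
      roles[gidx] <- if (stats::runif(1) < 0.7) "TC" else "TF"
    }

    gene_ids <- sprintf("%s_g%04d", mag, seq_len(n_genes_mag))
    start <- (slot_in_contig - 1L) * 1000L + 1L
    product <- rep("hypothetical protein", n_genes_mag)
    product[roles == "TC"] <- "TC"
    product[roles == "TF"] <- "TF"
    gene_syms <- grepl("^gene:", roles)
    product[gene_syms] <- sub("^gene:", "", roles[gene_syms])
    genes_list[[mi]] <- data.frame(
      gene_id = gene_ids, mag_id = mag, contig_id = contig_of,
      start = start, end = start + 899L,
      strand = sample(c("+", "-"), n_genes_mag, replace = TRUE),
      product_label = product, stringsAsFactors = FALSE)

    # annotation evidence for CAZyme genes
    caz <- which(roles == "CAZyme")
    if (length(caz)) {
      hits_list[[length(hits_list) + 1L]] <-
        emit_cazyme_hits(gene_ids[caz], fams[caz], plan, all_fams_catalog)
      truth_fam[[length(truth_fam) + 1L]] <- data.frame(
        protein_id = gene_ids[caz], mag_id = mag, family = fams[caz],
        substrate = sub_of[caz], stringsAsFactors = FALSE)
    }

    # sulfatase evidence + PF00884 domain rows
    sulf <- which(roles == "sulfatase")
    if (length(sulf)) {
      sulf_list[[length(sulf_list) + 1L]] <- data.frame(
        protein_id = gene_ids[sulf], source = "DIAMOND", label = fams[sulf],
        coverage = round(stats::runif(length(sulf), 0.55, 0.95), 3),
        identity = round(stats::runif(length(sulf), 0.35, 0.80), 3),
        evalue = 10^-round(stats::runif(length(sulf), 10, 60), 1),
        ec = NA_character_, domains = "", stringsAsFactors = FALSE)
      dom_list[[length(dom_list) + 1L]] <- data.frame(
        protein_id = gene_ids[sulf], domain = "PF00884",
        stringsAsFactors = FALSE)
    }

    # sulfatase decoys that must fail the acceptance filter
    if (length(sulf) && stats::runif(1) < 0.8) {
      other <- which(roles == "other")
      dec <- other[sample.int(length(other), 1L)]
      fail_cov <- stats::runif(1) < 0.5
      sulf_list[[length(sulf_list) + 1L]] <- data.frame(
        protein_id = gene_ids[dec], source = "DIAMOND", label = "S1_15",
        coverage = if (fail_cov) round(stats::runif(1, 0.05, 0.45), 3) else
          round(stats::runif(1, 0.55, 0.9), 3),
        identity = round(stats::runif(1, 0.35, 0.8), 3),
        evalue = 1e-12, ec = NA_character_, domains = "",
        stringsAsFactors = FALSE)
      if (!fail_cov) {
        # passes thresholds but lacks PF00884: no domain row emitted
      } else {
        dom_list[[length(dom_list) + 1L]] <- data.frame(
          protein_id = gene_ids[dec], domain = "PF00884",
          stringsAsFactors = FALSE)
      }
    }
  }

  genes <- do.call(rbind, genes_list)
  genes <- genes[order(genes$mag_id, genes$contig_id, genes$start), ,
                 drop = FALSE]
  hits <- if (length(hits_list)) do.call(rbind, hits_list) else
    data.frame(protein_id = character(), source = character(),
               label = character(), coverage = numeric(),
               identity = numeric(), evalue = numeric(), ec = character(),
               domains = character(), stringsAsFactors = FALSE)
  sulf_hits <- if (length(sulf_list)) do.call(rbind, sulf_list) else hits[0, ]
  dom_hits <- if (length(dom_list)) do.call(rbind, dom_list) else
    data.frame(protein_id = character(), domain = character(),
               stringsAsFactors = FALSE)

  mag_meta <- mt
  mag_meta$completeness <- round(stats::runif(n_mag,
                                              plan$completeness_range[1],
                                              plan$completeness_range[2]), 1)
  mag_meta$contamination <- round(stats::runif(n_mag,
                                               plan$contamination_range[1],
                                               plan$contamination_range[2]), 1)
  mag_meta$n_genes <- per_contig * plan$contigs_per_mag
  mag_meta$genome_size <- mag_meta$n_genes * 1000L

  ab <- sample_abundances(plan)
  expr <- simulate_transcripts(plan, genes, hits, sulf_hits)

  # ground truth
  truth_fam <- if (length(truth_fam)) do.call(rbind, truth_fam) else
    data.frame(protein_id = character(), mag_id = character(),
               family = character(), substrate = character(),
               stringsAsFactors = FALSE)
  truth_cgc <- if (length(truth_cgc)) do.call(rbind, truth_cgc) else
    data.frame(mag_id = character(), contig_id = character(),
               first_slot = integer(), last_slot = integer(),
               substrate = character(), degradative = logical(),
               stringsAsFactors = FALSE)
  truth_cap <- truth_capability(plan)
  truth_blocks <- do.call(rbind, c(list(
    data.frame(mag_id = character(), block = character(),
               stringsAsFactors = FALSE)),
    lapply(seq_along(plan$coabund_blocks), function(i)
      data.frame(mag_id = plan$coabund_blocks[[i]]$members,
                 block = sprintf("block%02d", i), stringsAsFactors = FALSE))))

  paths <- list(
    genes = file.path(dir, "genes.gff3"),
    cazyme_hits = file.path(dir, "cazyme_hits.tsv"),
    sulfatase_hits = file.path(dir, "sulfatase_hits.tsv"),
    domain_hits = file.path(dir, "domain_hits.tsv"),
    mag_metadata = file.path(dir, "mag_metadata.tsv"),
    abundance = file.path(dir, "abundance.tsv"),
    sample_metadata = file.path(dir, "sample_metadata.tsv"),
    transcript_counts = file.path(dir, "transcript_counts.tsv"))
  write_gene_table(genes, paths$genes)
  write_annotation_hits(hits, paths$cazyme_hits)
  write_annotation_hits(sulf_hits, paths$sulfatase_hits)
  write_tsv_exact(dom_hits, paths$domain_hits)
  write_tsv_exact(mag_meta, paths$mag_metadata)
  write_tsv_exact(ab$abundance, paths$abundance)
  write_tsv_exact(rbind(ab$sample_meta, rna_sample_metadata(plan)),
                  paths$sample_metadata)
  write_tsv_exact(expr, paths$transcript_counts)
  gt_dir <- file.path(dir, "ground_truth")
  write_tsv_exact(truth_fam, file.path(gt_dir, "truth_families.tsv"))
  write_tsv_exact(truth_cgc, file.path(gt_dir, "truth_cgcs.tsv"))
  write_tsv_exact(truth_cap, file.path(gt_dir, "truth_capability.tsv"))
  write_tsv_exact(truth_blocks, file.path(gt_dir, "truth_blocks.tsv"))
  yaml::write_yaml(list(rng_seed = plan$rng_seed,
                        n_mags = n_mag,
                        genes_per_mag = mag_meta$n_genes[1],
                        label_noise = plan$label_noise,
                        annotator_agreement = plan$annotator_agreement),
                   file.path(gt_dir, "plan.yaml"))

  truth <- list(families = truth_fam, cgcs = truth_cgc,
                capability = truth_cap, blocks = truth_blocks)
  invisible(list(dir = dir, paths = paths, truth = truth, plan = plan))
}

emit_cazyme_hits <- function(protein_ids, families, plan, fam_universe) {
  n <- length(protein_ids)
  out <- list()
  for (src in ANNOTATION_SOURCES) {
    present <- stats::runif(n) <= plan$annotator_agreement
    if (!any(present)) next
    ids <- protein_ids[present]
    fam <- families[present]
    noisy <- stats::runif(length(ids)) < plan$label_noise
    if (any(noisy)) {
      fam[noisy] <- vapply(fam[noisy], function(f) {
        alt <- setdiff(fam_universe, f)
        alt[sample.int(length(alt), 1L)]
      }, character(1))
    }
    label <- fam
    if (src == "eCAMI") {
      # k-mer classifier reports subfamily granularity for some proteins
      subfam <- stats::runif(length(ids)) < 0.3 & grepl("^(GH|PL|CE)", fam)
      label[subfam] <- paste0(fam[subfam], "_",
                              sample.int(5L, sum(subfam), replace = TRUE))
    }
    ec <- rep(NA_character_, length(ids))
    coverage <- round(stats::runif(length(ids), 0.6, 0.98), 3)
    identity <- round(stats::runif(length(ids), 0.35, 0.9), 3)
    if (src == "DIAMOND") {
      has_ec <- fam %in% names(FAMILY_EC)
      ec[has_ec] <- unname(FAMILY_EC[fam[has_ec]])
      fail <- stats::runif(length(ids)) < plan$ec_fail_rate
      coverage[has_ec & fail] <- round(stats::runif(sum(has_ec & fail),
                                                    0.05, 0.39), 3)
    }
    out[[length(out) + 1L]] <- data.frame(
      protein_id = ids, source = src, label = label,
      coverage = coverage, identity = identity,
      evalue = 10^-round(stats::runif(length(ids), 10, 80), 1),
      ec = ec, domains = "", stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

truth_capability <- function(plan) {
  mt <- plan$mag_table
  cap <- data.frame(mag_id = mt$mag_id, stringsAsFactors = FALSE)
  for (panel in SUBSTRATE_PANELS) {
    key <- switch(panel, sulfatase = "sulfate_removal", panel)
    cap[[panel]] <- vapply(mt$class, function(k)
      key %in% plan$class_guilds[[k]], logical(1))
  }
  cap
}

#' Sample a relative-abundance table from the plan
#'
#' Per-MAG baselines are lognormal with class-specific means; MAGs in the
#' same co-abundance block share a per-sample latent lognormal factor, and a
#' block's enriched section receives a multiplicative shift. Independent
#' multiplicative gamma noise is added per MAG and sample before closure to
#' 100% (closure of independent gammas yields Dirichlet-type residuals).
#' Uses the current RNG state.
#'
#' @param plan A [community_plan()].
#' @return A list with `abundance` (samples x MAGs, percent) and
#'   `sample_meta`.
#' @export
sample_abundances <- function(plan) {
  mt <- plan$mag_table
  n_mag <- nrow(mt)
  base_meanlog <- c(Bacteroidia = 1.5, Clostridia = 1.0, Bacilli = 0.2)
  ml <- ifelse(mt$class %in% names(base_meanlog),
               base_meanlog[mt$class], -0.5)
  base <- stats::rlnorm(n_mag, meanlog = ml, sdlog = 0.6)
  samples <- expand.grid(fish = seq_len(plan$n_fish),
                         section = plan$sections,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sample_id <- sprintf("MG_f%02d_%s", samples$fish, samples$section)
  block_of <- rep(NA_integer_, n_mag)
  for (i in seq_along(plan$coabund_blocks))
    block_of[match(plan$coabund_blocks[[i]]$members, mt$mag_id)] <- i
  x <- matrix(0, nrow = nrow(samples), ncol = n_mag,
              dimnames = list(sample_id, mt$mag_id))
  n_block <- length(plan$coabund_blocks)
  block_sd <- vapply(plan$coabund_blocks, function(b)
    if (is.null(b$sd)) plan$block_factor_sd else b$sd, numeric(1))
  trend <- vapply(plan$coabund_blocks, function(b)
    if (is.null(b$trend)) "none" else b$trend, character(1))
  for (s in seq_len(nrow(samples))) {
    f_block <- if (n_block) stats::rnorm(n_block, 0, block_sd) else numeric()
    lat <- ifelse(is.na(block_of), 0, f_block[block_of])
    shift <- rep(0, n_mag)
    if (n_block) {
      enr <- trend[block_of]
      shift[!is.na(block_of) & enr == samples$section[s]] <-
        plan$section_effect
    }
    noise <- if (plan$abund_noise_sd > 0)
      stats::rgamma(n_mag, shape = 1 / plan$abund_noise_sd^2,
                    rate = 1 / plan$abund_noise_sd^2) else rep(1, n_mag)
    w <- base * exp(lat + shift) * noise
    x[s, ] <- 100 * w / sum(w)
  }
  abundance <- data.frame(sample_id = sample_id, x, check.names = FALSE,
                          stringsAsFactors = FALSE)
  rownames(abundance) <- NULL
  sample_meta <- data.frame(
    sample_id = sample_id,
    fish_id = sprintf("fish%02d", samples$fish),
    section = samples$section,
    year = 2017L, assay = "metagenome", stringsAsFactors = FALSE)
  list(abundance = abundance, sample_meta = sample_meta)
}

# negative-binomial transcript counts for annotated genes, with
# class-by-section expression multipliers; metatranscriptome samples are
# emitted for rna_sections over n_fish_rna fish
simulate_transcripts <- function(plan, genes, hits, sulf_hits) {
  ann_genes <- unique(c(hits$protein_id, sulf_hits$protein_id,
                        genes$gene_id[genes$product_label %in%
                                        c("m2dh", "fructokinase", "pts_mtl",
                                          "m1pdh")]))
  if (!length(ann_genes))
    return(data.frame(gene_id = character(), stringsAsFactors = FALSE))
  mag <- genes$mag_id[match(ann_genes, genes$gene_id)]
  mt <- plan$mag_table
  klass <- mt$class[match(mag, mt$mag_id)]
  base <- stats::rlnorm(length(ann_genes), meanlog = 3, sdlog = 0.5)
  samples <- expand.grid(fish = seq_len(plan$n_fish_rna),
                         section = plan$rna_sections,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sid <- sprintf("MT_f%02d_%s", samples$fish, samples$section)
  out <- data.frame(gene_id = ann_genes, stringsAsFactors = FALSE)
  for (s in seq_len(nrow(samples))) {
    mult <- plan$expression_multipliers[[samples$section[s]]]
    m <- ifelse(klass %in% names(mult), mult[klass], 0.2)
    out[[sid[s]]] <- stats::rnbinom(length(ann_genes),
                                    mu = base * m, size = plan$nb_size)
  }
  out
}

# sample metadata rows for the metatranscriptome samples of a plan
rna_sample_metadata <- function(plan) {
  samples <- expand.grid(fish = seq_len(plan$n_fish_rna),
                         section = plan$rna_sections,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("MT_f%02d_%s", samples$fish,
                                 samples$section),
             fish_id = sprintf("rnafish%02d", samples$fish),
             section = samples$section,
             year = 2020L, assay = "metatranscriptome",
             stringsAsFactors = FALSE)
}

#' @export
print.community_plan <- function(x, ...) {
  cat(sprintf("<community_plan> %d MAGs (%s), %d genes/MAG, seed %d\n",
              nrow(x$mag_table),
              paste(sprintf("%s=%d", names(x$n_mags_per_class),
                            x$n_mags_per_class), collapse = ", "),
              x$genes_per_mag, x$rng_seed))
  invisible(x)
}
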