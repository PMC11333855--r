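cfg <- pipeline_config()
catalog <- load_substrate_catalog()

test_that("noise-free bundles give every protein three identical labels", {
  plan <- small_plan(seed = 3L)
  dir <- withr::local_tempdir()
  b <- generate_community(plan, dir)
  hits <- read_annotation_hits(b$paths$cazyme_hits)
  truth <- b$truth$families
  lab <- collapse_subfamily(hits$label)
  expect_identical(unname(lab),
                   unname(truth$family[match(hits$protein_id,
                                             truth$protein_id)]))
  # every annotated protein has all three streams
  expect_true(all(table(hits$protein_id) == 3L))
})

test_that("same plan and seed produce byte-identical bundles", {
  plan <- small_plan(seed = 11L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_community(plan, d1)
  generate_community(plan, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("the default plan emits 68 MAGs with quality in the retained window", {
  plan <- community_plan(genes_per_mag = 250L, cgc_rate = 0.5,
                         weak_cgc_rate = 0.5, singleton_scale = 0.1,
                         rng_seed = 5L)
  dir <- withr::local_tempdir()
  generate_community(plan, dir)
  meta <- read_mag_metadata(file.path(dir, "mag_metadata.tsv"))
  expect_equal(nrow(meta), 68L)
  expect_true(all(meta$completeness >= 75.0 & meta$completeness <= 99.5))
  expect_true(all(meta$contamination >= 0 & meta$contamination <= 6.4))
  expect_equal(sum(meta$class == "Bacteroidia"), 31L)
  expect_equal(sum(meta$class == "Clostridia"), 23L)
  expect_equal(sum(meta$class == "Bacilli"), 5L)
})

test_that("planted alginate clusters hold two dedicated lyases plus a transporter", {
  set.seed(1)
  for (i in 1:20) {
    tpl <- plant_cgc("MAGX", "alginate")
    caz <- tpl$family[tpl$role == "CAZyme"]
    expect_gte(sum(caz %in% c("PL6", "PL17", "PL34")), 2L)
    expect_true(any(tpl$role %in% c("TC", "TF")))
    gaps <- diff(tpl$offset[tpl$role %in% c("CAZyme", "TC", "TF", "STP")])
    expect_true(all(gaps - 1L <= 2L))
  }
  expect_error(plant_cgc("MAGX", "lignin"), "unknown substrate")
})

test_that("planted laminarin clusters pair an endo family with an exo glucosidase", {
  set.seed(2)
  for (i in 1:20) {
    tpl <- plant_cgc("MAGX", "laminarin",
                     guild = c("laminarin", "agarose"))
    caz <- tpl$family[tpl$role == "CAZyme"]
    expect_true(any(caz %in% c("GH16", "GH149")))  # endo-acting
    expect_true(any(caz %in% c("GH3", "GH1")))     # exo beta-glucosidase
  }
})

test_that("planted clusters are always recovered at zero noise", {
  total_planted <- 0L
  for (seed in c(21L, 22L)) {
    plan <- small_plan(seed = seed)
    dir <- withr::local_tempdir()
    b <- generate_community(plan, dir)
    genes <- read_gene_table(b$paths$genes)
    hits <- read_annotation_hits(b$paths$cazyme_hits)
    calls <- consensus_annotate(hits, cfg, gene_map = genes)
    cgcs <- detect_cgcs(genes, assign_gene_roles(genes, calls), cfg)
    cgcs <- infer_substrates(flag_degradative(cgcs, cfg), catalog)
    truth <- b$truth$cgcs
    total_planted <- total_planted + nrow(truth)
    expect_equal(nrow(cgcs$clusters), nrow(truth))
    # every planted degradative cluster is found with its substrate
    tr_deg <- truth[truth$degradative, , drop = FALSE]
    got <- cgcs$clusters[cgcs$clusters$substrates != "", , drop = FALSE]
    key <- function(m, c, s) paste(m, c, s)
    expect_setequal(key(got$mag_id, got$contig_id, got$substrates),
                    key(tr_deg$mag_id, tr_deg$contig_id, tr_deg$substrate))
  }
  expect_gt(total_planted, 0L)
})

test_that("abundance rows close to 100 percent", {
  plan <- small_plan(seed = 4L)
  set.seed(4)
  ab <- sample_abundances(plan)
  sums <- rowSums(ab$abundance[, -1])
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_true(all(as.matrix(ab$abundance[, -1]) >= 0))
})

test_that("a strong two-MAG block is tightly correlated over 8 samples", {
  plan <- community_plan(
    n_mags_per_class = c(Bacteroidia = 10L, Clostridia = 10L),
    genes_per_mag = 100L, n_fish = 4L, sections = c("IV", "V"),
    coabund_blocks = list(list(members = c("MAG_001", "MAG_002"), sd = 1.5,
                               trend = "none")),
    abund_noise_sd = 0.2, rng_seed = 7L)
  set.seed(7)
  ab <- sample_abundances(plan)
  r <- cor(ab$abundance$MAG_001, ab$abundance$MAG_002)
  expect_gt(r, 0.8)
})

test_that("zero factor sd and zero noise give proportional block members", {
  plan <- community_plan(
    n_mags_per_class = c(Bacteroidia = 6L, Clostridia = 4L),
    genes_per_mag = 100L, n_fish = 4L, sections = c("IV", "V"),
    coabund_blocks = list(
      list(members = c("MAG_001", "MAG_002"), sd = 0, trend = "none"),
      list(members = c("MAG_003", "MAG_004"), sd = 0.8, trend = "none")),
    abund_noise_sd = 0, rng_seed = 8L)
  set.seed(8)
  ab <- sample_abundances(plan)
  ratio <- ab$abundance$MAG_001 / ab$abundance$MAG_002
  expect_equal(ratio, rep(ratio[1], length(ratio)))
  expect_equal(cor(ab$abundance$MAG_001, ab$abundance$MAG_002), 1)
})

test_that("with label noise the consensus error matches the binomial expectation", {
  plan <- community_plan(
    n_mags_per_class = c(Bacteroidia = 14L, Clostridia = 8L),
    genes_per_mag = 1200L, contigs_per_mag = 3L, cgc_rate = 1,
    weak_cgc_rate = 0, label_noise = 0.1, coabund_blocks = FALSE,
    rng_seed = 31L)
  dir <- withr::local_tempdir()
  b <- generate_community(plan, dir)
  genes <- read_gene_table(b$paths$genes)
  hits <- read_annotation_hits(b$paths$cazyme_hits)
  calls <- consensus_annotate(hits, cfg, gene_map = genes)
  truth <- b$truth$families
  n <- nrow(truth)
  expect_gte(n, 1000L)
  called <- calls$family[match(truth$protein_id, calls$protein_id)]
  err <- sum(!is.na(called) & called != truth$family) / n
  nocall <- sum(is.na(called)) / n
  p <- 0.1
  L <- 29  # alternative labels the noise model draws from
  q <- 1 - p
  p_correct <- q^3 + 3 * q^2 * p
  p_err <- 3 * p^2 / L * (1 - p / L) + p^3 / L^2
  p_nocall <- 1 - p_correct - p_err
  se <- function(pr) sqrt(pr * (1 - pr) / n)
  expect_lt(abs(err - p_err), 3 * se(p_err) + 1e-12)
  expect_lt(abs(nocall - p_nocall), 3 * se(p_nocall))
})

test_that("generated bundles always satisfy the reader invariants", {
  set.seed(123)
  for (i in 1:25) {
    plan <- community_plan(
      n_mags_per_class = c(Bacteroidia = sample(1:3, 1),
                           Clostridia = sample(1:3, 1),
                           Desulfobacteria = 1L),
      genes_per_mag = sample(c(260L, 400L), 1),
      contigs_per_mag = sample(1:3, 1),
      cgc_rate = runif(1, 0, 1.5), weak_cgc_rate = runif(1, 0, 1),
      singleton_scale = 0.3,
      label_noise = runif(1, 0, 0.3),
      annotator_agreement = runif(1, 0.7, 1),
      coabund_blocks = FALSE,
      rng_seed = sample.int(1e6, 1))
    dir <- withr::local_tempdir()
    b <- generate_community(plan, dir)
    # readers validate on load; any invariant violation errors here
    expect_no_error({
      read_gene_table(b$paths$genes)
      read_annotation_hits(b$paths$cazyme_hits)
      read_annotation_hits(b$paths$sulfatase_hits)
      read_mag_metadata(b$paths$mag_metadata)
      read_abundance_table(b$paths$abundance)
      read_sample_metadata(b$paths$sample_metadata)
      read_transcript_counts(b$paths$transcript_counts)
    })
  }
})
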