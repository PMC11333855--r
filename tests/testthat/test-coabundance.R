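cfg <- pipeline_config()
catalog <- load_substrate_catalog()

make_abundance <- function(mat, sample_ids = sprintf("s%d", seq_len(nrow(mat)))) {
  data.frame(sample_id = sample_ids,
             sweep(mat, 1L, rowSums(mat), "/") * 100,
             check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("correlations match the direct product-moment formula", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5); z <- c(4, 3, 2, 1)
  ab <- data.frame(sample_id = sprintf("s%d", 1:4), M1 = x, M2 = y, M3 = z,
                   M4 = 100 - x - y - z, stringsAsFactors = FALSE)
  corr <- correlate_abundances(ab)
  want <- oracle_pearson(x, y)
  expect_equal(corr$r["M1", "M2"], want$r)
  expect_equal(corr$p["M1", "M2"], want$p)
  expect_equal(corr$r["M1", "M1"], 1)
  expect_equal(corr$r["M1", "M3"], -1)   # perfect anticorrelation
  expect_equal(corr$p["M1", "M3"], 0)
  expect_true(all(abs(corr$r - t(corr$r)) < 1e-12))

  ab$M2 <- 10; ab$M4 <- 100 - ab$M1 - 10 - ab$M3
  expect_warning(c2 <- correlate_abundances(ab), "constant")
  expect_false("M2" %in% colnames(c2$r))
})

test_that("identical vectors correlate at exactly 1 with p 0", {
  ab <- data.frame(sample_id = sprintf("s%d", 1:4),
                   M1 = c(10, 20, 30, 40), M2 = c(5, 10, 15, 20),
                   M3 = c(85, 70, 55, 40), stringsAsFactors = FALSE)
  corr <- correlate_abundances(ab)
  expect_equal(corr$r["M1", "M2"], 1)
  expect_equal(corr$p["M1", "M2"], 0)
})

test_that("fewer than 3 samples is an error", {
  ab <- data.frame(sample_id = c("s1", "s2"), M1 = c(60, 40),
                   M2 = c(40, 60), stringsAsFactors = FALSE)
  expect_error(correlate_abundances(ab), "at least 3 samples")
})

test_that("a single strong pair forms one two-member group", {
  # M1 and M2 share a linear trend; the remaining MAGs follow mutually
  # orthogonal polynomial contrasts, so every other pairwise r is exactly 0
  t <- 1:12
  ortho <- poly(t, 5)
  mat <- cbind(M1 = 10 + t, M2 = 5 + 2 * t,
               M3 = 8 + ortho[, 2], M4 = 8 + ortho[, 3],
               M5 = 8 + ortho[, 4], M6 = 8 + ortho[, 5])
  ab <- data.frame(sample_id = sprintf("s%d", t), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  corr <- correlate_abundances(ab)
  expect_equal(corr$r["M1", "M2"], 1)
  expect_equal(corr$r["M3", "M4"], 0)
  groups <- delineate_groups(corr, ab, config = cfg)
  expect_equal(nrow(groups$groups), 1L)
  expect_setequal(groups$members$mag_id, c("M1", "M2"))
  expect_equal(groups$groups$group_id, "G1")  # no section info
})

test_that("independent MAGs yield no groups", {
  set.seed(2)
  mat <- matrix(rlnorm(10 * 6, 2, 0.5), nrow = 10,
                dimnames = list(NULL, sprintf("M%d", 1:6)))
  ab <- make_abundance(mat)
  groups <- delineate_groups(correlate_abundances(ab), ab, config = cfg)
  expect_equal(nrow(groups$groups), 0L)
})

test_that("group delineation is invariant to MAG column order", {
  plan <- community_plan(
    n_mags_per_class = c(Bacteroidia = 5L, Clostridia = 4L, Bacilli = 3L),
    genes_per_mag = 100L, n_fish = 6L, sections = c("IV", "V"),
    coabund_blocks = list(
      list(members = sprintf("MAG_%03d", 1:3), sd = 1, trend = "V"),
      list(members = sprintf("MAG_%03d", 6:8), sd = 1, trend = "IV")),
    abund_noise_sd = 0.2, rng_seed = 17L)
  set.seed(17)
  ab <- sample_abundances(plan)
  corr <- correlate_abundances(ab$abundance)
  g1 <- delineate_groups(corr, ab$abundance, ab$sample_meta, cfg)
  perm <- c("sample_id", sample(setdiff(names(ab$abundance), "sample_id")))
  ab2 <- ab$abundance[, perm]
  g2 <- delineate_groups(correlate_abundances(ab2), ab2, ab$sample_meta, cfg)
  expect_equal(g1$groups, g2$groups)
  expect_equal(g1$members, g2$members)
})

test_that("recovered groups improve with latent factor strength", {
  skip_if_not_installed("mclust")
  ari_at_sd <- function(sd) {
    plan <- community_plan(
      n_mags_per_class = c(Bacteroidia = 5L, Clostridia = 4L),
      genes_per_mag = 100L, n_fish = 6L, sections = c("IV", "V"),
      coabund_blocks = list(
        list(members = sprintf("MAG_%03d", 1:5), sd = sd, trend = "none"),
        list(members = sprintf("MAG_%03d", 6:9), sd = sd, trend = "none")),
      abund_noise_sd = 0.3, rng_seed = 170L)
    set.seed(170)
    ab <- sample_abundances(plan)
    groups <- delineate_groups(correlate_abundances(ab$abundance),
                               ab$abundance, ab$sample_meta, cfg)
    truth <- rep(1:2, c(5, 4))
    names(truth) <- sprintf("MAG_%03d", 1:9)
    got <- rep(0L, 9); names(got) <- names(truth)
    if (nrow(groups$members))
      got[groups$members$mag_id] <-
        as.integer(factor(groups$members$group_id))
    mclust::adjustedRandIndex(truth, got)
  }
  aris <- vapply(c(0.2, 0.8, 1.4), ari_at_sd, numeric(1))
  expect_true(all(diff(aris) >= 0))
  expect_equal(aris[3], 1)
})

test_that("fold changes use section means with a pseudocount", {
  ab <- data.frame(sample_id = sprintf("s%d", 1:4),
                   M1 = c(1, 1, 10, 10), M2 = c(20, 20, 20, 20),
                   M3 = c(0, 0, 1, 1), M4 = c(79, 79, 69, 69),
                   stringsAsFactors = FALSE)
  sm <- data.frame(sample_id = ab$sample_id, fish_id = sprintf("f%d", 1:4),
                   section = c("IV", "IV", "V", "V"), year = 2017L,
                   assay = "metagenome", stringsAsFactors = FALSE)
  fc <- section_fold_change(ab, sm, eps = 1e-12)
  expect_equal(fc$log10_fc[fc$mag_id == "M1"], 1, tolerance = 1e-9)
  expect_equal(fc$log10_fc[fc$mag_id == "M2"], 0)
  fc2 <- section_fold_change(ab, sm, eps = 0.01)
  expect_equal(fc2$log10_fc[fc2$mag_id == "M3"],
               log10(1.01 / 0.01), tolerance = 1e-9)
  expect_equal(round(fc2$log10_fc[fc2$mag_id == "M3"], 4), 2.0043)

  ab$M3 <- 0; ab$M4 <- c(79, 79, 70, 70)
  expect_message(fc3 <- section_fold_change(ab, sm), "absent")
  expect_false("M3" %in% fc3$mag_id)
})

test_that("group capability panels reflect member calls only", {
  groups <- list(groups = data.frame(group_id = c("B1", "B2"),
                                     n_members = c(2L, 1L),
                                     mean_within_r = 0.9,
                                     section_trend = "stable",
                                     stringsAsFactors = FALSE),
                 members = data.frame(group_id = c("B1", "B1", "B2"),
                                      mag_id = c("M1", "M2", "M3"),
                                      stringsAsFactors = FALSE))
  calls <- rbind(make_call("p1", "PL6", "M1"),    # alginate HMW
                 make_call("p2", "GH3", "M2"))    # laminarin LMW
  panel <- group_capability_panel(groups, calls, catalog)
  b1_alg_h <- panel[panel$group_id == "B1" & panel$substrate == "alginate" &
                      panel$weight_class == "HMW", ]
  expect_equal(b1_alg_h$n_genes, 1L)
  expect_equal(b1_alg_h$mag_fraction, 0.5)
  b1_lam_l <- panel[panel$group_id == "B1" & panel$substrate == "laminarin" &
                      panel$weight_class == "LMW", ]
  expect_equal(b1_lam_l$n_genes, 1L)
  # group with no calls at all: all-zero rows
  expect_true(all(panel$n_genes[panel$group_id == "B2"] == 0L))
})

test_that("a group lacking endo-laminarinase shows LMW-only laminarin capacity", {
  groups <- list(groups = data.frame(group_id = "B3", n_members = 2L,
                                     mean_within_r = 0.9,
                                     section_trend = "V-enriched",
                                     stringsAsFactors = FALSE),
                 members = data.frame(group_id = "B3",
                                      mag_id = c("M1", "M2"),
                                      stringsAsFactors = FALSE))
  calls <- rbind(make_call(c("p1", "p2"), "GH3", "M1"),
                 make_call("p3", "GH1", "M2"))
  panel <- group_capability_panel(groups, calls, catalog)
  lam <- panel[panel$substrate == "laminarin", ]
  expect_equal(lam$n_genes[lam$weight_class == "HMW"], 0L)
  expect_equal(lam$n_genes[lam$weight_class == "LMW"], 3L)
  expect_equal(lam$mag_fraction[lam$weight_class == "LMW"], 1)
})
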