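cfg <- pipeline_config()
catalog <- load_substrate_catalog()

profiles_from_counts <- function(density_by_class) {
  # density_by_class: named list class -> vector of CAZyme counts per MAG
  # (n_genes fixed at 1000 so counts equal densities)
  rows <- list(); calls <- list(); i <- 0L
  for (k in names(density_by_class)) {
    for (d in density_by_class[[k]]) {
      i <- i + 1L
      mag <- sprintf("M%03d", i)
      rows[[i]] <- make_mag_meta(mag, class = k, n_genes = 1000L)
      if (d > 0)
        calls[[length(calls) + 1L]] <-
          make_call(sprintf("%s_p%03d", mag, seq_len(d)), "GH3", mag)
    }
  }
  meta <- do.call(rbind, rows)
  calls <- if (length(calls)) do.call(rbind, calls) else
    make_call(character(), character(), character())
  mag_profiles(calls, meta, cfg)
}

test_that("density is CAZymes per 1000 genes (or per Mbp on request)", {
  meta <- make_mag_meta("M1", n_genes = 2000L, genome_size = 2500000L)
  calls <- make_call(sprintf("p%02d", 1:50), "GH3", "M1")
  prof <- mag_profiles(calls, meta, cfg)
  expect_equal(prof$density, 25.0)
  expect_equal(prof$n_cazymes, 50L)

  prof0 <- mag_profiles(calls[0, ], meta, cfg)
  expect_equal(prof0$density, 0)

  prof_mbp <- mag_profiles(calls, meta,
                           pipeline_config(density_unit = "per_mbp"))
  expect_equal(prof_mbp$density, 20.0)

  meta$n_genes <- 0L
  expect_error(mag_profiles(calls, meta, cfg), "n_genes")
})

test_that("density is invariant to joint scaling of genes and CAZymes", {
  m1 <- mag_profiles(make_call(sprintf("p%d", 1:10), "GH3", "M1"),
                     make_mag_meta("M1", n_genes = 500L), cfg)
  m2 <- mag_profiles(make_call(sprintf("p%d", 1:30), "GH3", "M1"),
                     make_mag_meta("M1", n_genes = 1500L), cfg)
  expect_equal(m1$density, m2$density)
})

test_that("class density comparison matches the exact enumeration oracle", {
  prof <- profiles_from_counts(list(Bacteroidia = c(1, 2, 3),
                                    Clostridia = c(10, 11, 12)))
  got <- compare_density_classes(prof, "Bacteroidia", "Clostridia")
  want <- oracle_ranksum_exact(c(1, 2, 3), c(10, 11, 12))
  expect_equal(got$statistic, want$statistic)
  expect_equal(got$p_value, want$p_value)
  expect_equal(got$p_value, 0.1)

  set.seed(5)
  for (i in 1:10) {
    a <- sample(seq(1, 99, 2), sample(3:6, 1))  # odd vs even: no ties,
    b <- sample(seq(2, 100, 2), sample(3:6, 1)) # so the exact path is used
    prof <- profiles_from_counts(list(Bacteroidia = a, Clostridia = b))
    got <- compare_density_classes(prof, "Bacteroidia", "Clostridia")
    want <- oracle_ranksum_exact(a, b)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})

test_that("identical density multisets give a null comparison", {
  prof <- profiles_from_counts(list(Bacteroidia = c(5, 7, 9),
                                    Clostridia = c(5, 7, 9)))
  got <- compare_density_classes(prof, "Bacteroidia", "Clostridia")
  expect_gt(got$p_value, 0.99)
  prof1 <- profiles_from_counts(list(Bacteroidia = c(5, 7), Clostridia = 3))
  expect_error(compare_density_classes(prof1, "Bacteroidia", "Clostridia"),
               "at least 2 MAGs")
})

test_that("Bray-Curtis matches the direct formula and its contracts", {
  meta <- make_mag_meta(c("M1", "M2"), n_genes = 1000L)
  calls <- rbind(make_call("p1", "GH3", "M1"),
                 make_call(c("p2", "p3"), "GH2", "M1"),
                 make_call(c("p4", "p5"), "GH3", "M2"),
                 make_call("p6", "GH2", "M2"))
  prof <- mag_profiles(calls, meta, cfg)
  d <- bray_curtis_matrix(prof, feature = "counts")
  # x = (1, 2), y = (2, 1) -> 2/6 = 1/3
  expect_equal(d["M1", "M2"], 1 / 3)
  expect_equal(oracle_bray(c(1, 2), c(2, 1)), 1 / 3)
  expect_equal(diag(d), c(M1 = 0, M2 = 0))
  expect_equal(d, t(d))

  # identical profiles -> 0; disjoint supports -> 1
  calls_id <- rbind(make_call("p1", "GH3", "M1"), make_call("p2", "GH3", "M2"))
  expect_equal(bray_curtis_matrix(mag_profiles(calls_id, meta, cfg))["M1", "M2"], 0)
  calls_dis <- rbind(make_call("p1", "GH3", "M1"), make_call("p2", "GH2", "M2"))
  expect_equal(bray_curtis_matrix(mag_profiles(calls_dis, meta, cfg))["M1", "M2"], 1)
})

test_that("all-zero profile pairs are flagged NA, not silently 0", {
  meta <- make_mag_meta(c("M1", "M2", "M3"), n_genes = 1000L)
  calls <- make_call("p1", "GH3", "M1")
  prof <- mag_profiles(calls, meta, cfg)
  expect_warning(d <- bray_curtis_matrix(prof), "undefined")
  expect_true(is.na(d["M2", "M3"]))
  expect_equal(d["M1", "M2"], 1)
})

test_that("section summaries match Kruskal-Wallis oracles", {
  ab <- data.frame(sample_id = sprintf("s%d", 1:6),
                   M1 = c(1, 2, 3, 4, 5, 6), stringsAsFactors = FALSE)
  ab$M2 <- 100 - ab$M1
  sm <- data.frame(sample_id = ab$sample_id,
                   fish_id = sprintf("f%d", 1:6),
                   section = rep(c("IV", "V"), each = 3), year = 2017L,
                   assay = "metagenome", stringsAsFactors = FALSE)
  meta <- make_mag_meta(c("M1", "M2"), genus = c("Alistipes", "Rikenella"))
  res <- genus_section_summary(ab, sm, meta)
  a_iv <- res[res$taxon == "Alistipes" & res$section == "IV", ]
  expect_equal(a_iv$mean, 2)
  expect_equal(a_iv$sd, 1)
  h <- oracle_kruskal_h(c(1, 2, 3, 4, 5, 6), rep(c("IV", "V"), each = 3))
  kt <- stats::kruskal.test(ab$M1, factor(sm$section))
  expect_equal(unname(kt$statistic), h)
  expect_equal(unique(res$kw_p[res$taxon == "Alistipes"]), kt$p.value)

  # identical values in both sections -> p = 1
  ab$M1 <- 40; ab$M2 <- 60
  res0 <- genus_section_summary(ab, sm, meta)
  expect_equal(unique(res0$kw_p), 1)
})

test_that("a planted section shift is detected with good power", {
  set.seed(13)
  n_fish <- 6L; reps <- 200L
  hitcount <- 0L
  for (r in seq_len(reps)) {
    iv <- rnorm(n_fish, 40, 6)
    v <- rnorm(n_fish, 55, 6)  # +15 percentage points in section V
    p <- stats::kruskal.test(list(iv, v))$p.value
    if (p < 0.05) hitcount <- hitcount + 1L
  }
  expect_gte(hitcount / reps, 0.8)
})

test_that("pooled enzyme counts sum genes and MAGs per group", {
  meta <- make_mag_meta(c("M1", "M2", "M3"))
  groups <- list(groups = data.frame(group_id = "B1", n_members = 2L,
                                     mean_within_r = 0.9,
                                     section_trend = "stable",
                                     stringsAsFactors = FALSE),
                 members = data.frame(group_id = "B1",
                                      mag_id = c("M1", "M2"),
                                      stringsAsFactors = FALSE))
  calls <- rbind(make_call(c("p1", "p2", "p3"), "GH3", "M1"),
                 make_call("p4", "GH3", "M2"),
                 make_call("p5", "GH150", "M3"))
  pooled <- pool_enzyme_counts(calls, groups, meta, catalog)
  bg <- pooled[pooled$group_id == "B1" &
                 pooled$enzyme_label == "beta-glucosidase", ]
  expect_equal(bg$n_genes, 4L)
  expect_equal(bg$n_mags, 2L)
  expect_equal(bg$weight_class, "LMW")
  ung <- pooled[pooled$group_id == "ungrouped", ]
  expect_equal(ung$n_genes, 1L)
  expect_match(ung$enzyme_label, "carrageenase")
  # no carrageenase inside the group
  expect_false(any(pooled$group_id == "B1" &
                     grepl("carrageenase", pooled$enzyme_label)))
})
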