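test_that("field dataset covers the complete design", {
  fd <- generate_field(field_config(seed = 1))
  expect_equal(sort(unique(fd$variable)),
               sort(c("sand", "silt", "clay", "pH", "SM", "SOC", "DOC",
                      "TN", "TP", "TK", "AP", "AK", "NH4", "NO3",
                      "biomass")))
  # 100 rows per variable: 5 treatments x 10 plots x 2 seasons
  expect_true(all(table(fd$variable) == 100))
  cells <- unique(fd[, c("treatment_cm", "replicate", "season")])
  expect_equal(nrow(cells), 100)
})

test_that("zero noise returns the anchor means exactly", {
  fd <- generate_field(field_config(seed = 1, cv = 0))
  nh4 <- fd[fd$variable == "NH4" & fd$season == "rainy", ]
  mu <- tapply(nh4$value, nh4$treatment_cm, mean)
  expect_equal(unname(mu["0"]), 3.11, tolerance = 1e-12)
  expect_equal(unname(mu["40"]), 3.11 * (1 - 0.2719), tolerance = 1e-12)
  no3 <- fd[fd$variable == "NO3" & fd$season == "dry", ]
  mu3 <- tapply(no3$value, no3$treatment_cm, mean)
  expect_equal(unname(mu3["0"]), 0.27, tolerance = 1e-12)
  expect_equal(unname(mu3["40"]), 0.27 * (1 - 0.7899), tolerance = 1e-12)
})

test_that("sampled group means recover the anchors within Monte-Carlo error", {
  cfg <- field_config(seed = 101)
  fd <- generate_field(cfg)
  nh4 <- fd[fd$variable == "NH4" & fd$season == "rainy" &
              fd$treatment_cm == 0, ]
  se <- 0.15 * 3.11 / sqrt(10)
  expect_lt(abs(mean(nh4$value) - 3.11), 2 * se)
})

test_that("texture closes to 100 percent within every plot-season", {
  fd <- generate_field(field_config(seed = 5))
  tex <- fd[fd$variable %in% c("sand", "silt", "clay"), ]
  sums <- tapply(tex$value, paste(tex$plot_id, tex$season), sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_true(all(fd$value[fd$variable == "clay"] > 0))
})

test_that("configured monotone treatment trends hold in expectation", {
  decl <- c("silt", "SOC", "DOC", "TN", "TP", "AP", "AK", "biomass",
            "NH4", "NO3")
  incr <- c("sand", "TK")
  for (v in decl)
    expect_true(all(diff(treatment_means(v, "rainy")) < 1e-12), info = v)
  for (v in incr)
    expect_true(all(diff(treatment_means(v, "rainy")) > 0), info = v)
})

test_that("generation is bit-reproducible and concentrations non-negative", {
  f1 <- generate_field(field_config(seed = 9))
  f2 <- generate_field(field_config(seed = 9))
  expect_identical(f1, f2)
  expect_true(all(f1$value[f1$variable != "pH"] >= 0))
})

test_that("community tables have the study shape and seasonal turnover", {
  com <- generate_communities(field_config(seed = 2))
  expect_equal(dim(com$AMF$counts), c(100, 10))
  expect_equal(dim(com$nifH$counts), c(100, 20))
  expect_true(all(rowSums(com$AMF$counts) > 0))
  expect_true(all(com$AMF$counts == round(com$AMF$counts)))
  m <- com$AMF$metadata
  dry <- m$season == "dry"
  # dominant rainy AMF genera vanish in the dry season except Diversispora
  expect_true(all(com$AMF$counts[dry, "Glomus"] == 0))
  expect_gt(mean(com$AMF$counts[dry, "Diversispora"] /
                   rowSums(com$AMF$counts[dry, ])), 0.5)
  nm <- com$nifH$metadata
  expect_true(all(com$nifH$counts[nm$season == "dry", "Azospirillum"] == 0))
  expect_true(all(com$nifH$counts[nm$season == "rainy", "Skermanella"] == 0))
  # Bradyrhizobium dominant in both seasons
  rel <- com$nifH$counts / rowSums(com$nifH$counts)
  expect_true(all(tapply(rel[, "Bradyrhizobium"], nm$season, mean) > 0.2))
})

test_that("rainy-season composition is treatment-dependent, dry is not", {
  com <- generate_communities(field_config(seed = 4))
  m <- com$AMF$metadata
  for (s in c("rainy", "dry")) {
    sel <- m$season == s
    d <- bray_curtis(com$AMF$counts[sel, ])
    pv <- permanova(d, m$treatment_cm[sel], n_perm = 199, seed = 10)
    if (s == "rainy") expect_lt(pv$p, 0.05) else expect_gt(pv$p, 0.05)
  }
})

test_that("strong rainy-season shift separates the 0 and 40 cm treatments in most seeds", {
  hits <- 0
  for (seed in 1:10) {
    cfg <- field_config(seed = seed, replicates = 5, amf_tilt = 2)
    com <- generate_communities(cfg)
    m <- com$AMF$metadata
    sel <- m$season == "rainy" & m$treatment_cm %in% c(0, 40)
    d <- bray_curtis(com$AMF$counts[sel, ])
    pv <- permanova(d, m$treatment_cm[sel], n_perm = 199, seed = seed)
    if (pv$p <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("no treatment shift gives a calibrated PERMANOVA null", {
  # type-I behaviour of the generator + test chain at tilt = 0
  rejects <- 0
  n_seeds <- 60
  for (seed in seq_len(n_seeds)) {
    cfg <- field_config(seed = 300 + seed, replicates = 4, amf_tilt = 0)
    com <- generate_communities(cfg)
    m <- com$AMF$metadata
    sel <- m$season == "rainy"
    d <- bray_curtis(com$AMF$counts[sel, ])
    pv <- permanova(d, m$treatment_cm[sel], n_perm = 99, seed = seed)
    if (pv$p <= 0.05) rejects <- rejects + 1
  }
  expect_lte(rejects / n_seeds, 0.15)
})

test_that("the synthetic genus tree is rooted, reproducible and covers the tips", {
  com <- generate_communities(field_config(seed = 6))
  tr <- community_tree(colnames(com$AMF$counts), seed = 8)
  expect_s3_class(tr, "phylo")
  expect_true(ape::is.rooted(tr))
  expect_setequal(tr$tip.label, colnames(com$AMF$counts))
  tr2 <- community_tree(colnames(com$AMF$counts), seed = 8)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
})

test_that("writers emit the tidy CSV and genera-by-samples TSV layouts", {
  dir <- withr::local_tempdir()
  fd <- generate_field(field_config(seed = 1))
  write_field_csv(fd, file.path(dir, "field.csv"))
  back <- read.csv(file.path(dir, "field.csv"))
  expect_equal(nrow(back), nrow(fd))
  com <- generate_communities(field_config(seed = 1))
  write_abundance_tsv(com$AMF, file.path(dir, "amf.tsv"),
                      file.path(dir, "amf_meta.tsv"))
  counts <- read.delim(file.path(dir, "amf.tsv"), check.names = FALSE)
  expect_equal(counts$genus, colnames(com$AMF$counts))
  expect_equal(ncol(counts) - 1, nrow(com$AMF$counts))
})

test_that("invalid generator configurations are rejected", {
  expect_error(field_config(cv = -0.1), ">= 0")
  expect_error(field_config(concentration = 0), "> 0")
  expect_error(field_config(treatments = 0), "incomplete design")
})
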