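test_that("genome annotation honours its construction contract", {
  ann <- tiny_annotation(seed = 1)
  expect_s3_class(ann, "genome_annotation")
  expect_equal(nrow(ann$tads), 10)
  expect_equal(nrow(ann$genes), 100)
  expect_equal(nrow(ann$cres), 500)
  expect_true(all(!is.na(ann$genes$tad_id)))
  expect_true(all(!is.na(ann$cres$tad_id)))
  # TADs tile the chromosome without overlap
  tt <- ann$tads[order(ann$tads$start), ]
  expect_true(all(tt$start < tt$end))
  expect_true(all(tt$start[-1] >= tt$end[-nrow(tt)]))
  expect_true(all(ann$cres$start >= 0 & ann$cres$end <= 1e7))
  expect_true(all(ann$genes$tss >= 0 & ann$genes$tss < 1e7))
})

test_that("a single-TAD genome puts every element in that TAD", {
  ann <- generate_genome_annotation(seed = 2, n_tads = 1, n_genes = 20,
                                    n_cres = 30)
  expect_equal(length(unique(ann$genes$tad_id)), 1)
  expect_identical(unique(ann$cres$tad_id), unique(ann$genes$tad_id))
})

test_that("annotation generation is deterministic and rejects infeasible geometry", {
  expect_identical(tiny_annotation(seed = 7), tiny_annotation(seed = 7))
  expect_false(identical(tiny_annotation(seed = 7), tiny_annotation(seed = 8)))
  expect_error(
    generate_genome_annotation(seed = 1, chromosome_length = 1e5, n_tads = 10,
                               min_tad_width = 5e4),
    "infeasible"
  )
})

test_that("TAD lookup uses half-open membership with right-side boundaries", {
  tads <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 200),
                     tad_id = c("t1", "t2"))
  expect_identical(locate_tad("chr1", c(0, 99, 100, 199, 200), tads),
                   c("t1", "t1", "t2", "t2", NA))
})

test_that("co-culture truth ledger matches the planted design", {
  ann <- tiny_annotation(seed = 3)
  none <- generate_coculture_experiment(ann, seed = 4, planted_fraction = 0)
  expect_equal(nrow(none$truth$differential_cres), 0)
  expect_equal(nrow(none$truth$interactions), 0)

  exp1 <- generate_coculture_experiment(ann, seed = 4, planted_fraction = 0.1)
  expect_equal(nrow(exp1$truth$differential_cres), 50)
  # truth consistency: every interaction joins a CRE and gene in one TAD
  tr <- exp1$truth$interactions
  expect_true(all(tr$tad_id == ann$genes$tad_id[match(tr$gene_id, ann$genes$gene_id)]))
  expect_true(all(tr$tad_id == ann$cres$tad_id[match(tr$cre_id, ann$cres$cre_id)]))
  expect_true(all(tr$cre_id %in% exp1$truth$differential_cres$cre_id))
  # with coupling = 1 every planted gene is targeted by >= 1 planted CRE
  expect_setequal(unique(tr$gene_id), exp1$truth$differential_genes$gene_id)
  # determinism
  exp2 <- generate_coculture_experiment(ann, seed = 4, planted_fraction = 0.1)
  expect_identical(exp1$atac$counts, exp2$atac$counts)
  expect_identical(exp1$rna$counts, exp2$rna$counts)
})

test_that("co-culture counts follow the stated NB moments", {
  ann <- generate_genome_annotation(seed = 5, n_tads = 5, n_genes = 20,
                                    n_cres = 200)
  mu <- 100; alpha <- 0.05; reps <- 50
  exp1 <- generate_coculture_experiment(ann, seed = 6, n_replicates = reps,
                                        baseline_mean = mu, dispersion = alpha,
                                        planted_fraction = 0.1)
  unplanted <- setdiff(rownames(exp1$atac$counts),
                       exp1$truth$differential_cres$cre_id)
  k <- exp1$atac$counts[unplanted, ]
  se <- sqrt((mu + alpha * mu^2) / ncol(k))
  within3 <- abs(rowMeans(k) - mu) <= 3 * se
  expect_gte(mean(within3), 0.99)
  # grand mean pinned down much more tightly
  expect_lt(abs(mean(k) - mu), 3 * se / sqrt(length(unplanted)))
  # variance reflects overdispersion, not Poisson noise
  expect_gt(mean(apply(k, 1, var)), mu * 2)
})

test_that("coupling requires TADs", {
  ann <- tiny_annotation(seed = 3)
  ann$cres$tad_id <- NA_character_
  expect_error(generate_coculture_experiment(ann, seed = 1, coupling = 1),
               "TAD")
})

test_that("patient cohorts respect censoring and effect maps", {
  genes <- sprintf("g%02d", 1:5)
  coh <- generate_patient_cohort(seed = 10, n_patients = 100, genes = genes,
                                 censoring_rate = 0)
  expect_true(all(coh$event == 1))
  expect_error(generate_patient_cohort(seed = 1, n_patients = 50, genes = genes,
                                       censoring_rate = -0.1),
               "censoring_rate")
  expect_error(generate_patient_cohort(seed = 1, n_patients = 50, genes = genes,
                                       log_hazard_effects = c(zz = 1)),
               "listed genes")
  expect_identical(
    generate_patient_cohort(seed = 11, n_patients = 50, genes = genes),
    generate_patient_cohort(seed = 11, n_patients = 50, genes = genes)
  )
})

test_that("a planted hazard effect is recovered by a univariable Cox fit", {
  genes <- c("target", "noise")
  coh <- generate_patient_cohort(seed = 12, n_patients = 5000, genes = genes,
                                 log_hazard_effects = c(target = log(2)),
                                 censoring_rate = 0.2)
  fit <- fit_cox(coh, "target")
  est <- fit$coefficients$log_hr
  se <- fit$coefficients$se
  expect_lt(abs(est - log(2)), 3 * se)
})

test_that("null cohorts show no gene-survival association", {
  genes <- c("g1", "g2")
  ps <- vapply(1:30, function(s) {
    coh <- generate_patient_cohort(seed = 100 + s, n_patients = 120,
                                   genes = genes, censoring_rate = 0.3)
    fit <- fit_cox(coh, "g1")
    fit$coefficients$p
  }, numeric(1))
  # p-values roughly uniform under the null
  expect_lte(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("annotation and counts round-trip through their text formats", {
  ann <- generate_genome_annotation(seed = 20, n_tads = 3, n_genes = 10,
                                    n_cres = 15)
  dir <- withr::local_tempdir()
  write_annotation(ann, dir)
  tads <- read_bed_regions(file.path(dir, "tads.bed"), id_col = "tad_id")
  expect_equal(tads$start, ann$tads$start)
  expect_equal(tads$end, ann$tads$end)
  expect_equal(tads$tad_id, ann$tads$tad_id)

  exp1 <- generate_coculture_experiment(ann, seed = 21, n_replicates = 2)
  write_counts(exp1$atac, file.path(dir, "atac"))
  back <- read_counts(file.path(dir, "atac"))
  expect_equal(back$counts, exp1$atac$counts)
  expect_equal(back$condition, exp1$atac$condition)
})
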