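test_that("noiseless Z-specific and autosomal genes give exactly 0.5 and 1.0", {
  for (e in c(1.6, 1.9, 2.0)) {
    p <- qpcr_panel(c("z1", "a1", "rag1", "mos"),
                    c("target", "target", "reference", "reference"),
                    efficiency = e)
    sim <- noiseless_sim(n_per_sex = 2, panel = p)
    fit <- dose_ratio(sim$cq_table, sim$meta, p, n_bootstrap = 0)
    r <- fit$results
    expect_equal(r$r[r$gene_id == "z1"], 0.5, tolerance = 1e-12)
    expect_equal(r$r[r$gene_id == "a1"], 1.0, tolerance = 1e-12)
  }
})

test_that("a gene unusable in one sex yields a no-result marker, not r = 0", {
  sim <- noiseless_sim(n_per_sex = 2)
  cq <- sim$cq_table
  fem <- grepl("_F", cq$sample_id)
  drop <- fem & cq$gene_id == "z1"
  cq$qc_flag[drop] <- "no_amplification"
  cq$cq[drop] <- NA_real_
  res <- gene_dose_ratio("z1", cq, sim$meta, tiny_panel(), n_bootstrap = 0)
  expect_equal(res$status, "not_tested")
  expect_true(is.na(res$r))
  expect_false(identical(res$r, 0))
})

test_that("per-sample Cq offsets cancel through normalization (scale invariance)", {
  sim <- simulate_cq_table(list(sp = tiny_genome()), tiny_panel(),
                           n_per_sex = 3, noise = noise_model(cq_sd = 0.2),
                           seed = 11)
  base <- suppressWarnings(dose_ratio(sim$cq_table, sim$meta,
                                      tiny_panel(), n_bootstrap = 200,
                                      seed = 5))
  shifted <- sim$cq_table
  for (s in unique(shifted$sample_id)) {
    delta <- runif(1, -3, 3)   # template-amount / pipetting offset
    sel <- shifted$sample_id == s & shifted$qc_flag == "ok"
    shifted$cq[sel] <- shifted$cq[sel] + delta
  }
  shift_fit <- suppressWarnings(dose_ratio(shifted, sim$meta,
                                           tiny_panel(),
                                           n_bootstrap = 200, seed = 5))
  expect_equal(shift_fit$results$r, base$results$r, tolerance = 1e-10)
  expect_equal(shift_fit$results$ci_low, base$results$ci_low,
               tolerance = 1e-10)
  expect_equal(shift_fit$results$ci_high, base$results$ci_high,
               tolerance = 1e-10)
})

test_that("r increases strictly with the female copy number", {
  r_at <- function(cf) {
    g <- genome_model(c(z1 = 4L, a1 = 2L, rag1 = 2L, mos = 2L),
                      c(z1 = cf, a1 = 2L, rag1 = 2L, mos = 2L))
    sim <- simulate_cq_table(list(sp = g), tiny_panel(), n_per_sex = 1,
                             noise = noise_model(), seed = 1)
    gene_dose_ratio("z1", sim$cq_table, sim$meta, tiny_panel(),
                    n_bootstrap = 0)$r
  }
  rs <- vapply(1:4, r_at, 0)
  expect_true(all(diff(rs) > 0))
  expect_equal(rs, (1:4) / 4, tolerance = 1e-12)
})

test_that("bootstrap CI matches an independent naive reimplementation", {
  p <- tiny_panel()
  for (seed in c(2, 9)) {
    sim <- simulate_cq_table(list(sp = tiny_genome()), p, n_per_sex = 3,
                             noise = noise_model(cq_sd = 0.25), seed = seed)
    for (g in c("z1", "a1")) {
      res <- suppressWarnings(
        gene_dose_ratio(g, sim$cq_table, sim$meta, p,
                        n_bootstrap = 500, seed = seed * 100L))
      ora <- oracle_gene_dose_ratio(g, sim$cq_table, sim$meta, p,
                                    B = 500, seed = seed * 100L)
      expect_equal(res$r, ora$r, tolerance = 1e-12)
      expect_equal(c(res$ci_low, res$ci_high), ora$ci, tolerance = 1e-12)
    }
  }
})

test_that("the bootstrap oracle agrees when replicates were dropped by QC", {
  sim <- simulate_cq_table(list(sp = tiny_genome()), tiny_panel(),
                           n_per_sex = 2, noise = noise_model(cq_sd = 0.1),
                           seed = 4)
  cq <- sim$cq_table
  # push one female z1 well out of the spread window and fail one ref well
  i <- which(cq$sample_id == "sp_F1" & cq$gene_id == "z1" &
               cq$replicate == 1)
  cq$cq[i] <- cq$cq[i] + 2
  j <- which(cq$sample_id == "sp_M2" & cq$gene_id == "mos" &
               cq$replicate == 2)
  cq$qc_flag[j] <- "no_amplification"; cq$cq[j] <- NA_real_
  res <- suppressWarnings(
    gene_dose_ratio("z1", cq, sim$meta, tiny_panel(), n_bootstrap = 300,
                    seed = 77))
  ora <- oracle_gene_dose_ratio("z1", cq, sim$meta, tiny_panel(),
                                B = 300, seed = 77)
  expect_equal(res$r, ora$r, tolerance = 1e-12)
  expect_equal(c(res$ci_low, res$ci_high), ora$ci, tolerance = 1e-12)
})

test_that("the fit is reproducible under a fixed seed and reports CI order", {
  sim <- simulate_cq_table(list(sp = tiny_genome()), tiny_panel(),
                           n_per_sex = 3, noise = noise_model(cq_sd = 0.2),
                           seed = 8)
  f1 <- dose_ratio(sim$cq_table, sim$meta, tiny_panel(), n_bootstrap = 300,
                   seed = 42)
  f2 <- dose_ratio(sim$cq_table, sim$meta, tiny_panel(), n_bootstrap = 300,
                   seed = 42)
  expect_identical(f1$results, f2$results)
  ok <- f1$results$status == "ok"
  expect_true(all(f1$results$ci_low[ok] <= f1$results$r[ok]))
  expect_true(all(f1$results$r[ok] <= f1$results$ci_high[ok]))
})

test_that("fit accessors and reference fallback behave", {
  sim <- noiseless_sim(n_per_sex = 2)
  cq <- sim$cq_table
  # knock out mos in one sample: falls back to rag1 with a warning
  sel <- cq$sample_id == "sp_F1" & cq$gene_id == "mos"
  cq$qc_flag[sel] <- "no_amplification"; cq$cq[sel] <- NA_real_
  warns <- capture_warnings(
    fit <- dose_ratio(cq, sim$meta, tiny_panel(), n_bootstrap = 0))
  expect_true(any(grepl("REFERENCE_FALLBACK", warns)))
  expect_equal(unname(coef(fit)["sp:z1"]), 0.5, tolerance = 1e-12)
  expect_equal(dim(confint(fit)), c(2L, 2L))
  expect_s3_class(as.data.frame(fit), "data.frame")
  expect_output(print(fit), "gene-dose ratio fit")
})
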