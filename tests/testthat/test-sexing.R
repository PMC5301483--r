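rrna_panel <- function() {
  qpcr_panel(c("z1", "a1", "rag1", "mos", "rRNA_18S"),
             c("target", "target", "reference", "reference", "rrna"))
}

rrna_sim <- function(mult, n_per_sex = 1, seed = 1, noise = noise_model()) {
  g <- tiny_genome(rrna_mult = mult,
                   extra_male = c(rRNA_18S = 2L),
                   extra_female = c(rRNA_18S = 2L))
  simulate_cq_table(list(sp = g), rrna_panel(), n_per_sex = n_per_sex,
                    noise = noise, seed = seed)
}

test_that("18S ratio recovers the simulated female:male multiplier", {
  for (mult in c(3.43, 18.4)) {
    sim <- rrna_sim(mult)
    rat <- rrna_copy_ratio("sp_F1", "sp_M1", sim$cq_table, rrna_panel(),
                           meta = sim$meta)
    expect_equal(rat$pct_of_male, 100 * mult, tolerance = 1e-9)
    expect_equal(rat$reference_gene, "rag1")
  }
  # a male reference scored against itself sits at exactly 100%
  sim <- rrna_sim(3.43)
  self <- rrna_copy_ratio("sp_M1", "sp_M1", sim$cq_table, rrna_panel(),
                          meta = sim$meta)
  expect_equal(self$pct_of_male, 100, tolerance = 1e-12)
})

test_that("the rRNA assay refuses to run without its rag1 control", {
  sim <- rrna_sim(3.43)
  cq <- sim$cq_table
  sel <- cq$sample_id == "sp_F1" & cq$gene_id == "rag1"
  cq$qc_flag[sel] <- "secondary_product"; cq$cq[sel] <- NA_real_
  expect_error(
    rrna_copy_ratio("sp_F1", "sp_M1", cq, rrna_panel(), meta = sim$meta),
    "RRNA_UNUSABLE")
})

test_that("rRNA sex calls respect thresholds and species reliability", {
  mk_ratio <- function(pct, sp = "A_spinifera")
    data.frame(sample_id = "x", species_id = sp, pct_of_male = pct,
               reference_gene = "rag1", stringsAsFactors = FALSE)
  rel <- data.frame(species_id = c("A_spinifera", "L_p_punctata",
                                   "L_p_andersoni"),
                    reliable = c(TRUE, FALSE, FALSE))
  expect_equal(sex_call_rrna(mk_ratio(343), reliability_table = rel)$call,
               "female")
  expect_equal(sex_call_rrna(mk_ratio(100), reliability_table = rel)$call,
               "male")
  # male-like and intermediate scores in flagged species stay unreliable
  expect_equal(
    sex_call_rrna(mk_ratio(94, "L_p_punctata"), reliability_table = rel)$call,
    "unreliable")
  expect_equal(
    sex_call_rrna(mk_ratio(62, "L_p_andersoni"),
                  reliability_table = rel)$call,
    "unreliable")
  # scores between the male band and the female threshold are unreliable
  expect_equal(sex_call_rrna(mk_ratio(170), reliability_table = rel)$call,
               "unreliable")
  expect_warning(
    out <- sex_call_rrna(mk_ratio(343, "Unknown_sp"),
                         reliability_table = rel),
    "SPECIES_NOT_IN_RELIABILITY_TABLE")
  expect_equal(out$call, "unreliable")
})

test_that("reliability assessment separates W-amplified from flat species", {
  sim_hi <- rrna_sim(5.0, n_per_sex = 2, seed = 3,
                     noise = noise_model(cq_sd = 0.1))
  rel_hi <- assess_rrna_reliability(sim_hi$cq_table, sim_hi$meta,
                                    rrna_panel())
  expect_true(rel_hi$reliable)
  sim_lo <- rrna_sim(0.94, n_per_sex = 2, seed = 3,
                     noise = noise_model(cq_sd = 0.1))
  expect_warning(
    rel_lo <- assess_rrna_reliability(sim_lo$cq_table, sim_lo$meta,
                                      rrna_panel()),
    "RRNA_SPECIES_UNRELIABLE")
  expect_false(rel_lo$reliable)
})

test_that("Z-dosage sexing calls noiseless samples exactly", {
  sim <- noiseless_sim(n_per_sex = 2)
  # female: one Z copy against male references -> relative dose 0.5
  f <- sex_call_zdosage("sp_F1", c("sp_M1", "sp_M2"), "z1",
                        sim$cq_table, tiny_panel())
  expect_equal(f$call, "female")
  expect_equal(f$score, 0.5, tolerance = 1e-12)
  m <- sex_call_zdosage("sp_M1", c("sp_M1", "sp_M2"), "z1",
                        sim$cq_table, tiny_panel())
  expect_equal(m$call, "male")
  expect_equal(m$score, 1.0, tolerance = 1e-12)
  expect_error(
    sex_call_zdosage("sp_F1", c("sp_M1"), character(), sim$cq_table,
                     tiny_panel()),
    "NO_Z_GENES")
})

test_that("intermediate dosage (contaminated sample) is unreliable", {
  g <- genome_model(c(z1 = 4L, a1 = 2L, rag1 = 2L, mos = 2L),
                    c(z1 = 3L, a1 = 2L, rag1 = 2L, mos = 2L))
  sim <- simulate_cq_table(list(sp = g), tiny_panel(), n_per_sex = 1,
                           noise = noise_model(), seed = 1)
  out <- sex_call_zdosage("sp_F1", "sp_M1", "z1", sim$cq_table,
                          tiny_panel())
  expect_equal(out$score, 0.75, tolerance = 1e-12)
  expect_equal(out$call, "unreliable")
})

test_that("Z-dosage sexing is exact across all fixture taxa under plate noise", {
  # 10 animals/sex/species = 200 juveniles; every animal gets a definitive
  # correct call at clean-plate noise, and even at 0.3-cycle noise the
  # assay only ever abstains -- it never missexes
  z_all <- c("anapc7", "ccdc92", "cux2", "ppm1f", "sh2b3", "tmem132d")
  run_all <- function(cq_sd) {
    fx <- suppressWarnings(
      default_trionychid_fixture(seed = 19, n_per_sex = 10, cq_sd = cq_sd))
    reps <- suppressWarnings(zdose:::qc_replicate_sets(fx$cq_table, 2, 0.5))
    out <- character(0); truth <- character(0)
    for (sp in unique(fx$meta$species_id)) {
      m <- fx$meta[fx$meta$species_id == sp, ]
      males <- sort(m$sample_id[m$phenotypic_sex == "male"])[1:3]
      for (s in m$sample_id) {
        out <- c(out, suppressWarnings(
          sex_call_zdosage(s, setdiff(males, s), z_all, reps,
                           fx$panel)$call))
        truth <- c(truth, m$phenotypic_sex[m$sample_id == s])
      }
    }
    list(call = out, truth = truth)
  }
  clean <- run_all(0.1)
  expect_length(clean$call, 200L)
  expect_identical(clean$call, clean$truth)
  noisy <- run_all(0.3)
  definitive <- noisy$call != "unreliable"
  expect_identical(noisy$call[definitive], noisy$truth[definitive])
})

test_that("the two assays never conflict on clean consistent genomes", {
  fx <- default_trionychid_fixture(seed = 5, cq_sd = 0, template_sd = 0,
                                   rrna_jitter_sd = 0)
  fit <- dose_ratio(fx$cq_table, fx$meta, fx$panel, n_bootstrap = 0)
  calls <- classify_linkage(fit)
  sx <- suppressWarnings(
    zdose:::sex_all_samples(fx$cq_table, fx$meta, fx$panel, calls))
  wide <- merge(
    sx$calls[sx$calls$assay == "rrna_cnv", c("sample_id", "call")],
    sx$calls[sx$calls$assay == "z_dosage", c("sample_id", "call")],
    by = "sample_id", suffixes = c("_rrna", "_z"))
  conflict <- wide$call_rrna %in% c("male", "female") &
    wide$call_z %in% c("male", "female") & wide$call_rrna != wide$call_z
  expect_false(any(conflict))
})
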