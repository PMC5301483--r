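# Shared builders and independent oracles for the test suite.

tiny_panel <- function() {
  qpcr_panel(c("z1", "a1", "rag1", "mos"),
             c("target", "target", "reference", "reference"))
}

tiny_genome <- function(rrna_mult = 1, rrna_jitter_sd = 0,
                        extra_male = integer(), extra_female = integer()) {
  cm <- c(z1 = 2L, a1 = 2L, rag1 = 2L, mos = 2L, extra_male)
  cf <- c(z1 = 1L, a1 = 2L, rag1 = 2L, mos = 2L, extra_female)
  genome_model(cm, cf, rrna_w_multiplier = rrna_mult,
               rrna_jitter_sd = rrna_jitter_sd)
}

noiseless_sim <- function(n_per_sex = 1, seed = 1, panel = tiny_panel(),
                          genome = tiny_genome()) {
  simulate_cq_table(list(sp = genome), panel, n_per_sex = n_per_sex,
                    noise = noise_model(), seed = seed)
}

# ---------------------------------------------------------------------------
# Independent naive reimplementation of the dose-ratio estimator and its
# two-stage bootstrap, written with explicit loops. It re-derives replicate
# QC, per-individual doses and the bootstrap distribution from the raw
# table, drawing the same RNG streams in the documented order, so CI
# endpoints must match gene_dose_ratio() exactly.
oracle_gene_dose_ratio <- function(gene, cq_table, meta, panel, B, seed,
                                   min_replicates = 2, max_spread = 0.5) {
  usable_reps <- function(s, g) {
    m <- cq_table[cq_table$sample_id == s & cq_table$gene_id == g, ]
    if (nrow(m) == 0L || any(m$qc_flag == "secondary_product")) return(NULL)
    v <- m$cq[m$qc_flag == "ok"]
    if (length(v)) v <- v[abs(v - median(v)) <= max_spread]
    if (length(v) < min_replicates) return(NULL)
    v
  }
  eff <- function(g) panel$efficiency[panel$gene_id == g]
  refs_all <- sort(panel$gene_id[panel$role == "reference"])
  build <- function(s) {
    tr <- usable_reps(s, gene)
    if (is.null(tr)) return(NULL)
    rr <- list()
    for (g in refs_all) {
      v <- usable_reps(s, g)
      if (!is.null(v)) rr[[g]] <- v
    }
    if (length(rr) == 0L) return(NULL)
    list(target = tr, refs = rr)
  }
  dose_of <- function(ind, t_cq, ref_cqs) {
    q_t <- eff(gene)^(-t_cq)
    logs <- numeric(0)
    for (g in names(ind$refs)) logs <- c(logs, log(eff(g)^(-ref_cqs[[g]])))
    q_t / exp(mean(logs))
  }
  females <- sort(meta$sample_id[meta$phenotypic_sex == "female"])
  males <- sort(meta$sample_id[meta$phenotypic_sex == "male"])
  ind_f <- Filter(Negate(is.null), lapply(females, build))
  ind_m <- Filter(Negate(is.null), lapply(males, build))
  point_dose <- function(ind)
    dose_of(ind, mean(ind$target),
            lapply(ind$refs, mean))
  r_hat <- mean(sapply(ind_f, point_dose)) / mean(sapply(ind_m, point_dose))

  set.seed(as.integer(seed))
  # stream 1: replicate-resampled mean Cqs, females then males,
  # target gene then references alphabetically
  draw_means <- function(v) {
    k <- length(v)
    idx <- matrix(sample.int(k, B * k, replace = TRUE), nrow = B)
    out <- numeric(B)
    for (b in seq_len(B)) out[b] <- mean(v[idx[b, ]])
    out
  }
  boot_doses <- function(ind) {
    mt <- draw_means(ind$target)
    mr <- list()
    for (g in names(ind$refs)) mr[[g]] <- draw_means(ind$refs[[g]])
    out <- numeric(B)
    for (b in seq_len(B))
      out[b] <- dose_of(ind, mt[b], lapply(mr, `[`, b))
    out
  }
  Fd <- lapply(ind_f, boot_doses)
  Md <- lapply(ind_m, boot_doses)
  # stream 2 and 3: individual resampling
  n_f <- length(Fd); n_m <- length(Md)
  idx_f <- matrix(sample.int(n_f, B * n_f, replace = TRUE), nrow = B)
  idx_m <- matrix(sample.int(n_m, B * n_m, replace = TRUE), nrow = B)
  boot_r <- numeric(B)
  for (b in seq_len(B)) {
    mf <- mean(sapply(seq_len(n_f), function(j) Fd[[idx_f[b, j]]][b]))
    mm <- mean(sapply(seq_len(n_m), function(j) Md[[idx_m[b, j]]][b]))
    boot_r[b] <- mf / mm
  }
  list(r = r_hat,
       ci = unname(quantile(boot_r, c(0.025, 0.975))))
}

# ---------------------------------------------------------------------------
# Brute-force small parsimony: minimum number of state changes over all
# assignments of states to internal nodes (and to unknown tips).
brute_force_parsimony <- function(phy, tip_states, states = c("esd", "zw")) {
  n_tip <- length(phy$tip.label)
  n_node <- max(phy$edge)
  free <- c(which(tip_states[phy$tip.label] == "unknown"),
            seq.int(n_tip + 1L, n_node))
  fixed <- setdiff(seq_len(n_tip), free)
  assign_vec <- character(n_node)
  assign_vec[fixed] <- tip_states[phy$tip.label[fixed]]
  best <- Inf
  n_free <- length(free)
  for (code in seq_len(length(states)^n_free) - 1L) {
    x <- code
    for (j in seq_len(n_free)) {
      assign_vec[free[j]] <- states[x %% length(states) + 1L]
      x <- x %/% length(states)
    }
    changes <- sum(assign_vec[phy$edge[, 1L]] != assign_vec[phy$edge[, 2L]])
    if (changes < best) best <- changes
  }
  best
}

# wrap a bare phylo (no meaningful branch lengths) as a dated_tree for
# reconstruction-only tests
dated_from_phylo <- function(phy, tip_states, states = c("esd", "zw")) {
  st <- setNames(rep("unknown", length(phy$tip.label)), phy$tip.label)
  st[names(tip_states)] <- tip_states
  structure(list(phylo = phy, node_ages = rep(NA_real_, max(phy$edge)),
                 tip_states = st, states = states),
            class = "dated_tree")
}

random_tip_states <- function(labels, p_unknown = 0.2,
                              states = c("esd", "zw")) {
  s <- sample(c(states, "unknown"), length(labels), replace = TRUE,
              prob = c(rep((1 - p_unknown) / length(states),
                           length(states)), p_unknown))
  setNames(s, labels)
}
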