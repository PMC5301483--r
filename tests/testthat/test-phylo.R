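test_that("dated Newick parsing converts path lengths to node ages", {
  tr <- parse_dated_newick("((A:120,B:120):80,C:200);")
  expect_equal(max(tr$node_ages), 200)
  expect_equal(sort(unique(tr$node_ages)), c(0, 120, 200))
  expect_equal(tr$node_ages[1:3], c(0, 0, 0))
  # round trip
  tr2 <- parse_dated_newick(as_newick(tr))
  expect_equal(sort(tr2$node_ages), sort(tr$node_ages))

  single <- parse_dated_newick("(A:120);")
  expect_equal(length(single$phylo$tip.label), 1L)

  expect_error(parse_dated_newick("((A:120,B:120):80,C:150);"),
               "ultrametric")
  expect_error(parse_dated_newick("((A:-5,B:120):80,C:200);"), "negative")
  expect_error(parse_dated_newick("((:120,B:120):80,C:200);"), "tip")
  expect_error(
    parse_dated_newick("((A:120,B:120):80,C:200);",
                       tip_states = c(A = "zw", D = "esd")),
    "unknown tip")
  expect_error(
    parse_dated_newick("((A:120,B:120):80,C:200);",
                       tip_states = c(A = "xy")),
    "state space")
})

test_that("Fitch sets follow the intersection/union rule", {
  # two conflicting tips: ambiguous union at their ancestor
  tr <- parse_dated_newick("(A:10,B:10);",
                           tip_states = c(A = "esd", B = "zw"))
  rec <- fitch_ancestral(tr)
  expect_setequal(rec$node_sets[[3]], c("esd", "zw"))
  expect_equal(rec$score, 1L)

  # balanced 4-tip tree, zw,zw vs esd,esd: root ambiguous, one change
  tr4 <- parse_dated_newick(
    "((A:1,B:1):1,(C:1,D:1):1);",
    tip_states = c(A = "zw", B = "zw", C = "esd", D = "esd"))
  rec4 <- fitch_ancestral(tr4)
  expect_setequal(rec4$node_sets[[5]], c("esd", "zw"))
  expect_equal(rec4$score, 1L)
  expect_equal(rec4$score,
               brute_force_parsimony(tr4$phylo, tr4$tip_states))

  # unknown tips contribute the full set and cost nothing
  tru <- parse_dated_newick("((A:1,B:1):1,C:2);",
                            tip_states = c(A = "zw", C = "zw"))
  expect_equal(fitch_ancestral(tru)$score, 0L)
  expect_error(fitch_ancestral(parse_dated_newick("(A:1,B:1);")),
               "unknown")
})

test_that("the trionychid crown node reconstructs as fixed for ZW", {
  tr <- trionychid_fixture_tree()
  rec <- fitch_ancestral(tr)
  crown <- ape::getMRCA(tr$phylo,
                        which(tr$phylo$tip.label != "Carettochelys_insculpta"))
  expect_equal(rec$node_sets[[crown]], "zw")
  root <- length(tr$phylo$tip.label) + 1L
  expect_setequal(rec$node_sets[[root]], c("esd", "zw"))
  expect_equal(rec$score, 1L)
})

test_that("Fitch score equals brute-force minimum on all small topologies", {
  skip_if_not_installed("phangorn")
  for (n in 4:5) {
    trees <- phangorn::allTrees(n, rooted = TRUE,
                                tip.label = LETTERS[1:n])
    for (ti in seq_along(trees)) {
      phy <- trees[[ti]]
      for (code in seq_len(2^n) - 1L) {
        st <- setNames(
          c("esd", "zw")[(code %/% 2^(seq_len(n) - 1L)) %% 2 + 1L],
          LETTERS[1:n])
        dt <- dated_from_phylo(phy, st)
        got <- fitch_ancestral(dt)$score
        expect_identical(got, as.integer(brute_force_parsimony(phy, st)))
      }
    }
  }
})


test_that("Fitch score matches brute force and phangorn on random trees", {
  skip_if_not_installed("phangorn")
  set.seed(99)
  for (i in 1:40) {
    n <- sample(6:8, 1)
    phy <- ape::rtree(n)
    st <- random_tip_states(phy$tip.label)
    if (all(st == "unknown")) next
    dt <- dated_from_phylo(phy, st)
    got <- fitch_ancestral(dt)$score
    expect_identical(got, as.integer(brute_force_parsimony(phy, st)))
    if (all(st != "unknown")) {
      dat <- phangorn::phyDat(matrix(st[phy$tip.label], ncol = 1,
                                     dimnames = list(phy$tip.label, NULL)),
                              type = "USER", levels = c("esd", "zw"))
      expect_equal(got, phangorn::parsimony(phy, dat))
    }
  }
})

test_that("reconstruction is invariant to tip rotation in the Newick", {
  a <- parse_dated_newick("((A:120,B:120):80,C:200);",
                          tip_states = c(A = "zw", B = "zw", C = "esd"))
  b <- parse_dated_newick("(C:200,(B:120,A:120):80);",
                          tip_states = c(A = "zw", B = "zw", C = "esd"))
  oa <- origin_interval(a); ob <- origin_interval(b)
  expect_equal(oa$min_age, ob$min_age)
  expect_equal(oa$max_age, ob$max_age)
  expect_equal(fitch_ancestral(a)$score, fitch_ancestral(b)$score)
})

test_that("origin bracketing returns crown and stem ages", {
  oi <- origin_interval(trionychid_fixture_tree())
  expect_equal(oi$min_age, 120)
  expect_equal(oi$max_age, 200)
  expect_equal(oi$n_derived_tips, 10L)

  oi105 <- origin_interval(trionychid_fixture_tree(crown_age = 105))
  expect_equal(oi105$min_age, 105)
  expect_equal(oi105$max_age, 200)

  # adding more derived tips inside the clade leaves the bracket alone;
  # reducing the crown age lowers only the minimum
  expect_true(oi105$min_age < oi$min_age)
  expect_equal(oi105$max_age, oi$max_age)
})

test_that("degenerate and unbracketable cases are handled", {
  two <- parse_dated_newick("(A:200,B:200);",
                            tip_states = c(A = "zw", B = "esd"))
  expect_warning(oi <- origin_interval(two), "SINGLE_LINEAGE")
  expect_equal(oi$min_age, 0)
  expect_equal(oi$max_age, 200)

  all_zw <- parse_dated_newick("((A:120,B:120):80,C:200);",
                               tip_states = c(A = "zw", B = "zw",
                                              C = "zw"))
  expect_error(origin_interval(all_zw), "root")
  none <- parse_dated_newick("((A:120,B:120):80,C:200);",
                             tip_states = c(A = "esd", B = "esd",
                                            C = "esd"))
  expect_error(origin_interval(none, derived = "zw"), "absent")
})

test_that("Dollo reconstruction forces single gain with losses", {
  # one trionychid reverts: Fitch would allow two equally parsimonious
  # stories; Dollo must keep the crown ZW and count a loss
  tr <- trionychid_fixture_tree()
  st <- tr$tip_states
  st["Chitra_chitra"] <- "esd"
  rec <- fitch_ancestral(tr, tip_states = st, method = "dollo")
  crown <- ape::getMRCA(tr$phylo,
                        which(tr$phylo$tip.label != "Carettochelys_insculpta"))
  expect_equal(rec$node_sets[[crown]], "zw")
  expect_equal(rec$score, 2L)  # one gain + one loss
  expect_error(
    fitch_ancestral(trionychid_fixture_tree(), method = "dollo",
                    derived = "absent_state"),
    "absent")
})
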