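test_that("the nine categories map to the four outcomes", {
  expect_equal(classify_nine("P2_higher", "equal")$outcome, "blending")
  expect_equal(classify_nine("equal", "equal")$outcome, "inheritance")
  expect_equal(classify_nine("P2_higher", "P1_higher")$outcome, "reversal")
  expect_equal(classify_nine("equal", "P1_higher")$outcome, "bias")
  # bijection over all nine state pairs
  states <- c("P2_higher", "P1_higher", "equal")
  grid <- expand.grid(p = states, a = states, stringsAsFactors = FALSE)
  nine <- classify_nine(grid$p, grid$a)
  expect_setequal(nine$nine_category, 1:9)
  expect_equal(unname(table(nine$outcome)[c("inheritance", "blending",
                                            "bias", "reversal")]),
               c(3L, 2L, 2L, 2L), ignore_attr = TRUE)
  expect_error(classify_nine("up", "down"), "states")
})

test_that("outcome proportions tally classified genes", {
  all_eq <- data.frame(gene_id = sprintf("g%d", 1:5),
                       parent_state = "equal", allo_state = "equal",
                       nine_category = 3L, outcome = "inheritance",
                       stringsAsFactors = FALSE)
  expect_equal(unname(outcome_proportions(all_eq)["inheritance"]), 1)
  # 20-gene toy set against a hand tally
  states <- rbind(
    do.call(rbind, replicate(8, c("equal", "equal"), simplify = FALSE)),
    do.call(rbind, replicate(3, c("P2_higher", "P2_higher"),
                             simplify = FALSE)),
    do.call(rbind, replicate(4, c("P1_higher", "equal"), simplify = FALSE)),
    do.call(rbind, replicate(4, c("equal", "P2_higher"), simplify = FALSE)),
    do.call(rbind, replicate(1, c("P1_higher", "P2_higher"),
                             simplify = FALSE)))
  fates <- classify_fates(data.frame(gene_id = sprintf("g%02d", 1:20),
                                     parent_state = states[, 1],
                                     allo_state = states[, 2],
                                     stringsAsFactors = FALSE))
  pr <- outcome_proportions(fates)
  expect_equal(unname(pr), c(11, 4, 4, 1) / 20)
  expect_equal(sum(pr), 1)
})

test_that("dominance bins genes by which parent the allopolyploid matches", {
  ids <- c("dom_high", "dom_low", "inter", "no_parent_de")
  # library totals 1e6 per parent and per allopolyploid side; the combined
  # homeolog RPM is computed over the summed (2e6) assigned total
  pc <- rbind(dom_high = c(100000, 10000), dom_low = c(100000, 10000),
              inter = c(100000, 10000), no_parent_de = c(50000, 50000))
  ac <- rbind(dom_high = c(150000, 50000),  # combined RPM 1e5 = high parent
              dom_low = c(10000, 10000),    # combined RPM 1e4 = low parent
              inter = c(32000, 32000),      # combined RPM 3.2e4: unlike both
              no_parent_de = c(25000, 25000))
  rownames(pc) <- rownames(ac) <- ids
  totp <- c(p1 = 1e6, p2 = 1e6); tota <- c(1e6, 1e6)
  rec <- expression_records(pc, totp, ac, tota)
  dom <- dominance_classify(rec, pc, totp, ac, tota)
  expect_equal(dom$dominance[dom$gene_id == "dom_high"], "dominant_high")
  expect_equal(dom$dominance[dom$gene_id == "dom_low"], "dominant_low")
  expect_equal(dom$dominance[dom$gene_id == "inter"], "intermediate")
  expect_equal(dom$dominance[dom$gene_id == "no_parent_de"],
               "not_applicable")
  expect_equal(dom$high_parent[dom$gene_id == "dom_high"], "P1")
})

test_that("the dominance driver flags the non-dominant homeolog's change", {
  ids <- c("changed", "unchanged")
  pc <- rbind(changed = c(40000, 10000), unchanged = c(40000, 10000))
  # both genes come out dominant_high (combined RPM within 2-fold of the
  # high P1 parent, >= 2-fold above the low P2 parent). 'changed' gets
  # there by silencing the non-dominant P2 homeolog; 'unchanged' keeps
  # both homeologs at parental levels (combined RPM 2.5e4: 1.6-fold below
  # the high parent, 2.5-fold above the low one).
  ac <- rbind(changed = c(79000, 1000), unchanged = c(40000, 10000))
  rownames(pc) <- rownames(ac) <- ids
  totp <- c(p1 = 1e6, p2 = 1e6); tota <- c(1e6, 1e6)
  rec <- expression_records(pc, totp, ac, tota)
  dom <- dominance_classify(rec, pc, totp, ac, tota)
  expect_equal(dom$dominance, c("dominant_high", "dominant_high"))
  expect_equal(dom$driver[dom$gene_id == "changed"], "non_dominant_changed")
  expect_equal(dom$driver[dom$gene_id == "unchanged"],
               "non_dominant_unchanged")
})

test_that("EDE flags require eligibility and extreme expression", {
  cm <- rbind(one_sided = c(100, 0), fold50 = c(200, 3),
              below_min = c(3, 1), ordinary = c(120, 80))
  tot <- c(1e5, 1e5)
  ede <- find_ede(cm, tot)
  expect_equal(unname(ede["one_sided"]), "one_sided")
  expect_equal(unname(ede["fold50"]), "fold50")
  expect_equal(unname(ede["below_min"]), "none")
  expect_equal(unname(ede["ordinary"]), "none")
  # RPM ratio, not raw counts, drives the 50-fold rule
  tot2 <- c(1e5, 2e6)  # P2 library 20x deeper
  ede2 <- find_ede(rbind(g = c(200, 80)), tot2)
  expect_equal(unname(ede2["g"]), "fold50")  # 200/1e5 vs 80/2e6 = 50x
})

test_that("loss candidates count silent homeologs without a read filter", {
  cm <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 250), d = c(5, 5))
  lc <- loss_candidates(cm)
  expect_equal(unname(lc$flag), c("both_silent", "P2_only", "P1_only",
                                  "none"))
  expect_equal(lc$total, 3)
  expect_equal(lc$detection_rate_pct, 75)
})

test_that("EDE clusters are maximal runs with culled genes transparent", {
  coords <- data.frame(gene_id = sprintf("g%d", 1:6),
                       supercontig = "sc1",
                       start = c(0, 100, 200, 300, 400, 500),
                       stringsAsFactors = FALSE)
  # [EDE, EDE, non, EDE, ...] -> one cluster of 2
  flags <- setNames(c("one_sided", "fold50", "none", "one_sided", "none",
                      "none"), coords$gene_id)
  cl <- cluster_ede(coords, flags)
  expect_equal(cl$n_clustered, 2)
  expect_equal(sort(cl$clusters$gene_id), c("g1", "g2"))
  # [EDE, culled, EDE]: the culled gene does not break the run
  flags2 <- setNames(c("one_sided", "none", "one_sided", "none", "none",
                       "none"), coords$gene_id)
  retained <- setdiff(coords$gene_id, "g2")
  flags2 <- flags2[retained]
  cl2 <- cluster_ede(coords, flags2, retained)
  expect_equal(sort(cl2$clusters$gene_id), c("g1", "g3"))
  expect_equal(cl2$clustered_fraction_pct, 100)
  # no EDE genes: empty list
  none <- setNames(rep("none", 6), coords$gene_id)
  expect_equal(nrow(cluster_ede(coords, none)$clusters), 0)
})

test_that("log-ratio export pseudocounts zeros and keeps orientation", {
  pc <- rbind(g1 = c(100, 400), g2 = c(50, 50))
  ac <- rbind(g1 = c(200, 0), g2 = c(50, 50))
  lr <- log_ratio_table(pc, c(1e6, 1e6), ac, c(1e6, 1e6))
  expect_equal(lr$parent_log2[1], log2(400.5 / 100.5))
  expect_equal(lr$allo_log2[1], log2(0.5 / 200.5))   # finite despite zero
  expect_equal(lr$allo_log2[2], 0)
  expect_equal(lr$p1_copy_log2[1], log2(200.5 / 100.5))
})

test_that("independence proportions follow the chosen treatment", {
  counts <- c(biased_inheritance = 10, bias = 5, blending = 10,
              unbiased = 75)
  ex <- independence_proportions(counts, "exclude_unbiased")
  expect_equal(c(ex$full, ex$partial, ex$none), c(0.40, 0.20, 0.40))
  ni <- independence_proportions(counts, "unbiased_as_nonindependent")
  expect_equal(c(ni$full, ni$partial, ni$none), c(0.10, 0.05, 0.85))
  ii <- independence_proportions(counts, "unbiased_as_independent")
  expect_equal(c(ii$full, ii$partial, ii$none), c(0.85, 0.05, 0.10))
  # all bias/blending empty: any biased-inheritance gene means full = 1
  only_full <- c(biased_inheritance = 3, bias = 0, blending = 0,
                 unbiased = 50)
  expect_equal(independence_proportions(only_full, "exclude_unbiased")$full,
               1)
  # table input agrees with count input
  fates <- classify_fates(data.frame(
    gene_id = sprintf("g%03d", 1:100),
    parent_state = c(rep("P2_higher", 10), rep("P2_higher", 10),
                     rep("equal", 5), rep("equal", 75)),
    allo_state = c(rep("P2_higher", 10), rep("equal", 10),
                   rep("P2_higher", 5), rep("equal", 75)),
    stringsAsFactors = FALSE))
  ex2 <- independence_proportions(fates, "exclude_unbiased")
  expect_equal(c(ex2$full, ex2$partial, ex2$none), c(0.40, 0.20, 0.40))
})
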