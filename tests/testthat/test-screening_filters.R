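test_that("screen_samples partitions by anchor call state", {
  # 6 samples with anchor states D,D,A,A,M,AMBIG
  gm <- make_gm(matrix(c("D", "D", "A", "A", "M", "?"), 6, 1),
                names = "ANCH")
  scr <- screen_samples(gm, "ANCH")
  expect_setequal(scr$cases, c("s01", "s02"))
  expect_setequal(scr$controls, c("s03", "s04"))
  expect_setequal(scr$excluded, c("s05", "s06"))
  expect_length(c(scr$cases, scr$controls, scr$excluded), 6)

  # all samples derived at the anchor -> controls empty, warning
  gm2 <- make_gm(matrix("D", 4, 1), names = "ANCH")
  expect_warning(screen_samples(gm2, "ANCH"), "vacuous")
  expect_error(screen_samples(gm, "NOPE"), "not found")
})

test_that("noiseless screening recovers the simulated case cohort", {
  ds <- simulate_dataset(noiseless_config(31))
  scr <- screen_samples(ds$gm, "L11")
  expect_setequal(scr$cases, ds$truth$case_samples)
  expect_setequal(scr$controls, ds$truth$control_samples)
  expect_length(scr$excluded, 0)
})

test_that("F1 fails on any observed derived control; unobserved controls are uninformative", {
  # variant 2: one control derived among nine ancestral -> fail
  # variant 3: all controls missing -> vacuous pass with annotation
  ext <- cbind(c(rep("D", 2), rep("A", 10)),
               c(rep("D", 2), "D", rep("A", 9)),
               c(rep("D", 2), rep("M", 10)))
  gm <- make_anchored_gm(ext, n_case = 2, n_ctrl = 10)
  scr <- screen_samples(gm, "ANCH")
  f1 <- filter_control_ancestral(gm, scr)
  expect_equal(unname(f1[-1]), c(TRUE, FALSE, TRUE))
  expect_equal(unname(attr(f1, "no_informative_controls")[-1]),
               c(FALSE, FALSE, TRUE))
  fr <- run_filters(gm, scr)
  expect_equal(fr$table$outcome[3], "FAIL_CONTROL_DERIVED")
  expect_equal(fr$table$annotation[4], "no informative controls")
})

test_that("F2 boundary: one derived case fails, two pass; ambiguous never counts", {
  ext <- cbind(c("D", "A", "A", rep("A", 3)),
               c("D", "D", "A", rep("A", 3)),
               c("D", "?", "A", rep("A", 3)))
  gm <- make_anchored_gm(ext, n_case = 3, n_ctrl = 3)
  scr <- screen_samples(gm, "ANCH")
  f2 <- filter_non_singleton(gm, scr)
  expect_equal(unname(f2[-1]), c(FALSE, TRUE, FALSE))
  expect_equal(unname(attr(f2, "n_derived_cases")[-1]), c(1, 2, 1))
})

test_that("F3 counts ambiguous calls against the configured maximum", {
  ext <- cbind(c("D", "D", "?", "A"), c("D", "D", "A", "A"),
               c("?", "?", "D", "A"))
  gm <- make_anchored_gm(ext, n_case = 3, n_ctrl = 1)
  scr <- screen_samples(gm, "ANCH")
  expect_equal(unname(filter_ambiguous(gm, scr, 0)[-1]),
               c(FALSE, TRUE, FALSE))
  expect_equal(unname(filter_ambiguous(gm, scr, 2)[-1]),
               c(TRUE, TRUE, TRUE))
  expect_equal(unname(filter_ambiguous(gm, scr, 1)[-1]),
               c(TRUE, TRUE, FALSE))
})

test_that("compatible implements the rooted gamete test", {
  all_s <- c("a", "b", "c", "d")
  expect_true(compatible(c("a", "b"), c("a", "b", "c"), all_s))   # nested
  expect_true(compatible(c("a", "b"), c("c", "d"), all_s))        # disjoint
  expect_false(compatible(c("a", "b"), c("b", "c"), all_s))       # 3 gametes
  # restriction to jointly observed can rescue a conflict
  expect_true(compatible(c("a", "b"), c("b", "c"), c("a", "b", "d")))
})

test_that("F4 removes exactly the recurrent artefact in a crafted conflict", {
  # v1 on parent branch {a,b,c,d}; v2 on child {a,b}; artefact {a,b,e,f}
  # (child's carriers plus a disjoint branch): conflicts with v1 only among
  # mutually compatible others -> artefact removed
  ext <- cbind(c("D", "D", "D", "D", "A", "A", rep("A", 2)),
               c("D", "D", "A", "A", "A", "A", rep("A", 2)),
               c("D", "D", "A", "A", "D", "D", rep("A", 2)))
  gm <- make_anchored_gm(ext, n_case = 6, n_ctrl = 2,
                         names = c("V1", "V2", "ART"))
  scr <- screen_samples(gm, "ANCH")
  fr <- run_filters(gm, scr)
  out <- stats::setNames(fr$table$outcome,
                         fr$gm$variants$name[match(fr$table$id,
                                                   fr$gm$variants$id)])
  expect_equal(unname(out[c("V1", "V2")]), c("RETAINED", "RETAINED"))
  expect_equal(unname(out["ART"]), "FAIL_INCONSISTENT")
  expect_match(fr$table$conflict_partners[fr$table$outcome ==
                                            "FAIL_INCONSISTENT"], ".")
  expect_gt(nrow(fr$edges), 0)
})

test_that("noiseless cascade recovers all truth classes across seeds", {
  for (s in c(41, 42, 43)) {
    cfg <- noiseless_config(s, recurrent_count = 3)
    ds <- simulate_dataset(cfg)
    scr <- screen_samples(ds$gm, "L11")
    fr <- run_filters(ds$gm, scr)
    tab <- fr$table
    expect_setequal(tab$id[tab$outcome == "FAIL_SINGLETON"],
                    names(ds$truth$singleton_variants))
    expect_setequal(tab$id[tab$outcome == "FAIL_INCONSISTENT"],
                    names(ds$truth$artefact_variants))
    expect_setequal(setdiff(fr$retained, ds$truth$anchor_id),
                    unlist(ds$truth$branch_variants))
  }
})

test_that("cascade accounting and order invariance hold", {
  ds <- simulate_dataset(sim_config(seed = 44))
  scr <- screen_samples(ds$gm, "L11")
  fr <- run_filters(ds$gm, scr)
  expect_equal(sum(table(fr$table$outcome)), nrow(ds$gm$variants))

  # permute variant and sample order: outcomes identical per variant id
  set.seed(1)
  pv <- sample(ncol(ds$gm$calls))
  ps <- sample(nrow(ds$gm$calls))
  gm2 <- genotype_matrix(ds$gm$calls[ps, pv], ds$gm$variants[pv, ],
                         ds$gm$samples[ps, ])
  fr2 <- run_filters(gm2, screen_samples(gm2, "L11"))
  m <- match(fr$table$id, fr2$table$id)
  expect_equal(fr$table$outcome, fr2$table$outcome[m])
  expect_equal(fr$table$conflict_partners, fr2$table$conflict_partners[m])
})

test_that("missingness cannot rescue a variant whose derived control stays observed", {
  ext <- cbind(c("D", "D", "A", "D", "A", "A"))
  gm <- make_anchored_gm(ext, n_case = 3, n_ctrl = 3)
  scr <- screen_samples(gm, "ANCH")
  fr <- run_filters(gm, scr)
  expect_equal(fr$table$outcome[2], "FAIL_CONTROL_DERIVED")
  # degrade every other observation to MISSING; the offending control call
  # remains observed -> still fails
  gm2 <- gm
  gm2$calls[c(2, 5, 6), 2] <- CALL_STATES[["MISSING"]]
  fr2 <- run_filters(gm2, scr)
  expect_equal(fr2$table$outcome[2], "FAIL_CONTROL_DERIVED")
})

test_that("control-majority orientation flips sites and flags ties UNUSABLE", {
  # variant 2: controls mostly derived as read -> flipped; variant 3: tie
  ext <- cbind(c("A", "A", "D", "D", "D"),
               c("D", "D", "D", "A", "A"))   # controls: 2 D vs 2 A = tie
  gm <- make_anchored_gm(ext, n_case = 1, n_ctrl = 4)
  scr <- screen_samples(gm, "ANCH")
  o <- orient_by_controls(gm, scr)
  # variant 2 (col 2): controls 3 D vs 1 A? columns: col2 = ext[,1]
  expect_equal(unname(o$gm$calls[, 2]),
               unname(CALL_STATES[c("DERIVED", "DERIVED", "ANCESTRAL",
                                    "ANCESTRAL", "ANCESTRAL")]))
  expect_equal(o$gm$variants$ancestral[2], "T")   # alleles swapped
  expect_equal(o$unusable, gm$variants$id[3])     # 2 D vs 2 A tie
  fr <- run_filters(gm, scr, orientation = "control-majority")
  expect_equal(fr$table$outcome[3], "UNUSABLE")
})

test_that("annotate_novelty keys on (contig, position, derived)", {
  gm <- make_gm(matrix("D", 2, 3), positions = c(100L, 200L, 300L))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tcontig\tposition\tderived",
               "DF27\tchrY\t100\tT",      # match
               "Z225\tchrY\t200\tG"), p)  # same position, wrong allele
  v <- annotate_novelty(gm$variants, read_known_list(p))
  expect_equal(v$known, c(TRUE, FALSE, FALSE))
  expect_equal(v$name[1], "DF27")
})

test_that("pre-seeding 4 of the branch variants leaves the rest novel", {
  ds <- simulate_dataset(noiseless_config(45))
  branch_ids <- unlist(ds$truth$branch_variants)
  seeded <- branch_ids[1:4]
  v <- ds$gm$variants[match(seeded, ds$gm$variants$id), ]
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tcontig\tposition\tderived",
               sprintf("KN%d\t%s\t%d\t%s", seq_len(4), v$contig, v$position,
                       v$derived)), p)
  ann <- annotate_novelty(ds$gm$variants, read_known_list(p))
  in_branch <- ann$id %in% branch_ids
  expect_equal(sum(ann$known[in_branch]), 4)
  expect_equal(sum(!ann$known[in_branch]), length(branch_ids) - 4)
})
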