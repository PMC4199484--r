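test_that("toy universes are deterministic per seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_toy_universe(make_toy_universe(1), d1)
  write_toy_universe(make_toy_universe(1), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  u3 <- make_toy_universe(3)
  expect_false(identical(make_toy_universe(1)$blast, u3$blast))
})

test_that("planted evidence reaches its likelihood targets within 0.05", {
  for (seed in c(1, 7, 23)) {
    u <- make_toy_universe(seed)
    p <- stats::setNames(u$rxn_lik$likelihood, u$rxn_lik$reaction_id)
    err <- abs(p[u$planted$reaction_id] - u$planted$target_p)
    expect_lt(max(err), 0.05)
    # the long path is strong, the short path has no evidence at all
    expect_true(all(p[c("L1", "L2", "L3", "L4")] >= 0.8))
    expect_false(any(c("S1", "S2") %in% u$rxn_lik$reaction_id[
      u$rxn_lik$likelihood > 0]))
    # gold model grows on its media
    fba <- run_fba(apply_media(u$gold_model, u$gold_media))
    expect_gt(fba$objective_value, 1e-9)
    # every gold reaction exists in the universal database
    expect_true(all(u$gold_model$reactions$id %in% u$universal$reactions$id))
  }
})

test_that("the universe exercises penalties and priority classes", {
  u <- make_toy_universe(1)
  r <- u$universal$reactions
  expect_true(any(r$is_transporter))
  expect_true(any(!is.na(r$delta_g) & r$delta_g > 0))
  expect_true(any(r$source_confidence == "low"))
  expect_true(all(c("central", "biosynthesis", "peripheral") %in%
                    r$priority_class))
})

test_that("draft construction respects the inclusion threshold", {
  u <- make_toy_universe(1)
  expect_error(make_draft_model(u$universal, u$rxn_lik, 1.1), "validation")
  expect_error(make_draft_model(u$universal, u$rxn_lik, -0.1), "validation")
  # threshold 0: every gene-associated universal reaction
  d0 <- make_draft_model(u$universal, u$rxn_lik, 0)
  assoc <- u$rxn_lik$reaction_id[nzchar(u$rxn_lik$gpr)]
  expect_true(all(assoc %in% d0$reactions$id))
  # threshold 0.5 excludes the zero-evidence short path and the
  # moderate-evidence distractors
  d5 <- make_draft_model(u$universal, u$rxn_lik, 0.5)
  expect_false(any(c("S1", "S2") %in% d5$reactions$id))
  expect_false(any(grepl("^DGN", d5$reactions$id)))
  expect_true(all(c("L1", "L2", "L3", "L4", "R1", "R2", "R3", "bio1") %in%
                    d5$reactions$id))
  # included transporters bring their exchange reactions
  expect_true(all(c("EX_glc_e", "EX_nh4_e") %in% d5$reactions$id))
})

test_that("removing the long path breaks biomass until gap filled", {
  u <- make_toy_universe(1)
  draft <- remove_reactions(u$gold_model, c("L1", "L2", "L3", "L4"))
  fba <- run_fba(apply_media(draft, complete_media(draft)))
  expect_lt(fba$objective_value, 1e-9)
  sol <- gapfill_target(draft, u$universal,
                        compute_costs(u$universal, draft, u$rxn_lik),
                        "bio1", complete_media(draft))
  expect_true(all(c("L1", "L2", "L3", "L4") %in% sol$added$reaction_id))
})

test_that("gap-filling instances stay within the enumeration budget", {
  for (seed in 1:5) {
    inst <- make_gapfill_instance(seed)
    costs <- compute_costs(inst$universal, inst$draft, NULL)
    expect_lte(nrow(costs), 12)
    expect_true(all(costs$cost >= 0))
    expect_identical(inst$draft$biomass_reaction_id, "SINK")
  }
})
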