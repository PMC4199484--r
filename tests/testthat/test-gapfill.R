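toy <- make_toy_universe(1)

test_that("cost assignment follows the penalty scheme", {
  u <- toy$universal
  draft <- remove_reactions(toy$gold_model, c("L1", "L2", "L3", "L4"))
  pc <- compute_costs(u, draft, NULL)
  cl <- compute_costs(u, draft, toy$rxn_lik)
  get <- function(costs, id, dir = "forward")
    costs$cost[costs$reaction_id == id & costs$direction == dir &
                 costs$kind == "addition"]
  # p = 0 intracellular favorable: lambda = 1 in both modes
  expect_equal(get(pc, "S1"), 1)
  expect_equal(get(cl, "S1"), 1)
  # p = 0.9 intracellular favorable, likelihood mode: 0.1
  expect_equal(get(cl, "L1"), 0.1, tolerance = 1e-9)
  expect_equal(get(pc, "L1"), 1)
  # p = 0 transporter: 1 + 25 = 26
  expect_equal(get(pc, "T_wex"), 26)
  expect_equal(get(cl, "T_wex"), 26)
  # unfavorable direction, dG = +10: surcharge (12 + 2*10)/10 = 3.2,
  # never likelihood-scaled
  expect_equal(get(pc, "U_unfav"), 1 + 3.2)
  expect_equal(get(cl, "U_unfav"), 1 + 3.2)
  # same reaction backwards is favorable (dG = -10): base cost only
  expect_equal(get(pc, "U_unfav", "reverse"), 1)
  # low-confidence source: 1 + 5 (forward is favorable at dG = -1)
  expect_equal(get(pc, "U_low"), 6)
  # reversibility change of an existing reaction: 12 * U/1.2, identical
  # across modes; R1 has dG = -5, so its reverse has dG_dir = +5 and
  # U = (12 + 10)/10 = 2.2 -> cost 22
  grev <- function(costs, id)
    costs$cost[costs$reaction_id == id & costs$kind == "reversal"]
  expect_equal(grev(pc, "R1"), 12 * 2.2 / 1.2)
  expect_equal(grev(cl, "R1"), 12 * 2.2 / 1.2)
  # likelihood mode without likelihoods is a usage error
  expect_error(compute_costs(u, draft, NULL, mode = "likelihood"),
               "usage error")
})

test_that("two-pathway fixture: parsimony picks short, likelihood long", {
  draft <- remove_reactions(toy$gold_model, c("L1", "L2", "L3", "L4"))
  cm <- complete_media(draft)
  sp <- gapfill_target(draft, toy$universal,
                       compute_costs(toy$universal, draft, NULL),
                       "bio1", cm)
  expect_equal(sp$objective_value, 2, tolerance = 1e-6)
  expect_identical(sort(sp$added$reaction_id), c("S1", "S2"))
  sl <- gapfill_target(draft, toy$universal,
                       compute_costs(toy$universal, draft, toy$rxn_lik),
                       "bio1", cm)
  expect_equal(sl$objective_value, 0.4, tolerance = 1e-6)
  expect_identical(sort(sl$added$reaction_id), c("L1", "L2", "L3", "L4"))
  # objective equals the sum of per-item costs
  expect_equal(sp$objective_value,
               sum(sp$added$cost) + sum(sp$reversed$cost), tolerance = 1e-6)
  expect_equal(sl$objective_value,
               sum(sl$added$cost) + sum(sl$reversed$cost), tolerance = 1e-6)
  # integration activates biomass in both cases
  mp <- integrate_solution(draft, sp)
  ml <- integrate_solution(draft, sl, toy$rxn_lik)
  expect_gte(run_fba(apply_media(mp, cm))$objective_value, 1e-9)
  expect_gte(run_fba(apply_media(ml, cm))$objective_value, 1e-9)
  # likelihood integration carries candidate GPRs; parsimony leaves
  # them empty until post-processing
  expect_identical(ml$reactions$gpr[ml$reactions$id == "L1"], "g_l1")
  expect_identical(mp$reactions$gpr[mp$reactions$id == "S1"], "")
  mp2 <- attach_candidate_gprs(mp, toy$rxn_lik)
  expect_identical(mp2$reactions$gpr[mp2$reactions$id == "S1"], "")  # p = 0
  expect_false("L1" %in% mp$reactions$id)
})

test_that("active targets and impossible targets are handled", {
  cm <- complete_media(toy$gold_model)
  costs <- compute_costs(toy$universal, toy$gold_model, NULL)
  sol <- gapfill_target(toy$gold_model, toy$universal, costs, "bio1", cm)
  expect_equal(sol$objective_value, 0)
  expect_equal(nrow(sol$added), 0)
  expect_true(models_equal(integrate_solution(toy$gold_model, sol),
                           toy$gold_model))
  # a target whose product has no sink anywhere in the universe
  draft <- make_draft_model(toy$universal, toy$rxn_lik, 0.2)
  rnd <- grep("^RND", draft$reactions$id, value = TRUE)
  expect_length(rnd, 1)
  expect_error(
    gapfill_target(draft, toy$universal,
                   compute_costs(toy$universal, draft, NULL), rnd, cm),
    "infeasibility error")
})

test_that("MILP agrees with the exhaustive reachability oracle", {
  for (seed in 1:8) {
    inst <- make_gapfill_instance(seed)
    for (mode_lik in c(FALSE, TRUE)) {
      costs <- compute_costs(inst$universal, inst$draft,
                             if (mode_lik) inst$rxn_lik)
      expect_lte(nrow(costs), 12)
      oracle <- oracle_gapfill_mincost(inst, costs)
      sol <- tryCatch(
        gapfill_target(inst$draft, inst$universal, costs, inst$target,
                       inst$media),
        error = function(e) e)
      if (oracle$feasible) {
        expect_false(inherits(sol, "error"))
        expect_equal(sol$objective_value, oracle$objective,
                     tolerance = 1e-6,
                     label = sprintf("seed %d lik %d", seed, mode_lik))
      } else {
        expect_true(inherits(sol, "error"))
        expect_match(conditionMessage(sol), "infeasibility")
      }
    }
  }
})

test_that("likelihood mode degenerates to parsimony when all p = 0", {
  inst <- make_gapfill_instance(5)
  zero_lik <- inst$rxn_lik
  zero_lik$likelihood <- 0
  cp <- compute_costs(inst$universal, inst$draft, NULL)
  cl <- compute_costs(inst$universal, inst$draft, zero_lik)
  expect_equal(cl$cost, cp$cost)
  sp <- gapfill_target(inst$draft, inst$universal, cp, inst$target, inst$media)
  sl <- gapfill_target(inst$draft, inst$universal, cl, inst$target, inst$media)
  expect_equal(sp$objective_value, sl$objective_value, tolerance = 1e-9)
})

test_that("raising a pathway's likelihoods never raises its cost", {
  draft <- remove_reactions(toy$gold_model, c("L1", "L2", "L3", "L4"))
  cm <- complete_media(draft)
  lift <- toy$rxn_lik
  sel <- lift$reaction_id %in% c("L1", "L2", "L3", "L4")
  lift$likelihood[sel] <- 0.95
  s1 <- gapfill_target(draft, toy$universal,
                       compute_costs(toy$universal, draft, toy$rxn_lik),
                       "bio1", cm)
  s2 <- gapfill_target(draft, toy$universal,
                       compute_costs(toy$universal, draft, lift),
                       "bio1", cm)
  expect_lte(s2$objective_value, s1$objective_value + 1e-9)
})

test_that("complete media lists exactly the transported compounds", {
  cm <- complete_media(toy$gold_model)
  expect_identical(names(cm$uptake_limits), c("glc_e", "nh4_e", "zsub_e"))
  expect_true(all(cm$uptake_limits == 100))
  # no transporters: empty media
  m <- linear_model()
  m$reactions$is_transporter <- FALSE
  m2 <- remove_reactions(m, "T_A")
  expect_length(complete_media(m2)$uptake_limits, 0)
})

test_that("the time-limit escalation schedule doubles up to t_max", {
  draft <- remove_reactions(toy$gold_model, c("L1", "L2", "L3", "L4"))
  cm <- complete_media(draft)
  costs <- compute_costs(toy$universal, draft, NULL)
  # a time limit of 0 can never complete; the schedule must double past
  # t_max and throw the timeout error rather than loop forever
  expect_error(
    gapfill_target(draft, toy$universal, costs, "bio1", cm,
                   time_limit = 0, t_max = 0),
    "timeout error")
})
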