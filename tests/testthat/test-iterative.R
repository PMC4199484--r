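test_that("targets are ordered by priority class then id", {
  m <- make_toy_universe(1)$universal
  expect_identical(order_targets(m, c("PZ", "R1", "L1")),
                   c("R1", "L1", "PZ"))
  expect_identical(order_targets(m, c("L2", "L1")), c("L1", "L2"))
  expect_identical(order_targets(m, character()), character())
})

test_that("iterative gap filling activates fillable targets, logs failures", {
  u <- make_toy_universe(2)
  draft <- make_draft_model(u$universal, u$rxn_lik, 0.2)
  cm <- complete_media(draft)
  costs <- compute_costs(u$universal, draft, u$rxn_lik)
  sol0 <- gapfill_target(draft, u$universal, costs, "bio1", cm)
  m0 <- integrate_solution(draft, sol0, u$rxn_lik)
  before_active <- setdiff(m0$reactions$id,
                           find_inactive_reactions(m0, cm))
  it <- iterative_gapfill(m0, u$universal,
                          compute_costs(u$universal, m0, u$rxn_lik), cm)
  ok <- Filter(function(s) !isTRUE(s$failed), it$solutions)
  failed <- Filter(function(s) isTRUE(s$failed), it$solutions)
  # the three degradation targets get secretion routes; the
  # disconnected distractor cannot be filled and is recorded failed
  expect_identical(sort(vapply(ok, `[[`, character(1), "target")),
                   c("DGN1", "DGN2", "DGN3"))
  expect_length(failed, 1)
  expect_match(failed[[1]]$target, "^RND")
  inact <- find_inactive_reactions(it$model, cm, gene_associated_only = TRUE)
  expect_identical(inact, failed[[1]]$target)
  # activation is monotone: previously active reactions stay active
  after_active <- setdiff(it$model$reactions$id,
                          find_inactive_reactions(it$model, cm))
  expect_true(all(before_active %in% after_active))
  # idempotence: a second pass adds nothing
  it2 <- iterative_gapfill(it$model, u$universal,
                           compute_costs(u$universal, it$model, u$rxn_lik), cm)
  expect_length(Filter(function(s) !isTRUE(s$failed), it2$solutions), 0)
  # no inactive targets at all: unchanged model, empty solution list
  it3 <- iterative_gapfill(u$gold_model, u$universal,
                           compute_costs(u$universal, u$gold_model, NULL),
                           complete_media(u$gold_model))
  expect_length(it3$solutions, 0)
  expect_true(models_equal(it3$model, u$gold_model))
})

# model whose biomass runs through one essential gap-filled reaction and
# one pair of mutually redundant gap-filled duplicates
redundant_model <- function() {
  mets <- data.frame(id = c("A_e", "A_c", "B_c"),
                     name = c("A_e", "A_c", "B_c"),
                     compartment = c("e", "c", "c"), stringsAsFactors = FALSE)
  rxns <- data.frame(id = "EX_A_e", lower_bound = -100, upper_bound = 100,
                     stringsAsFactors = FALSE)
  st <- list(EX_A_e = c(A_e = -1))
  m <- new_model("redundant", mets,
                 rbind(rxns, data.frame(id = "bio", lower_bound = 0,
                                        upper_bound = 100)),
                 c(st, list(bio = c(B_c = -1))), "bio")
  m <- add_reaction(m, "T_A", c(A_e = -1, A_c = 1), 0, 100)   # essential fill
  m <- add_reaction(m, "dup1", c(A_c = -1, B_c = 1), 0, 100)  # redundant pair
  m <- add_reaction(m, "dup2", c(A_c = -1, B_c = 1), 0, 100)
  m
}

test_that("sensitivity classifies essential, activating and redundant fills", {
  m <- redundant_model()
  media <- new_media("mA", c(A_e = 10))
  rep <- reaction_sensitivity(m, c("T_A", "dup1", "dup2"), "parsimony", media)
  # parsimony order: reverse of addition order
  expect_identical(rep$reaction_id, c("dup2", "dup1", "T_A"))
  expect_true(rep$essential[rep$reaction_id == "T_A"])
  expect_false(rep$non_contributing[rep$reaction_id == "T_A"])
  # each duplicate alone is non-contributing (the other covers it)
  expect_true(all(rep$non_contributing[rep$reaction_id %in% c("dup1", "dup2")]))
  # likelihood mode processes lowest likelihood first
  gf <- data.frame(reaction_id = c("dup1", "dup2"), kind = "addition",
                   likelihood = c(0.9, 0.1), order = 1:2)
  rep2 <- reaction_sensitivity(m, gf, "likelihood", media)
  expect_identical(rep2$reaction_id, c("dup2", "dup1"))
  expect_error(reaction_sensitivity(m, "ghost", "parsimony", media),
               "not in model")
})

test_that("a removed gap fill that inactivates other reactions is contributing", {
  u <- make_toy_universe(2)
  draft <- make_draft_model(u$universal, u$rxn_lik, 0.2)
  cm <- complete_media(draft)
  it <- iterative_gapfill(draft, u$universal,
                          compute_costs(u$universal, draft, u$rxn_lik), cm)
  gf <- gaplik:::gapfilled_reactions(it$solutions)
  rep <- reaction_sensitivity(it$model, gf, "likelihood", cm)
  t1 <- rep[rep$reaction_id == "T_dgn1", ]
  expect_false(t1$essential)
  expect_true("DGN1" %in% t1$activated[[1]])
  expect_false(t1$non_contributing)
})

test_that("pruning removes exactly one of a mutually redundant pair", {
  m <- redundant_model()
  media <- new_media("mA", c(A_e = 10))
  rep <- reaction_sensitivity(m, c("T_A", "dup1", "dup2"), "parsimony", media)
  pruned <- prune_noncontributing(m, rep, media)
  left <- intersect(c("dup1", "dup2"), pruned$reactions$id)
  expect_length(left, 1)
  expect_true("T_A" %in% pruned$reactions$id)
  expect_gte(run_fba(apply_media(pruned, media))$objective_value, 1e-9)
  # nothing flagged: model unchanged
  rep0 <- rep; rep0$non_contributing <- FALSE
  expect_true(models_equal(prune_noncontributing(m, rep0, media), m))
})
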