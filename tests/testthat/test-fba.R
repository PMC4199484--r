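test_that("FBA solves the hand-checked linear pathway", {
  m <- apply_media(linear_model(), media_A(10))
  r <- run_fba(m)
  expect_identical(r$status, "optimal")
  expect_equal(r$objective_value, 10)
  # steady state holds at the optimum
  S <- model_smatrix(m)
  expect_lt(max(abs(S %*% r$fluxes)), 1e-6)
  # closed media: zero growth
  r0 <- run_fba(apply_media(linear_model(), new_media("empty")))
  expect_equal(r0$objective_value, 0)
})

test_that("forced flux against closed media is infeasible", {
  m <- apply_media(linear_model(), new_media("empty"))
  i <- match("R_AB", m$reactions$id)
  m$reactions$lower_bound[i] <- 5; m$reactions$upper_bound[i] <- 5
  expect_identical(run_fba(m)$status, "infeasible")
})

test_that("apply_media sets uptake bounds only and is idempotent", {
  m <- linear_model()
  m1 <- apply_media(m, media_A(7))
  expect_equal(m1$reactions$lower_bound[m1$reactions$id == "EX_A_e"], -7)
  expect_equal(m1$reactions$upper_bound[m1$reactions$id == "EX_A_e"], 100)
  expect_true(models_equal(apply_media(m1, media_A(7)), m1))
  # complete media opens every exchange to the default limit
  mc <- apply_media(m, new_media("c", complete = TRUE))
  expect_equal(mc$reactions$lower_bound[mc$reactions$id == "EX_A_e"], -100)
  # unknown compound: warning, compound ignored
  expect_warning(apply_media(m, new_media("w", c(ghost_e = 5))),
                 "no exchange reaction")
})

test_that("FVA ranges bracket FBA fluxes and find dead ends", {
  m <- apply_media(deadend_model(), media_A(10))
  fva <- run_fva(m)
  fba <- run_fba(m)
  for (k in seq_len(nrow(fva))) {
    expect_lte(fva$min[k], fba$fluxes[[fva$reaction_id[k]]] + 1e-9)
    expect_gte(fva$max[k], fba$fluxes[[fva$reaction_id[k]]] - 1e-9)
    expect_lte(fva$min[k], fva$max[k] + 1e-12)
  }
  # mass balance forces the dead-end branch to zero
  expect_equal(unlist(fva[fva$reaction_id == "R_dead", c("min", "max")]),
               c(min = 0, max = 0))
  # irreversible active pathway reaction at fraction 0: (0, positive)
  expect_equal(fva$min[fva$reaction_id == "R_AB"], 0)
  expect_equal(fva$max[fva$reaction_id == "R_AB"], 10)
  # fully coupled pair (T_A and R_AB both feed the single route)
  expect_equal(unlist(fva[fva$reaction_id == "T_A", c("min", "max")]),
               unlist(fva[fva$reaction_id == "R_AB", c("min", "max")]))
})

test_that("growth-constrained FVA pins the coupled pathway", {
  m <- apply_media(linear_model(), media_A(10))
  fva <- run_fva(m, "R_AB", fraction_of_optimum = 1)
  expect_equal(fva$min, 10, tolerance = 1e-6)
  expect_equal(fva$max, 10, tolerance = 1e-6)
})

test_that("find_inactive_reactions identifies blocked reactions", {
  m <- deadend_model()
  inact <- find_inactive_reactions(m, media_A(10))
  expect_identical(inact, "R_dead")
  # gap-free model: empty set
  expect_identical(find_inactive_reactions(linear_model(), media_A(10)),
                   character())
  # gene-associated restriction drops unassociated blocked reactions
  m2 <- add_reaction(m, "R_dead2", c(A_c = -1, D_c = 1))
  expect_identical(
    find_inactive_reactions(m2, media_A(10), gene_associated_only = TRUE),
    "R_dead")
  # a 3-reaction disconnected pathway is returned whole
  m3 <- linear_model()
  m3 <- add_reaction(m3, "P1", c(Q1_c = -1, Q2_c = 1), gpr = "gq")
  m3 <- add_reaction(m3, "P2", c(Q2_c = -1, Q3_c = 1), gpr = "gq")
  m3 <- add_reaction(m3, "P3", c(Q3_c = -1, Q4_c = 1), gpr = "gq")
  expect_identical(find_inactive_reactions(m3, media_A(10)),
                   c("P1", "P2", "P3"))
})
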