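test_that("knockout simulation follows GPR evaluation and the threshold", {
  u <- make_toy_universe(1)
  g <- u$gold_model
  ko <- simulate_knockouts(g, u$gold_media,
                           c("g_absent", "g_r1", "g_l1", "g_r2a", "g_tnh4a"))
  expect_true(ko[["g_absent"]])    # gene in no GPR: baseline growth
  expect_false(ko[["g_r1"]])      # sole gene on the only glucose route
  expect_false(ko[["g_l1"]])      # precursor pathway, no alternative
  expect_true(ko[["g_r2a"]])      # isoenzyme g_r2b still carries R2
  expect_false(ko[["g_tnh4a"]])   # AND-complex subunit is essential
  # baseline non-growth is a precondition error pointing at gap filling
  expect_error(simulate_knockouts(g, u$media$no_carbon, "g_r1"),
               "precondition error.*gap fill")
})

test_that("knockouts are monotone under gene-set growth", {
  u <- make_toy_universe(1)
  m <- apply_media(u$gold_model, u$gold_media)
  ko_one <- simulate_knockouts(u$gold_model, u$gold_media, "g_r2a")
  # knocking out a superset can only remove growth
  off <- vapply(m$reactions$gpr, function(e)
    !evaluate_gpr(e, c("g_r2a", "g_r2b")), logical(1))
  m2 <- m
  m2$reactions$lower_bound[off] <- 0
  m2$reactions$upper_bound[off] <- 0
  both <- run_fba(m2)$objective_value >= 1e-9
  expect_true(ko_one[["g_r2a"]])
  expect_false(both)
})

test_that("biolog simulation augments transporters once and predicts growth", {
  u <- make_toy_universe(1)
  media_list <- unname(u$media)
  bl <- simulate_biolog(u$gold_model, media_list)
  expect_true(bl[["minimal_glc"]])
  expect_true(bl[["minimal_zsub"]])
  expect_false(bl[["no_carbon"]])   # no carbon source
  # order independence
  bl2 <- simulate_biolog(u$gold_model, rev(media_list))
  expect_equal(bl2[names(bl)], bl)
  expect_length(simulate_biolog(u$gold_model, list()), 0)
})

test_that("score_predictions computes the confusion metrics", {
  # hand 2x2: 10 observed growth / 8 predicted; 10 no-growth / 6 correct
  obs <- phenotype_set(data.frame(
    kind = "biolog", key = paste0("m", 1:20),
    observed_growth = rep(c(1, 0), each = 10)))
  pred <- stats::setNames(c(rep(TRUE, 8), rep(FALSE, 2),
                            rep(FALSE, 6), rep(TRUE, 4)), paste0("m", 1:20))
  res <- score_predictions(pred, obs)
  expect_equal(res$sensitivity, 0.8)
  expect_equal(res$specificity, 0.6)
  expect_equal(res$tp + res$fp + res$tn + res$fn, 20)
  # perfect predictions
  res2 <- score_predictions(stats::setNames(rep(c(TRUE, FALSE), each = 10),
                                            paste0("m", 1:20)), obs)
  expect_equal(unlist(res2[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
  # zero denominator: undefined, reported NA rather than 0
  obs0 <- phenotype_set(data.frame(kind = "biolog", key = c("m1", "m2"),
                                   observed_growth = c(0, 0)))
  res3 <- score_predictions(c(m1 = FALSE, m2 = FALSE), obs0)
  expect_true(is.na(res3$sensitivity))
  expect_true(is.na(res3$ppv))
  expect_equal(res3$specificity, 1)
  expect_error(score_predictions(c(mX = TRUE), obs0), "no prediction")
})

test_that("phenotype sets validate and round-trip through TSV", {
  expect_error(phenotype_set(data.frame(kind = "knockout", key = "g1",
                                        observed_growth = 1)),
               "must name a media")
  expect_error(phenotype_set(data.frame(kind = "biolog",
                                        key = c("m1", "m1"),
                                        observed_growth = c(1, 0))),
               "duplicate")
  u <- make_toy_universe(1)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_phenotype_set(u$phenotypes, p)
  ps <- read_phenotype_set(p)
  expect_equal(as.data.frame(ps), as.data.frame(u$phenotypes))
})
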