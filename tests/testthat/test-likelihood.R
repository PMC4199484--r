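one_hit <- function(e) blast_hit_table(
  data.frame(query = "g1", target = "t1", evalue = e))
ref1 <- reference_db(c(t1 = "annA", t2 = "annB"))

test_that("log-scores follow -log10(E + k)", {
  s <- compute_log_scores(one_hit(1e-40))
  expect_equal(s$score, 40, tolerance = 1e-9)
  expect_equal(compute_log_scores(one_hit(0))$score, 200)
  expect_equal(compute_log_scores(one_hit(1e-5))$score, 5, tolerance = 1e-9)
  expect_error(compute_log_scores(data.frame(query = "g", target = "t",
                                             evalue = -1)), "negative")
})

test_that("pseudocount calibration: one hit at E = 1e-40 gives exactly 0.5", {
  ann <- compute_annotation_likelihoods(compute_log_scores(one_hit(1e-40)), ref1)
  expect_equal(ann$likelihood, 0.5, tolerance = 1e-9)
})

test_that("annotation likelihoods match hand-derived values", {
  # two hits to the same annotation at E = 1e-40: 3200/(1600+3200) = 2/3
  hits <- blast_hit_table(data.frame(query = "g1", target = c("t1", "t1b"),
                                     evalue = 1e-40))
  ref <- reference_db(c(t1 = "annA", t1b = "annA"))
  ann <- compute_annotation_likelihoods(compute_log_scores(hits), ref)
  expect_equal(ann$likelihood, 2 / 3, tolerance = 1e-12)
  # hits annA@1e-80 and annB@1e-40: 6400/11200 and 1600/11200
  hits <- blast_hit_table(data.frame(query = "g1", target = c("t1", "t2"),
                                     evalue = c(1e-80, 1e-40)))
  ann <- compute_annotation_likelihoods(compute_log_scores(hits), ref1)
  expect_equal(ann$likelihood[ann$annotation == "annA"], 6400 / 11200,
               tolerance = 1e-12)
  expect_equal(ann$likelihood[ann$annotation == "annB"], 1600 / 11200,
               tolerance = 1e-12)
  expect_lt(sum(ann$likelihood), 1)
  # unknown target gene
  expect_error(
    compute_annotation_likelihoods(
      compute_log_scores(one_hit(1e-40)), reference_db(c(tX = "annA"))),
    "missing from reference")
  # no hits at all: empty table
  empty <- compute_annotation_likelihoods(
    compute_log_scores(blast_hit_table(
      data.frame(query = character(), target = character(),
                 evalue = numeric()))), ref1)
  expect_equal(nrow(empty), 0)
})

test_that("role, complex and reaction propagation follow sum/max/min/max", {
  tpl <- new_template(
    data.frame(annotation = c("a1", "a2", "a3"),
               role = c("r1", "r1", "r2")),
    data.frame(complex = c("c1", "c2", "c2"), role = c("r1", "r1", "r2")),
    data.frame(complex = c("c1", "c2"), reaction = c("x1", "x1")))
  ann <- structure(
    data.frame(gene = c("g1", "g1", "g2", "g2"),
               annotation = c("a1", "a2", "a1", "a3"),
               likelihood = c(0.3, 0.2, 0.45, 0.4)),
    class = c("annotation_likelihoods", "data.frame"))
  roles <- compute_role_likelihoods(ann, tpl)
  # per-gene sum: g1 has a1 + a2 -> r1 = 0.5
  pg <- roles$per_gene
  expect_equal(pg$likelihood[pg$gene == "g1" & pg$role == "r1"], 0.5)
  # organism max and 80% retention: g2 at 0.45 >= 0.8 * 0.5 kept
  org <- stats::setNames(roles$organism$likelihood, roles$organism$role)
  expect_equal(unname(org["r1"]), 0.5)
  expect_identical(roles$retained$r1, c("g1", "g2"))
  # complex = min over roles; c2 limited by r2 = 0.4
  cx <- compute_complex_likelihoods(roles, tpl)
  expect_equal(cx$likelihood[cx$complex == "c1"], 0.5)
  expect_equal(cx$likelihood[cx$complex == "c2"], 0.4)
  expect_identical(cx$gpr[cx$complex == "c2"], "(g1 or g2) and g2")
  # reaction = max over complexes; both complexes retained (0.4 >= 0.8*0.5)
  rl <- compute_reaction_likelihoods(cx, tpl)
  expect_equal(rl$likelihood[rl$reaction_id == "x1"], 0.5)
  expect_identical(rl$gpr, "((g1 or g2) and g2) or g1 or g2")
})

test_that("retention thresholds are inclusive and zero evidence propagates", {
  tpl <- new_template(
    data.frame(annotation = c("a1", "a2", "a3"),
               role = c("r1", "r1", "r1")),
    data.frame(complex = c("c1", "c2", "c3"), role = "r1"),
    data.frame(complex = c("c1", "c2", "c3"), reaction = "x1"))
  # genes scoring 0.5, 0.45, 0.2: retained set is exactly {g1, g2}
  ann <- structure(
    data.frame(gene = c("g1", "g2", "g3"), annotation = c("a1", "a2", "a3"),
               likelihood = c(0.5, 0.45, 0.2)),
    class = c("annotation_likelihoods", "data.frame"))
  roles <- compute_role_likelihoods(ann, tpl)
  expect_identical(roles$retained$r1, c("g1", "g2"))
  # role with no mapped annotations -> p_org = 0
  tpl0 <- new_template(data.frame(annotation = "aX", role = "rX"),
                       data.frame(complex = "cX", role = "rX"),
                       data.frame(complex = "cX", reaction = "xX"))
  roles0 <- compute_role_likelihoods(
    compute_annotation_likelihoods(
      compute_log_scores(one_hit(1e-40)), reference_db(c(t1 = "other"))),
    tpl0)
  expect_equal(roles0$organism$likelihood, 0)
  rl0 <- compute_reaction_likelihoods(
    compute_complex_likelihoods(roles0, tpl0), tpl0)
  expect_equal(rl0$likelihood, 0)
  expect_identical(rl0$gpr, "")
  # complex referencing an unknown role errors
  badtpl <- tpl0
  badtpl$complex_roles$role <- "ghost"
  expect_error(compute_complex_likelihoods(roles0, badtpl), "unknown roles")
})

test_that("likelihood chain matches the brute-force oracle", {
  for (seed in 1:25) {
    inst <- random_likelihood_instance(seed)
    oracle <- oracle_likelihood_chain(inst$hits, inst$ref, inst$template)
    scores <- compute_log_scores(inst$hits)
    ann <- compute_annotation_likelihoods(scores, inst$ref)
    merged <- merge(as.data.frame(ann), oracle$annotation,
                    by = c("gene", "annotation"))
    expect_equal(nrow(merged), nrow(oracle$annotation))
    expect_equal(merged$likelihood.x, merged$likelihood.y, tolerance = 1e-12)
    rl <- compute_likelihoods(inst$hits, inst$ref, inst$template)
    expect_equal(stats::setNames(rl$likelihood, rl$reaction_id),
                 oracle$reactions[rl$reaction_id], tolerance = 1e-12)
  }
})

test_that("per-gene likelihoods are sub-normalized and monotone", {
  set.seed(99)
  for (i in 1:30) {
    inst <- random_likelihood_instance(1000 + i)
    ann <- compute_annotation_likelihoods(
      compute_log_scores(inst$hits), inst$ref)
    sums <- tapply(ann$likelihood, ann$gene, sum)
    expect_true(all(sums < 1))
  }
  # adding a hit to annotation b (below S_max) raises p(b), lowers p(a)
  ref <- reference_db(c(t1 = "annA", t2 = "annB", t3 = "annB"))
  h1 <- blast_hit_table(data.frame(query = "g1", target = c("t1", "t2"),
                                   evalue = c(1e-80, 1e-40)))
  h2 <- rbind(h1, data.frame(query = "g1", target = "t3", evalue = 1e-30))
  a1 <- compute_annotation_likelihoods(compute_log_scores(h1), ref)
  a2 <- compute_annotation_likelihoods(compute_log_scores(blast_hit_table(h2)), ref)
  get <- function(a, ann) a$likelihood[a$annotation == ann]
  expect_gt(get(a2, "annB"), get(a1, "annB"))
  expect_lt(get(a2, "annA"), get(a1, "annA"))
})

test_that("likelihoods are deterministic under input row order", {
  inst <- random_likelihood_instance(42)
  rl1 <- compute_likelihoods(inst$hits, inst$ref, inst$template)
  set.seed(1)
  shuffled <- inst$hits[sample(nrow(inst$hits)), ]
  rl2 <- compute_likelihoods(blast_hit_table(shuffled), inst$ref, inst$template)
  expect_identical(rl1$reaction_id, rl2$reaction_id)
  expect_identical(rl1$likelihood, rl2$likelihood)
  expect_identical(rl1$gpr, rl2$gpr)
})

test_that("ROC of gene-reaction links separates planted true/false links", {
  u <- make_toy_universe(1)
  roc <- roc_gene_reaction_links(u$rxn_lik, u$gold_model,
                                 cutoffs = c(0, 0.5, 0.99))
  # cutoff 0 retains everything; a cutoff above every likelihood nothing
  expect_equal(roc$true_positive_pct[1], 100)
  expect_equal(roc$false_positive_pct[1], 100)
  expect_equal(roc$true_positive_pct[3], 0)
  expect_equal(roc$false_positive_pct[3], 0)
  # true links (gold genes) are strong, false links (distractors) weak
  expect_equal(roc$true_positive_pct[2], 100)
  expect_equal(roc$false_positive_pct[2], 0)
  nogpr <- u$gold_model
  nogpr$reactions$gpr <- ""
  expect_error(roc_gene_reaction_links(u$rxn_lik, nogpr), "no GPRs")
})
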