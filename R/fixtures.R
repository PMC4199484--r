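#' Seeded synthetic fixtures
#'
#' Generators for every input the rest of the package consumes: a toy
#' universal reaction database with a gold-standard model, planted
#' BLAST evidence with known likelihood targets, a biochemistry
#' template, media and phenotypes.  The centerpiece scenario mirrors
#' the two-route precursor problem: a biomass precursor (`IPP_c`)
#' reachable either through a short 2-reaction path with *no* gene
#' evidence (`S1`, `S2`) or through a long 4-reaction path (`L1`-`L4`)
#' whose genes carry strong planted homology (reaction likelihood
#' exactly 0.9).  Parsimony-based gap filling picks the short path
#' (cost 2), likelihood-based gap filling the long one (cost 0.4).
#'
#' Evidence is planted by inverting the likelihood formula: `n` equal
#' hits at log-score `S` give `p = nS / (PC + nS)`, so a target `p` is
#' hit exactly with `S = PC * p / (n - n p)` and E-value `10^-S`.
#'
#' All generators are pure functions of `seed` (the R RNG is seeded
#' internally) and return identical objects for identical seeds.
#'
#' @name fixtures
NULL

# E-value giving exact likelihood p with n equal hits (PC = 40)
planted_evalue <- function(p, n = 1, PC = DEFAULT_PC) 10^(-PC * p / (n * (1 - p)))

#' Generate the toy universe
#'
#' Contents (deterministic skeleton, seeded random distractors):
#' a linear core pathway glucose -> B -> C with ammonia-dependent
#' biosynthesis of D, the two IPP routes described in [fixtures],
#' transporters (including a two-subunit ammonia transporter, an AND
#' complex), an isoenzyme pair on `R2` (an OR complex), a
#' thermodynamically unfavorable reaction (`U_unfav`, dG = +10
#' kcal/mol), a low-confidence-database reaction, peripheral
#' degradation targets with moderate gene evidence that iterative gap
#' filling must activate by adding secretion routes, and seeded
#' disconnected distractor reactions (one of them gene-associated and
#' unfillable).
#'
#' @param seed integer seed.
#' @param n_random number of random disconnected distractor reactions.
#' @return object of class `toy_universe`: list with `universal`,
#'   `template`, `genome`, `reference` (named vector), `blast`
#'   (hit table), `gold_model`, `gold_media`, `media` (named list),
#'   `phenotypes`, `planted` (data.frame of planted reaction
#'   likelihood targets), `seed`.
#' @export
make_toy_universe <- function(seed, n_random = 8) {
  set.seed(as.integer(seed))
  mets <- function(ids, comp) data.frame(id = ids, name = ids,
                                         compartment = comp,
                                         stringsAsFactors = FALSE)
  M <- rbind(
    mets(c("glc_e", "nh4_e", "zsub_e", "wex_e"), "e"),
    mets(c("glc_c", "nh4_c", "zsub_c", "wex_c", "B_c", "C_c", "D_c",
           "X1_c", "Y1_c", "Y2_c", "Y3_c", "IPP_c", "W1_c"), "c"))

  rx <- list(); st <- list()
  addrx <- function(id, stoich, lb = 0, ub = 100, gene_ann = NULL,
                    delta_g = NA_real_, conf = "high", class = "other") {
    rx[[id]] <<- list(id = id, lb = lb, ub = ub, gene_ann = gene_ann,
                      delta_g = delta_g, conf = conf, class = class)
    st[[id]] <<- stoich
  }
  s <- function(...) unlist(list(...))

  ## exchanges (export convention) and transporters
  addrx("EX_glc_e", s(glc_e = -1), -100, 100)
  addrx("EX_nh4_e", s(nh4_e = -1), -100, 100)
  addrx("EX_zsub_e", s(zsub_e = -1), -100, 100)
  addrx("T_glc", s(glc_e = -1, glc_c = 1), gene_ann = "g_tglc")
  addrx("T_nh4", s(nh4_e = -1, nh4_c = 1))     # AND complex, handled below
  addrx("T_zsub", s(zsub_e = -1, zsub_c = 1), gene_ann = "g_tzsub",
        class = "peripheral")
  ## core and biosynthesis
  addrx("R1", s(glc_c = -1, B_c = 1), gene_ann = "g_r1", delta_g = -5,
        class = "central")
  addrx("R2", s(B_c = -1, C_c = 1), delta_g = -2, class = "central")
  addrx("R3", s(C_c = -1, nh4_c = -1, D_c = 1), gene_ann = "g_r3",
        delta_g = -3, class = "biosynthesis")
  addrx("L1", s(C_c = -1, Y1_c = 1), gene_ann = "g_l1", delta_g = -1,
        class = "biosynthesis")
  addrx("L2", s(Y1_c = -1, Y2_c = 1), gene_ann = "g_l2", delta_g = -1,
        class = "biosynthesis")
  addrx("L3", s(Y2_c = -1, Y3_c = 1), gene_ann = "g_l3", delta_g = -1,
        class = "biosynthesis")
  addrx("L4", s(Y3_c = -1, IPP_c = 1), gene_ann = "g_l4", delta_g = -1,
        class = "biosynthesis")
  addrx("PZ", s(zsub_c = -1, B_c = 1), gene_ann = "g_pz", delta_g = -2,
        class = "peripheral")
  addrx("bio1", s(C_c = -1, D_c = -1, IPP_c = -1))
  gold_ids <- names(rx)

  ## universal-only: the short zero-evidence IPP route and penalty cases
  addrx("EX_wex_e", s(wex_e = -1), -100, 100)
  addrx("T_wex", s(wex_e = -1, wex_c = 1))     # no gene: penalty exerciser
  addrx("S1", s(B_c = -1, X1_c = 1), delta_g = -1, class = "biosynthesis")
  addrx("S2", s(X1_c = -1, IPP_c = 1), delta_g = -1, class = "biosynthesis")
  addrx("U_unfav", s(C_c = -1, W1_c = 1), delta_g = 10)
  addrx("U_low", s(W1_c = -1, D_c = 1), delta_g = -1, conf = "low")

  ## peripheral degradation targets: product requires a secretion route
  ## that only the universal database provides
  n_dgn <- 3
  for (d in seq_len(n_dgn)) {
    cm <- paste0("dgn", d, "_c"); em <- paste0("dgn", d, "_e")
    M <- rbind(M, mets(cm, "c"), mets(em, "e"))
    addrx(paste0("DGN", d), stats::setNames(c(-1, 1), c("B_c", cm)),
          gene_ann = paste0("g_dgn", d), delta_g = -1, class = "peripheral")
    addrx(paste0("T_dgn", d), stats::setNames(c(-1, 1), c(cm, em)))
    addrx(paste0("EX_dgn", d, "_e"), stats::setNames(-1, em), 0, 100)
  }

  ## seeded disconnected distractors; exactly one is gene-associated
  ## (and unfillable: its product has no sink anywhere in the universe)
  rand_assoc <- sample.int(n_random, 1)
  for (j in seq_len(n_random)) {
    pm <- paste0("rnd", j, "_c")
    M <- rbind(M, mets(pm, "c"))
    from <- sample(c("B_c", "C_c"), 1)
    addrx(paste0("RND", j), stats::setNames(c(-1, 1), c(from, pm)),
          gene_ann = if (j == rand_assoc) paste0("g_rnd", j),
          delta_g = round(stats::runif(1, -3, -1), 2))
  }

  rxdf <- reaction_defaults(length(rx))
  for (i in seq_along(rx)) {
    r <- rx[[i]]
    rxdf$id[i] <- r$id; rxdf$name[i] <- r$id
    rxdf$lower_bound[i] <- r$lb; rxdf$upper_bound[i] <- r$ub
    rxdf$delta_g[i] <- r$delta_g
    rxdf$source_confidence[i] <- r$conf
    rxdf$priority_class[i] <- r$class
  }
  universal <- new_model(paste0("toy_universal_seed", seed), M, rxdf, st, "bio1")

  ## ---- template: annotation -> role -> complex -> reaction ----------------
  simple <- c("tglc", "tzsub", "r1", "r3", "l1", "l2", "l3", "l4", "pz",
              paste0("dgn", seq_len(n_dgn)), paste0("rnd", rand_assoc))
  ann_roles <- data.frame(annotation = paste0("ann_", simple),
                          role = paste0("role_", simple),
                          stringsAsFactors = FALSE)
  cx_roles <- data.frame(complex = paste0("cpx_", simple),
                         role = paste0("role_", simple),
                         stringsAsFactors = FALSE)
  rxn_of <- c(tglc = "T_glc", tzsub = "T_zsub", r1 = "R1", r3 = "R3",
              l1 = "L1", l2 = "L2", l3 = "L3", l4 = "L4", pz = "PZ")
  rxn_of[paste0("dgn", seq_len(n_dgn))] <- paste0("DGN", seq_len(n_dgn))
  rxn_of[paste0("rnd", rand_assoc)] <- paste0("RND", rand_assoc)
  cx_rxns <- data.frame(complex = paste0("cpx_", simple),
                        reaction = unname(rxn_of[simple]),
                        stringsAsFactors = FALSE)
  ## R2: two alternative single-gene complexes (isoenzymes, OR)
  ann_roles <- rbind(ann_roles,
                     data.frame(annotation = c("ann_r2a", "ann_r2b"),
                                role = c("role_r2a", "role_r2b")))
  cx_roles <- rbind(cx_roles,
                    data.frame(complex = c("cpx_r2a", "cpx_r2b"),
                               role = c("role_r2a", "role_r2b")))
  cx_rxns <- rbind(cx_rxns,
                   data.frame(complex = c("cpx_r2a", "cpx_r2b"),
                              reaction = c("R2", "R2")))
  ## T_nh4: one two-subunit complex (AND)
  ann_roles <- rbind(ann_roles,
                     data.frame(annotation = c("ann_tnh4a", "ann_tnh4b"),
                                role = c("role_tnh4a", "role_tnh4b")))
  cx_roles <- rbind(cx_roles,
                    data.frame(complex = c("cpx_tnh4", "cpx_tnh4"),
                               role = c("role_tnh4a", "role_tnh4b")))
  cx_rxns <- rbind(cx_rxns,
                   data.frame(complex = "cpx_tnh4", reaction = "T_nh4"))
  ## noise annotations map to roles used by no complex (orphans)
  ann_roles <- rbind(ann_roles,
                     data.frame(annotation = paste0("ann_noise", 1:3),
                                role = paste0("role_noise", 1:3)))
  template <- new_template(ann_roles, cx_roles, cx_rxns)

  ## ---- planted BLAST evidence ---------------------------------------------
  blast <- list(); ref <- character(); genome <- list()
  plant <- function(gene, ann, p, n_hits) {
    ev <- planted_evalue(p, n_hits)
    for (h in seq_len(n_hits)) {
      tid <- paste0("t_", ann, "_", h)
      ref[tid] <<- ann
      blast[[length(blast) + 1L]] <<-
        data.frame(query = gene, target = tid, evalue = ev,
                   stringsAsFactors = FALSE)
    }
    genome[[length(genome) + 1L]] <<-
      data.frame(gene = gene, annotation = ann, stringsAsFactors = FALSE)
  }
  planted <- list()
  tgt <- function(reaction, p) planted[[length(planted) + 1L]] <<-
    data.frame(reaction_id = reaction, target_p = p, stringsAsFactors = FALSE)
  ## strong evidence: the long IPP pathway at exactly 0.9
  for (i in 1:4) { plant(paste0("g_l", i), paste0("ann_l", i), 0.9, 2)
                   tgt(paste0("L", i), 0.9) }
  ## the rest of the gold network at 0.8 (0.7 for the weaker isoenzyme)
  for (nm in c("tglc", "tzsub", "r1", "r3", "pz"))
    plant(paste0("g_", nm), paste0("ann_", nm), 0.8, 2)
  tgt("T_glc", 0.8); tgt("T_zsub", 0.8); tgt("R1", 0.8)
  tgt("R3", 0.8); tgt("PZ", 0.8)
  plant("g_r2a", "ann_r2a", 0.8, 2); plant("g_r2b", "ann_r2b", 0.7, 1)
  tgt("R2", 0.8)
  plant("g_tnh4a", "ann_tnh4a", 0.8, 2); plant("g_tnh4b", "ann_tnh4b", 0.8, 2)
  tgt("T_nh4", 0.8)
  ## moderate evidence: degradation targets and the one unfillable distractor
  for (d in seq_len(n_dgn)) {
    p_d <- round(stats::runif(1, 0.25, 0.42), 3)
    plant(paste0("g_dgn", d), paste0("ann_dgn", d), p_d, 1)
    tgt(paste0("DGN", d), p_d)
  }
  p_r <- round(stats::runif(1, 0.25, 0.42), 3)
  plant(paste0("g_rnd", rand_assoc), paste0("ann_rnd", rand_assoc), p_r, 1)
  tgt(paste0("RND", rand_assoc), p_r)
  ## weak spurious hits to orphan noise annotations (never on L genes or
  ## the exactly-calibrated isoenzyme pair)
  for (g in c("g_r1", "g_tglc", "g_pz", "g_r3")) {
    for (h in seq_len(sample(0:2, 1))) {
      ann <- paste0("ann_noise", sample(3, 1))
      tidn <- paste0("t_", ann, "_1")
      ref[tidn] <- ann
      blast[[length(blast) + 1L]] <-
        data.frame(query = g, target = tidn,
                   evalue = 10^(-stats::runif(1, 6, 8)),
                   stringsAsFactors = FALSE)
    }
  }
  blast <- blast_hit_table(do.call(rbind, blast))
  genome <- do.call(rbind, genome)
  planted <- do.call(rbind, planted)

  ## ---- gold model and media -----------------------------------------------
  gold <- universal
  gold$reactions <- gold$reactions[gold$reactions$id %in% gold_ids, ]
  rownames(gold$reactions) <- NULL
  gold$stoichiometry <- gold$stoichiometry[gold$reactions$id]
  gold$id <- paste0("toy_gold_seed", seed)
  keep_mets <- unique(unlist(lapply(gold$stoichiometry, names)))
  gold$metabolites <- gold$metabolites[gold$metabolites$id %in% keep_mets, ]
  rownames(gold$metabolites) <- NULL
  ## gold GPRs = the planted truth
  rxn_lik <- compute_likelihoods(blast, reference_db(ref), template)
  gold <- attach_candidate_gprs(gold, rxn_lik, gold$reactions$id)
  gold <- validate_model(gold)

  gold_media <- new_media("minimal_glc", c(glc_e = 10, nh4_e = 100))
  media <- list(
    minimal_glc = gold_media,
    minimal_zsub = new_media("minimal_zsub", c(zsub_e = 10, nh4_e = 100)),
    no_carbon = new_media("no_carbon", c(nh4_e = 100)))

  fba <- run_fba(apply_media(gold, gold_media))
  stopifnot(fba$status == "optimal", fba$objective_value > GROWTH_THRESHOLD)

  phenotypes <- phenotype_set(data.frame(
    kind = c(rep("knockout", 5), rep("biolog", 3)),
    key = c("g_r1", "g_l1", "g_pz", "g_r2a", "g_tnh4a",
            "minimal_glc", "minimal_zsub", "no_carbon"),
    media_name = c(rep("minimal_glc", 5), NA, NA, NA),
    observed_growth = c(0, 0, 1, 1, 0, 1, 1, 0),
    stringsAsFactors = FALSE))

  structure(list(universal = universal, template = template,
                 genome = genome, reference = reference_db(ref),
                 blast = blast, rxn_lik = rxn_lik,
                 gold_model = gold, gold_media = gold_media, media = media,
                 phenotypes = phenotypes, planted = planted, seed = seed),
            class = "toy_universe")
}

#' Build a simplified draft model from reaction likelihoods
#'
#' Stand-in for a full template-based draft reconstruction: the draft
#' consists of every universal reaction whose computed likelihood is at
#' least `include_threshold` and whose GPR is non-empty (gene
#' associated), with the candidate GPRs attached, plus exchange
#' reactions for all compounds touched by included transporters and
#' the biomass reaction.
#'
#' @param universal universal database model.
#' @param rxn_lik `reaction_likelihoods` over the universal reactions.
#' @param include_threshold inclusion threshold in `[0, 1]`.
#' @return a draft [metabolic_model].
#' @export
make_draft_model <- function(universal, rxn_lik, include_threshold) {
  if (include_threshold < 0 || include_threshold > 1)
    stop("validation error: include_threshold must be in [0, 1]")
  p <- reaction_likelihood(rxn_lik, universal$reactions$id)
  g <- reaction_gpr(rxn_lik, universal$reactions$id)
  keep <- nzchar(g) & p >= include_threshold
  ids <- universal$reactions$id[keep]
  ## exchanges for compounds of included transporters
  emets <- universal$metabolites$id[universal$metabolites$compartment == "e"]
  trans <- ids[universal$reactions$is_transporter[keep]]
  touched <- unique(unlist(lapply(trans, function(r)
    intersect(names(universal$stoichiometry[[r]]), emets))))
  ex <- exchange_reactions(universal)
  ex_keep <- ex[vapply(ex, function(r)
    exchange_metabolite(universal, r) %in% touched, logical(1))]
  ids <- unique(c(ids, ex_keep, universal$biomass_reaction_id))
  draft <- universal
  draft$reactions <- draft$reactions[draft$reactions$id %in% ids, ]
  rownames(draft$reactions) <- NULL
  draft$stoichiometry <- draft$stoichiometry[draft$reactions$id]
  draft$id <- paste0(universal$id, "_draft")
  draft <- attach_candidate_gprs(draft, rxn_lik, draft$reactions$id)
  validate_model(draft)
}

#' Generate a small random gap-filling instance
#'
#' A chain-style network over six cytosolic metabolites with a seeded
#' set of unit-stoichiometry candidate reactions, sized so the total
#' number of candidate reaction-directions (additions in both
#' directions plus reversibility changes) stays at or below 12 --
#' small enough for exhaustive subset enumeration.  Because every
#' reaction moves one metabolite to another, feasibility of a candidate
#' subset is equivalent to graph reachability from the uptaken
#' metabolite to the target's substrate, which gives an LP-free
#' independent oracle.
#'
#' @param seed integer seed.
#' @param n_candidates number of candidate reactions (default 5; each
#'   contributes two directions).
#' @return list with `draft`, `universal`, `media`, `target`
#'   (`"SINK"`), and `rxn_lik` (random likelihoods over candidates).
#' @export
make_gapfill_instance <- function(seed, n_candidates = 5) {
  set.seed(as.integer(seed))
  core <- paste0("M", 1:6, "_c")
  M <- data.frame(id = c("M1_e", core), name = c("M1_e", core),
                  compartment = c("e", rep("c", 6)),
                  stringsAsFactors = FALSE)
  rxdf <- reaction_defaults(0)
  st <- list()
  draft_ids <- c("EX_M1_e", "T_M1", "SINK")
  st[["EX_M1_e"]] <- c(M1_e = -1)
  st[["T_M1"]] <- c(M1_e = -1, M1_c = 1)
  st[["SINK"]] <- c(M6_c = -1)
  bounds <- list(EX_M1_e = c(-100, 100), T_M1 = c(0, 100), SINK = c(0, 100))
  ## optionally one fixed internal edge (its reversal becomes a candidate)
  if (stats::runif(1) < 0.5) {
    i <- sample(2:5, 1)
    id <- paste0("FIX_M", i)
    st[[id]] <- stats::setNames(c(-1, 1), c(core[i], core[sample(setdiff(1:5, i), 1)]))
    bounds[[id]] <- c(0, 100)
    draft_ids <- c(draft_ids, id)
  }
  cand_ids <- character()
  pairs <- expand.grid(from = 1:6, to = 1:6)
  pairs <- pairs[pairs$from != pairs$to, ]
  pick <- pairs[sample(nrow(pairs), n_candidates), ]
  for (k in seq_len(n_candidates)) {
    id <- paste0("CND", k)
    st[[id]] <- stats::setNames(c(-1, 1), core[c(pick$from[k], pick$to[k])])
    bounds[[id]] <- c(0, 100)
    cand_ids <- c(cand_ids, id)
  }
  ids <- names(st)
  rxdf <- reaction_defaults(length(ids))
  rxdf$id <- ids; rxdf$name <- ids
  rxdf$lower_bound <- vapply(ids, function(i) bounds[[i]][1], numeric(1))
  rxdf$upper_bound <- vapply(ids, function(i) bounds[[i]][2], numeric(1))
  ## random attributes to diversify costs
  for (id in cand_ids) {
    i <- match(id, rxdf$id)
    rxdf$source_confidence[i] <- sample(c("high", "low"), 1, prob = c(.7, .3))
    rxdf$delta_g[i] <- sample(c(NA_real_, round(stats::runif(1, -8, 12), 1)), 1)
  }
  universal <- new_model(paste0("inst", seed), M, rxdf, st, "SINK")
  draft <- universal
  draft$reactions <- draft$reactions[draft$reactions$id %in% draft_ids, ]
  rownames(draft$reactions) <- NULL
  draft$stoichiometry <- draft$stoichiometry[draft$reactions$id]
  lik <- round(stats::runif(length(cand_ids), 0, 0.95), 3)
  lik[stats::runif(length(cand_ids)) < 0.3] <- 0
  rxn_lik <- structure(
    data.frame(reaction_id = cand_ids, likelihood = lik,
               gpr = ifelse(lik > 0, paste0("g_", tolower(cand_ids)), ""),
               stringsAsFactors = FALSE),
    class = c("reaction_likelihoods", "data.frame"))
  list(draft = validate_model(draft), universal = universal,
       media = new_media(paste0("inst", seed), c(M1_e = 10)),
       target = "SINK", rxn_lik = rxn_lik)
}

#' Write all toy-universe inputs to a directory
#'
#' Materializes the fixture as the plain-text interchange files the
#' command-line interface consumes: universal and gold models
#' (JSON + SBML + attribute sidecars), BLAST hit TSV, reference TSV,
#' template TSVs, media TSVs and the phenotype TSV.
#'
#' @param universe a [make_toy_universe()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_universe <- function(universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_model(universe$universal, file.path(dir, "universal.json"),
              "json", sidecar = TRUE)
  write_model(universe$gold_model, file.path(dir, "gold.json"),
              "json", sidecar = TRUE)
  write_model(universe$gold_model, file.path(dir, "gold.xml"), "sbml")
  utils::write.table(
    data.frame(qseqid = universe$blast$query, sseqid = universe$blast$target,
               evalue = universe$blast$evalue),
    file.path(dir, "blast.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(universe$reference),
               annotation = unname(universe$reference)),
    file.path(dir, "reference.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_template(universe$template, dir)
  for (m in universe$media)
    write_media(m, file.path(dir, paste0(m$name, ".tsv")))
  write_media(new_media("complete", complete = TRUE),
              file.path(dir, "complete.tsv"))
  write_phenotype_set(universe$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_reaction_likelihoods(universe$rxn_lik,
                             file.path(dir, "likelihoods.tsv"))
  invisible(dir)
}
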