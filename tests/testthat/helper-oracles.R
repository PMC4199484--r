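# Independent brute-force oracles.  These re-derive expected values by
# direct enumeration, deliberately sharing no code with the package's
# vectorized/optimized implementations.

# naive per-gene, per-annotation likelihood by explicit loops
oracle_annotation_likelihoods <- function(hits, ref, PC = 40, k = 1e-200) {
  out <- list()
  for (g in sort(unique(hits$query))) {
    rows <- hits[hits$query == g, ]
    S <- -log10(rows$evalue + k)
    smax <- max(S)
    denom <- PC * smax + sum(S^2)
    for (a in sort(unique(ref[rows$target]))) {
      num <- 0
      for (i in seq_len(nrow(rows)))
        if (identical(unname(ref[[rows$target[i]]]), a)) num <- num + S[i]^2
      out[[length(out) + 1L]] <- data.frame(gene = g, annotation = a,
                                            likelihood = num / denom,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# naive full chain: annotation -> role (sum) -> organism (max) ->
# complex (min) -> reaction (max)
oracle_likelihood_chain <- function(hits, ref, template, PC = 40,
                                    k = 1e-200) {
  ann <- oracle_annotation_likelihoods(hits, ref, PC, k)
  ar <- template$annotation_roles
  roles <- sort(unique(c(ar$role, template$complex_roles$role)))
  genes <- sort(unique(ann$gene))
  per_gene <- matrix(0, length(genes), length(roles),
                     dimnames = list(genes, roles))
  for (i in seq_len(nrow(ann)))
    for (r in ar$role[ar$annotation == ann$annotation[i]])
      per_gene[ann$gene[i], r] <- per_gene[ann$gene[i], r] + ann$likelihood[i]
  org <- if (length(genes)) apply(per_gene, 2, max) else
    stats::setNames(numeric(length(roles)), roles)
  cxs <- sort(unique(template$complex_roles$complex))
  cx <- stats::setNames(numeric(length(cxs)), cxs)
  for (cc in cxs)
    cx[cc] <- min(org[template$complex_roles$role[
      template$complex_roles$complex == cc]])
  rxns <- sort(unique(template$complex_reactions$reaction))
  rl <- stats::setNames(numeric(length(rxns)), rxns)
  for (x in rxns)
    rl[x] <- max(cx[template$complex_reactions$complex[
      template$complex_reactions$reaction == x]])
  list(annotation = ann, per_gene = per_gene, organism = org,
       complexes = cx, reactions = rl)
}

# random small likelihood-chain instance (<= 5 genes x 5 annotations x
# 4 roles x 3 complexes), used for the oracle-equivalence suite
random_likelihood_instance <- function(seed) {
  set.seed(seed)
  n_ann <- sample(2:5, 1)
  anns <- paste0("a", seq_len(n_ann))
  # 1-2 reference proteins per annotation, unique gene ids
  ref <- character()
  for (a in anns)
    for (j in seq_len(sample(1:2, 1))) ref[paste0("t_", a, "_", j)] <- a
  genes <- paste0("g", seq_len(sample(2:5, 1)))
  rows <- list()
  for (g in genes) {
    tgt <- sample(names(ref), sample(1:min(4, length(ref)), 1))
    for (t in tgt)
      rows[[length(rows) + 1L]] <- data.frame(
        query = g, target = t,
        evalue = 10^(-runif(1, 5, 190)), stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  roles <- paste0("r", seq_len(sample(2:4, 1)))
  ar <- data.frame(annotation = anns,
                   role = sample(roles, n_ann, replace = TRUE),
                   stringsAsFactors = FALSE)
  cxs <- paste0("c", seq_len(sample(1:3, 1)))
  cr <- do.call(rbind, lapply(cxs, function(cc)
    data.frame(complex = cc,
               role = sample(roles, sample(1:2, 1)),
               stringsAsFactors = FALSE)))
  cx_rxn <- do.call(rbind, lapply(cxs, function(cc)
    data.frame(complex = cc, reaction = paste0("x", sample(1:3, 1)),
               stringsAsFactors = FALSE)))
  list(hits = blast_hit_table(hits), ref = reference_db(ref),
       template = new_template(ar, unique(cr), unique(cx_rxn)))
}

# ---- gap-filling enumeration oracle ---------------------------------------

# edge (from metabolite -> to metabolite) for each unit-stoichiometry
# candidate direction; draft reactions contribute always-on edges
instance_edges <- function(model, ids = model$reactions$id, reverse = FALSE) {
  do.call(rbind, lapply(ids, function(r) {
    st <- model$stoichiometry[[r]]
    if (length(st) != 2) return(NULL)   # exchanges handled separately
    from <- names(st)[st < 0]; to <- names(st)[st > 0]
    if (reverse) data.frame(from = to, to = from, stringsAsFactors = FALSE)
    else data.frame(from = from, to = to, stringsAsFactors = FALSE)
  }))
}

reachable <- function(edges, start) {
  seen <- start
  repeat {
    new <- unique(edges$to[edges$from %in% seen & !(edges$to %in% seen)])
    if (!length(new)) return(seen)
    seen <- c(seen, new)
  }
}

# exhaustive min-cost oracle for make_gapfill_instance() universes:
# feasibility of a candidate subset == reachability M1_c -> M6_c over
# always-on draft edges plus the subset's direction edges.  Subsets are
# scanned in increasing total cost, so the first feasible one is optimal.
oracle_gapfill_mincost <- function(inst, costs) {
  draft <- inst$draft
  base_edges <- instance_edges(draft,
    setdiff(draft$reactions$id, c("EX_M1_e", "SINK")))
  cand_edges <- do.call(rbind, lapply(seq_len(nrow(costs)), function(k) {
    rid <- costs$reaction_id[k]
    model <- if (costs$kind[k] == "addition") inst$universal else draft
    instance_edges(model, rid, reverse = costs$direction[k] == "reverse")
  }))
  n <- nrow(costs)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  total <- as.matrix(subsets) %*% costs$cost
  ord <- order(total)
  for (s in ord) {
    sel <- which(unlist(subsets[s, ]))
    edges <- rbind(base_edges, cand_edges[sel, , drop = FALSE])
    if ("M6_c" %in% reachable(edges, "M1_c"))
      return(list(objective = total[s], feasible = TRUE))
  }
  list(objective = NA_real_, feasible = FALSE)
}
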