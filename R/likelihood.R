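#' Annotation and reaction likelihoods from sequence homology
#'
#' The scoring chain turns BLAST hits against a high-confidence
#' reference into probability-like evidence scores:
#'
#' 1. **Log-scores.** Each hit (query gene *i*, reference gene *j*) gets
#'    `S_ij = -log10(E_ij + k)` with `k = 1e-200` guarding against
#'    reported E-values of zero (so `S <= 200`).  Hits are pre-filtered
#'    at `E <= 1e-5`, hence `S >= 5`.
#' 2. **Annotation likelihoods.** With `A_a` the reference genes carrying
#'    annotation `a` and `S_max` the gene's best score,
#'    `p(i in A_a) = sum_{j in A_a} S_ij^2 / (PC * S_max + sum_j S_ij^2)`.
#'    The pseudocount `PC = 40` calibrates a single hit at `E = 1e-40`
#'    (base-10 score 40) to likelihood exactly 0.5, and guarantees
#'    `sum_a p(i in A_a) < 1` per gene.  Squaring the scores keeps large
#'    numbers of weak hits from dominating.
#' 3. **Role likelihoods.** Per gene, the sum of its annotation
#'    likelihoods over annotations mapping to the role; per organism,
#'    the maximum over genes.  Genes within 80% of the maximum are
#'    retained, OR-linked.
#' 4. **Complex likelihoods.** Minimum over member roles (every subunit
#'    must be present); role gene clauses are AND-linked.
#' 5. **Reaction likelihoods.** Maximum over complexes mapped to the
#'    reaction; complexes within 80% of the maximum are retained and
#'    OR-linked into the final GPR.
#'
#' All 80% retention thresholds are inclusive.
#'
#' @name likelihood
NULL

DEFAULT_PC <- 40
DEFAULT_LOG_K <- 1e-200
DEFAULT_E_CUTOFF <- 1e-5
DEFAULT_RETAIN_FRACTION <- 0.8

#' Compute BLAST log-scores
#'
#' @param hits BLAST hit table (data.frame `query`, `target`, `evalue`),
#'   already filtered at the ingest cutoff (see [blast_hit_table()]).
#' @param k additive guard against `log10(0)` (default `1e-200`).
#' @return data.frame with columns `query`, `target`, `score`.
#' @export
compute_log_scores <- function(hits, k = DEFAULT_LOG_K) {
  if (any(hits$evalue < 0)) stop("validation error: negative E-value")
  data.frame(query = hits$query, target = hits$target,
             score = -log10(hits$evalue + k),
             stringsAsFactors = FALSE)
}

#' Compute annotation likelihoods
#'
#' @param scores log-score table from [compute_log_scores()].
#' @param ref reference database (named character vector, target gene ->
#'   annotation; see [reference_db()]).  Every target in `scores` must
#'   be present.
#' @param PC pseudocount (default 40).
#' @return object of class `annotation_likelihoods`: data.frame `gene`,
#'   `annotation`, `likelihood`, with the per-gene best score in
#'   `attr(, "s_max")`.  Genes with no hits have no rows (likelihood 0
#'   for every annotation).
#' @export
compute_annotation_likelihoods <- function(scores, ref, PC = DEFAULT_PC) {
  missing <- setdiff(unique(scores$target), names(ref))
  if (length(missing))
    stop("validation error: target genes missing from reference: ",
         paste(missing, collapse = ", "))
  if (nrow(scores) == 0) {
    out <- data.frame(gene = character(), annotation = character(),
                      likelihood = numeric(), stringsAsFactors = FALSE)
    return(structure(out, s_max = numeric(), PC = PC,
                     class = c("annotation_likelihoods", "data.frame")))
  }
  scores$annotation <- unname(ref[scores$target])
  s_max <- tapply(scores$score, scores$query, max)
  denom_sum <- tapply(scores$score^2, scores$query, sum)
  num <- stats::aggregate(score_sq ~ query + annotation,
                          data = transform(scores, score_sq = score^2), sum)
  num$likelihood <- num$score_sq /
    (PC * s_max[num$query] + denom_sum[num$query])
  out <- data.frame(gene = num$query, annotation = num$annotation,
                    likelihood = num$likelihood, stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$annotation), ]
  rownames(out) <- NULL
  structure(out, s_max = s_max, PC = PC,
            class = c("annotation_likelihoods", "data.frame"))
}

#' Compute functional-role likelihoods
#'
#' Per gene, `p(i in R_r)` is the sum of the gene's likelihoods over all
#' annotations the template maps to role `r`; the organism-level role
#' likelihood is the maximum over genes, and genes within
#' `retain_fraction` of that maximum are retained (OR-linked).
#'
#' @param ann an `annotation_likelihoods` object.
#' @param template a [new_template] biochemistry template.
#' @param retain_fraction inclusive retention threshold (default 0.8).
#' @return list with `per_gene` (data.frame `gene`, `role`,
#'   `likelihood`), `organism` (data.frame `role`, `likelihood` for all
#'   template roles, 0 when no evidence), and `retained` (named list,
#'   role -> retained gene ids).
#' @export
compute_role_likelihoods <- function(ann, template,
                                     retain_fraction = DEFAULT_RETAIN_FRACTION) {
  map <- template$annotation_roles
  all_roles <- sort(unique(c(map$role, template$complex_roles$role)))
  merged <- merge(as.data.frame(ann), map, by = "annotation")
  if (nrow(merged)) {
    per_gene <- stats::aggregate(likelihood ~ gene + role, data = merged, sum)
    per_gene <- per_gene[order(per_gene$gene, per_gene$role),
                         c("gene", "role", "likelihood")]
    rownames(per_gene) <- NULL
  } else {
    per_gene <- data.frame(gene = character(), role = character(),
                           likelihood = numeric(), stringsAsFactors = FALSE)
  }
  org <- stats::setNames(numeric(length(all_roles)), all_roles)
  retained <- stats::setNames(vector("list", length(all_roles)), all_roles)
  for (r in all_roles) {
    rows <- per_gene[per_gene$role == r, ]
    if (nrow(rows) == 0 || max(rows$likelihood) == 0) {
      retained[[r]] <- character()
      next
    }
    org[[r]] <- max(rows$likelihood)
    keep <- rows$gene[rows$likelihood >= retain_fraction * org[[r]]]
    retained[[r]] <- sort(keep)
  }
  list(per_gene = per_gene,
       organism = data.frame(role = all_roles, likelihood = unname(org),
                             stringsAsFactors = FALSE),
       retained = retained)
}

#' Compute protein-complex likelihoods
#'
#' `p(c)` is the minimum organism-level likelihood over the complex's
#' member roles; the partial GPR ANDs together each member role's
#' OR-clause of retained genes.
#'
#' @param roles result of [compute_role_likelihoods()].
#' @param template a [new_template] object.
#' @return data.frame `complex`, `likelihood`, `gpr` (canonical string).
#' @export
compute_complex_likelihoods <- function(roles, template) {
  org <- stats::setNames(roles$organism$likelihood, roles$organism$role)
  cx_ids <- sort(unique(template$complex_roles$complex))
  out <- data.frame(complex = cx_ids, likelihood = NA_real_, gpr = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(cx_ids)) {
    member_roles <- template$complex_roles$role[
      template$complex_roles$complex == cx_ids[i]]
    unknown <- setdiff(member_roles, names(org))
    if (length(unknown))
      stop("validation error: complex ", cx_ids[i],
           " references unknown roles: ", paste(unknown, collapse = ", "))
    out$likelihood[i] <- min(org[member_roles])
    clauses <- lapply(member_roles, function(r) gpr_or(as.list(roles$retained[[r]])))
    if (!any(vapply(clauses, is.null, logical(1))))
      out$gpr[i] <- gpr_string(gpr_and(clauses))
  }
  out
}

#' Compute reaction likelihoods and assemble GPRs
#'
#' `p(x)` is the maximum likelihood over complexes linked to reaction
#' `x`; complexes within `retain_fraction` of the maximum are retained
#' and their partial GPRs OR-linked.  Reactions without linked complexes
#' (or with only zero-likelihood complexes) get `p = 0` and an empty
#' GPR.
#'
#' @param complexes result of [compute_complex_likelihoods()].
#' @param template a [new_template] object.
#' @param retain_fraction inclusive retention threshold (default 0.8).
#' @return object of class `reaction_likelihoods`: data.frame
#'   `reaction_id`, `likelihood`, `gpr`, with per-reaction complex
#'   diagnostics in `attr(, "complexes")`.
#' @export
compute_reaction_likelihoods <- function(complexes, template,
                                         retain_fraction = DEFAULT_RETAIN_FRACTION) {
  links <- template$complex_reactions
  rxn_ids <- sort(unique(links$reaction))
  out <- data.frame(reaction_id = rxn_ids, likelihood = 0, gpr = "",
                    stringsAsFactors = FALSE)
  diagnostics <- list()
  for (i in seq_along(rxn_ids)) {
    cx <- links$complex[links$reaction == rxn_ids[i]]
    rows <- complexes[complexes$complex %in% cx, , drop = FALSE]
    diagnostics[[rxn_ids[i]]] <- rows
    if (nrow(rows) == 0) next
    pmaxc <- max(rows$likelihood)
    out$likelihood[i] <- pmaxc
    if (pmaxc == 0) next
    keep <- rows[rows$likelihood >= retain_fraction * pmaxc & nzchar(rows$gpr), ]
    out$gpr[i] <- gpr_string(gpr_or(lapply(keep$gpr, gpr_parse)))
  }
  structure(out, complexes = diagnostics,
            class = c("reaction_likelihoods", "data.frame"))
}

#' Full likelihood chain: BLAST hits to reaction likelihoods
#'
#' Convenience wrapper running [compute_log_scores()],
#' [compute_annotation_likelihoods()], [compute_role_likelihoods()],
#' [compute_complex_likelihoods()] and
#' [compute_reaction_likelihoods()] with shared defaults.
#'
#' @param hits BLAST hit table (see [blast_hit_table()]).
#' @param ref reference database (see [reference_db()]).
#' @param template a [new_template] object.
#' @param PC pseudocount.
#' @param k log-score guard.
#' @param retain_fraction retention threshold.
#' @return a `reaction_likelihoods` object.
#' @export
compute_likelihoods <- function(hits, ref, template, PC = DEFAULT_PC,
                                k = DEFAULT_LOG_K,
                                retain_fraction = DEFAULT_RETAIN_FRACTION) {
  scores <- compute_log_scores(hits, k = k)
  ann <- compute_annotation_likelihoods(scores, ref, PC = PC)
  roles <- compute_role_likelihoods(ann, template, retain_fraction)
  cx <- compute_complex_likelihoods(roles, template)
  compute_reaction_likelihoods(cx, template, retain_fraction)
}

# likelihood lookup helper: 0 for reactions without an entry
reaction_likelihood <- function(rxn_lik, ids) {
  if (is.null(rxn_lik)) return(stats::setNames(numeric(length(ids)), ids))
  p <- rxn_lik$likelihood[match(ids, rxn_lik$reaction_id)]
  p[is.na(p)] <- 0
  stats::setNames(p, ids)
}

reaction_gpr <- function(rxn_lik, ids) {
  if (is.null(rxn_lik)) return(stats::setNames(character(length(ids)), ids))
  g <- rxn_lik$gpr[match(ids, rxn_lik$reaction_id)]
  g[is.na(g)] <- ""
  stats::setNames(g, ids)
}

#' True/false-positive retention of gene-reaction links vs a curated model
#'
#' Computed links are all (gene, reaction) pairs where the gene appears
#' in the assembled likelihood GPR; each link carries the reaction
#' likelihood.  A link is *true* iff the gene appears in the curated
#' model's GPR for that reaction.  At each cutoff the fractions of true
#' and of false links with likelihood `>= cutoff` are reported (as
#' percentages), tracing a ROC-style curve.
#'
#' @param rxn_lik a `reaction_likelihoods` object.
#' @param curated a [metabolic_model] with curated GPRs.
#' @param cutoffs numeric vector of likelihood cutoffs.
#' @return data.frame `cutoff`, `true_positive_pct`, `false_positive_pct`.
#' @export
roc_gene_reaction_links <- function(rxn_lik, curated, cutoffs) {
  if (!any(nzchar(curated$reactions$gpr)))
    stop("validation error: curated model has no GPRs")
  links <- do.call(rbind, lapply(seq_len(nrow(rxn_lik)), function(i) {
    genes <- gpr_genes(rxn_lik$gpr[i])
    if (!length(genes)) return(NULL)
    data.frame(gene = genes, reaction_id = rxn_lik$reaction_id[i],
               likelihood = rxn_lik$likelihood[i], stringsAsFactors = FALSE)
  }))
  if (is.null(links)) stop("no computed gene-reaction links")
  cur_genes <- lapply(stats::setNames(curated$reactions$gpr, curated$reactions$id),
                      gpr_genes)
  links$true <- mapply(function(g, r)
    r %in% names(cur_genes) && g %in% cur_genes[[r]],
    links$gene, links$reaction_id)
  pct <- function(mask, cutoff)
    if (!any(mask)) NA_real_
    else 100 * mean(links$likelihood[mask] >= cutoff)
  data.frame(cutoff = cutoffs,
             true_positive_pct = vapply(cutoffs, function(ct) pct(links$true, ct), numeric(1)),
             false_positive_pct = vapply(cutoffs, function(ct) pct(!links$true, ct), numeric(1)))
}
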