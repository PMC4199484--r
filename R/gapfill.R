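#' Targeted gap filling
#'
#' Gap filling activates a target reaction (typically biomass) in a
#' draft network by selecting a minimum-cost set of modifications from a
#' universal reaction database: adding reactions in either direction, or
#' re-opening the closed direction of an existing draft reaction
#' (a reversibility change).  The selection is a mixed-integer program
#'
#' \deqn{\min \sum_j \lambda_j z_j \quad s.t.\;
#'   S v = 0,\; 0 \le v_j \le M z_j,\; v_{target} \ge \epsilon}
#'
#' over binary selections `z`, solved by LP-based branch and bound on
#' the built-in simplex (see [solve_lp()]).  Costs come from
#' [compute_costs()]: parsimony mode counts modifications (with
#' penalties), likelihood mode scales the base cost of each addition by
#' `C(x) = 1 - p(x)` so that well-supported reactions are cheap.  If the
#' node budget tied to `time_limit` is exhausted the limit is doubled
#' and the solve retried, up to `t_max` (default one day), after which a
#' timeout error is thrown; a provably infeasible instance errors
#' immediately.
#'
#' @name gapfill
NULL

GAPFILL_EPSILON <- 1e-5
GAPFILL_BIG_M <- 1000

#' Gap-filling penalty set
#'
#' Defaults follow the likelihood-optimal values (transporter 25,
#' unfavorable reversibility 12), which are also used for parsimony
#' mode.  The direction constants (12, 10) define the
#' unfavorable-direction surcharge
#' `U(dG) = (12 + 2 * max(dG, 0)) / 10` (in units of average
#' intracellular reaction additions; `U = 1.2` when dG is unknown).
#'
#' @param transporter penalty for adding a transport reaction.
#' @param unfavorable_reversibility scale for reversibility-change costs.
#' @param low_confidence_db penalty for reactions from low-confidence
#'   database sources.
#' @param direction_numerator,direction_denominator the (12, 10)
#'   constants of the surcharge.
#' @return object of class `gapfill_penalties`.
#' @export
gapfill_penalties <- function(transporter = 25, unfavorable_reversibility = 12,
                              low_confidence_db = 5,
                              direction_numerator = 12,
                              direction_denominator = 10) {
  stopifnot(transporter >= 0, unfavorable_reversibility >= 0,
            low_confidence_db >= 0)
  structure(list(transporter = transporter,
                 unfavorable_reversibility = unfavorable_reversibility,
                 low_confidence_db = low_confidence_db,
                 direction_numerator = direction_numerator,
                 direction_denominator = direction_denominator),
            class = "gapfill_penalties")
}

# unfavorable-direction surcharge for a directional delta-G (NA = unknown)
direction_surcharge <- function(dg_dir, pen) {
  dg <- ifelse(is.na(dg_dir), 0, pmax(dg_dir, 0))
  (pen$direction_numerator + 2 * dg) / pen$direction_denominator
}

# a direction is thermodynamically unfavorable iff its delta-G is known
# and strictly positive
direction_unfavorable <- function(dg_dir) !is.na(dg_dir) & dg_dir > 0

#' Compute gap-filling candidate costs
#'
#' Builds the cost table over candidate modifications: every universal
#' reaction absent from the draft, in both directions (additions), and
#' the closed direction of every irreversible non-exchange draft
#' reaction (reversibility changes).  For additions,
#' `lambda = base + U` (parsimony) or `lambda = (1 - p(x)) * base + U`
#' (likelihood), where `base = 1 + P_transporter + P_low_confidence_db`
#' as applicable and the surcharge `U` applies only in a
#' thermodynamically unfavorable direction and is never
#' likelihood-scaled.  Reversibility changes cost
#' `P_reversibility * U(dG_dir) / 1.2` in both modes.
#'
#' @param universal universal reaction database (a [metabolic_model]).
#' @param draft draft model being gap filled.
#' @param rxn_lik `reaction_likelihoods` (required for likelihood mode),
#'   or `NULL`.
#' @param pen a [gapfill_penalties] object.
#' @param mode `"parsimony"` or `"likelihood"`.
#' @return data.frame of class `gapfill_costs` with columns
#'   `reaction_id`, `direction` (`"forward"`/`"reverse"`), `kind`
#'   (`"addition"`/`"reversal"`), `likelihood`, `cost`.
#' @export
compute_costs <- function(universal, draft, rxn_lik = NULL,
                          pen = gapfill_penalties(),
                          mode = if (is.null(rxn_lik)) "parsimony" else "likelihood") {
  mode <- match.arg(mode, c("parsimony", "likelihood"))
  if (mode == "likelihood" && is.null(rxn_lik))
    stop("usage error: likelihood mode requires reaction likelihoods")
  rows <- list()
  add_ids <- setdiff(universal$reactions$id, draft$reactions$id)
  p <- reaction_likelihood(if (mode == "likelihood") rxn_lik else NULL, add_ids)
  for (rid in add_ids) {
    r <- get_reaction(universal, rid)
    base <- 1 + pen$transporter * r$is_transporter +
      pen$low_confidence_db * (r$source_confidence == "low")
    for (dir in c("forward", "reverse")) {
      dg_dir <- if (dir == "forward") r$delta_g else -r$delta_g
      surcharge <- if (direction_unfavorable(dg_dir))
        direction_surcharge(dg_dir, pen) else 0
      lambda <- if (mode == "likelihood")
        (1 - p[[rid]]) * base + surcharge else base + surcharge
      rows[[length(rows) + 1L]] <- data.frame(
        reaction_id = rid, direction = dir, kind = "addition",
        likelihood = p[[rid]], cost = lambda, stringsAsFactors = FALSE)
    }
  }
  ex <- exchange_reactions(draft)
  u_base <- direction_surcharge(NA_real_, pen)
  for (i in seq_len(nrow(draft$reactions))) {
    r <- draft$reactions[i, ]
    if (r$id %in% ex || r$id == draft$biomass_reaction_id) next
    closed <- c(if (r$lower_bound >= 0) "reverse", if (r$upper_bound <= 0) "forward")
    for (dir in closed) {
      dg_dir <- if (dir == "forward") r$delta_g else -r$delta_g
      rows[[length(rows) + 1L]] <- data.frame(
        reaction_id = r$id, direction = dir, kind = "reversal",
        likelihood = NA_real_,
        cost = pen$unfavorable_reversibility *
          direction_surcharge(dg_dir, pen) / u_base,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction_id = character(), direction = character(),
               kind = character(), likelihood = numeric(), cost = numeric(),
               stringsAsFactors = FALSE)
  structure(out, mode = mode, penalties = pen,
            rxn_lik = if (mode == "likelihood") rxn_lik else NULL,
            class = c("gapfill_costs", "data.frame"))
}

# Build the merged LP for a gap-filling instance.  Returns the matrix,
# bounds, candidate column bookkeeping, and the candidate table actually
# admitted (exchange uptake directions are capped by the media and
# dropped when the cap is zero).
build_gapfill_lp <- function(draft, universal, costs, target, media,
                             epsilon = GAPFILL_EPSILON, big_m = GAPFILL_BIG_M,
                             default_uptake = DEFAULT_UPTAKE) {
  draft_m <- apply_media(draft, media, default_uptake)
  mets <- unique(c(draft$metabolites$id, universal$metabolites$id))
  ## the target's own reversal is excluded: together with the forward
  ## direction it forms a futile two-cycle that would "activate" the
  ## target in the direction-split MILP but not in the integrated model
  costs <- costs[!(costs$reaction_id == target & costs$kind == "reversal"), ,
                 drop = FALSE]
  ncand <- nrow(costs)
  keep <- rep(TRUE, ncand)
  uni_ex <- exchange_reactions(universal)
  cap <- rep(big_m, ncand)
  for (k in seq_len(ncand)) {
    rid <- costs$reaction_id[k]
    if (costs$kind[k] == "addition" && rid %in% uni_ex &&
        costs$direction[k] == "reverse") {
      met <- exchange_metabolite(universal, rid)
      lim <- if (media$complete) default_uptake
             else if (met %in% names(media$uptake_limits))
               media$uptake_limits[[met]] else 0
      cap[k] <- min(big_m, lim)
      if (cap[k] <= 0) keep[k] <- FALSE
    }
  }
  costs <- costs[keep, , drop = FALSE]; cap <- cap[keep]
  ncand <- nrow(costs)
  nd <- nrow(draft_m$reactions)
  ncol_tot <- nd + ncand
  S <- matrix(0, length(mets), ncol_tot)
  rownames(S) <- mets
  for (i in seq_len(nd))
    S[names(draft_m$stoichiometry[[draft_m$reactions$id[i]]]), i] <-
      draft_m$stoichiometry[[draft_m$reactions$id[i]]]
  lb <- c(draft_m$reactions$lower_bound, numeric(ncand))
  ub <- c(draft_m$reactions$upper_bound, cap)
  for (k in seq_len(ncand)) {
    rid <- costs$reaction_id[k]
    st <- if (costs$kind[k] == "addition") universal$stoichiometry[[rid]]
          else draft$stoichiometry[[rid]]
    sgn <- if (costs$direction[k] == "forward") 1 else -1
    S[names(st), nd + k] <- S[names(st), nd + k] + sgn * st
  }
  ti <- match(target, draft_m$reactions$id)
  if (is.na(ti)) stop("usage error: target reaction ", target, " not in draft")
  if (draft_m$reactions$upper_bound[ti] < epsilon)
    stop("usage error: target upper bound below epsilon")
  lb[ti] <- max(lb[ti], epsilon)
  ## bound tightening: a flux direction consuming an unproducible (or
  ## producing an unconsumable) metabolite can never carry flux in any
  ## steady state; iterate to a fixed point, then drop dead candidates.
  repeat {
    can_pos <- ub > 1e-12; can_neg <- lb < -1e-12
    producible <- rowSums(S[, can_pos, drop = FALSE] > 0) +
      rowSums(S[, can_neg, drop = FALSE] < 0) > 0
    consumable <- rowSums(S[, can_pos, drop = FALSE] < 0) +
      rowSums(S[, can_neg, drop = FALSE] > 0) > 0
    changed <- FALSE
    for (m in which(!producible)) {
      hit <- which(S[m, ] < 0 & ub > 1e-12)
      if (length(hit)) { ub[hit] <- pmin(ub[hit], 0); changed <- TRUE }
      hit <- which(S[m, ] > 0 & lb < -1e-12)
      if (length(hit)) { lb[hit] <- pmax(lb[hit], 0); changed <- TRUE }
    }
    for (m in which(!consumable)) {
      hit <- which(S[m, ] > 0 & ub > 1e-12)
      if (length(hit)) { ub[hit] <- pmin(ub[hit], 0); changed <- TRUE }
      hit <- which(S[m, ] < 0 & lb < -1e-12)
      if (length(hit)) { lb[hit] <- pmax(lb[hit], 0); changed <- TRUE }
    }
    if (!changed) break
  }
  if (ub[ti] < epsilon || lb[ti] > ub[ti])
    return(list(infeasible = TRUE, costs = costs[0, , drop = FALSE]))
  dead <- which(ub[nd + seq_len(ncand)] <= 1e-12)
  if (length(dead)) {
    keep_cols <- setdiff(seq_len(ncol(S)), nd + dead)
    S <- S[, keep_cols, drop = FALSE]
    lb <- lb[keep_cols]; ub <- ub[keep_cols]
    costs <- costs[-dead, , drop = FALSE]
    ncand <- nrow(costs)
  }
  live_rows <- rowSums(S != 0) > 0
  S <- S[live_rows, , drop = FALSE]
  list(S = S, lb = lb, ub = ub, nd = nd, costs = costs,
       rxn_ids = c(draft_m$reactions$id, paste0(costs$reaction_id, ":", costs$direction)))
}

# LP-based branch and bound over candidate selections.
# Returns list(status, objective, selected (row indices into costs)).
milp_branch_and_bound <- function(lp, big_m = GAPFILL_BIG_M,
                                  time_limit = 600, ztol = 1e-7) {
  ncand <- nrow(lp$costs)
  cand_cols <- lp$nd + seq_len(ncand)
  cost <- lp$costs$cost
  t0 <- Sys.time()
  nmet <- nrow(lp$S)
  node_lp <- function(fixed1, fixed0) {
    obj <- numeric(ncol(lp$S))
    free <- setdiff(seq_len(ncand), c(fixed1, fixed0))
    obj[cand_cols[free]] <- cost[free] / big_m
    ub <- lp$ub
    ub[cand_cols[fixed0]] <- 0
    res <- solve_lp(obj, lp$S, numeric(nmet), lp$lb, ub, maximize = FALSE)
    list(res = res, free = free)
  }
  best_cost <- Inf; best_sel <- NULL
  stack <- list(list(fixed1 = integer(), fixed0 = integer()))
  nodes <- 0L
  while (length(stack)) {
    if (as.numeric(difftime(Sys.time(), t0, units = "secs")) > time_limit)
      return(list(status = "timeout", objective = best_cost, selected = best_sel))
    node <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    lbnd <- sum(cost[node$fixed1])
    if (lbnd >= best_cost - 1e-9) next
    sol <- node_lp(node$fixed1, node$fixed0)
    if (sol$res$status != "optimal") next
    lbnd <- lbnd + sol$res$objective
    if (lbnd >= best_cost - 1e-9) next
    xfree <- sol$res$x[cand_cols[sol$free]]
    used_free <- sol$free[xfree > ztol]
    inc_sel <- sort(c(node$fixed1, used_free))
    inc_cost <- sum(cost[inc_sel])
    if (inc_cost < best_cost - 1e-9) {
      best_cost <- inc_cost; best_sel <- inc_sel
    }
    if (!length(used_free)) next   # node solved exactly
    j <- used_free[which.max(cost[used_free] * xfree[match(used_free, sol$free)])]
    stack[[length(stack) + 1L]] <-
      list(fixed1 = c(node$fixed1, j), fixed0 = node$fixed0)
    stack[[length(stack) + 1L]] <-
      list(fixed1 = node$fixed1, fixed0 = c(node$fixed0, j))
  }
  if (is.infinite(best_cost))
    list(status = "infeasible", objective = NA_real_, selected = NULL)
  else
    list(status = "optimal", objective = best_cost, selected = best_sel)
}

#' Gap fill a target reaction
#'
#' @param draft draft [metabolic_model] (must contain `target`).
#' @param universal universal reaction database model; reactions sharing
#'   an id with draft reactions are treated as already present.
#' @param costs cost table from [compute_costs()] for this pair.
#' @param target reaction id to activate (flux `>= epsilon`).
#' @param media a [new_media] object for the gap-filling condition.
#' @param time_limit initial solver time limit, seconds.
#' @param t_max maximum limit of the doubling schedule (default 86400 s).
#' @param epsilon minimum target flux.
#' @param big_m flux capacity granted to selected candidates.
#' @return object of class `gapfill_solution` with fields `target`,
#'   `media_name`, `mode`, `objective_value`, `solver_status`, `added`
#'   (data.frame `reaction_id`, `direction`, `cost`, `likelihood`,
#'   `gpr`), `reversed` (data.frame `reaction_id`, `new_direction`,
#'   `cost`), and the data needed by [integrate_solution()].
#' @export
gapfill_target <- function(draft, universal, costs, target, media,
                           time_limit = 600, t_max = 86400,
                           epsilon = GAPFILL_EPSILON, big_m = GAPFILL_BIG_M) {
  mode <- attr(costs, "mode") %||% "parsimony"
  # already active?
  dm <- apply_media(draft, media)
  if (target %in% dm$reactions$id) {
    act <- run_fba(dm, target, "max")
    if (act$status == "optimal" && act$objective_value >= epsilon) {
      return(new_gapfill_solution(target, media, mode, 0, "optimal",
                                  empty_selection(), empty_reversal(),
                                  universal))
    }
  }
  lp <- build_gapfill_lp(draft, universal, costs, target, media,
                         epsilon = epsilon, big_m = big_m)
  if (isTRUE(lp$infeasible))
    stop("infeasibility error: no gap-filling solution exists for target ",
         target, " on media ", media$name)
  limit <- time_limit
  repeat {
    res <- milp_branch_and_bound(lp, big_m = big_m, time_limit = limit)
    if (res$status != "timeout") break
    if (limit >= t_max)
      stop("timeout error: gap filling exceeded t_max = ", t_max, " s")
    limit <- min(2 * limit, t_max)
  }
  if (res$status == "infeasible")
    stop("infeasibility error: no gap-filling solution exists for target ",
         target, " on media ", media$name)
  sel <- lp$costs[res$selected, , drop = FALSE]
  added <- sel[sel$kind == "addition", , drop = FALSE]
  reversed <- sel[sel$kind == "reversal", , drop = FALSE]
  added_df <- data.frame(reaction_id = added$reaction_id,
                         direction = added$direction,
                         cost = added$cost, likelihood = added$likelihood,
                         gpr = unname(reaction_gpr(attr(costs, "rxn_lik"),
                                                   added$reaction_id)),
                         stringsAsFactors = FALSE)
  reversed_df <- data.frame(reaction_id = reversed$reaction_id,
                            new_direction = reversed$direction,
                            cost = reversed$cost, stringsAsFactors = FALSE)
  new_gapfill_solution(target, media, mode, res$objective, "optimal",
                       added_df, reversed_df, universal)
}

empty_selection <- function()
  data.frame(reaction_id = character(), direction = character(),
             cost = numeric(), likelihood = numeric(), gpr = character(),
             stringsAsFactors = FALSE)

empty_reversal <- function()
  data.frame(reaction_id = character(), new_direction = character(),
             cost = numeric(), stringsAsFactors = FALSE)

new_gapfill_solution <- function(target, media, mode, objective, status,
                                 added, reversed, universal) {
  slice <- NULL
  if (nrow(added)) {
    ids <- unique(added$reaction_id)
    slice <- list(reactions = universal$reactions[
                    match(ids, universal$reactions$id), , drop = FALSE],
                  stoichiometry = universal$stoichiometry[ids],
                  metabolites = universal$metabolites)
  }
  structure(list(target = target, media = media, media_name = media$name,
                 mode = mode, objective_value = objective,
                 solver_status = status, added = added, reversed = reversed,
                 universal_slice = slice),
            class = "gapfill_solution")
}

#' @export
print.gapfill_solution <- function(x, ...) {
  cat("<gapfill_solution>", x$mode, "target:", x$target,
      "media:", x$media_name, "\n  objective:", x$objective_value,
      " added:", nrow(x$added), " reversed:", nrow(x$reversed), "\n")
  invisible(x)
}

#' Integrate a gap-filling solution into a model
#'
#' Added reactions are inserted with bounds opened in the selected
#' direction(s) (magnitude `DEFAULT_UPTAKE`), carrying the universal
#' database's reaction attributes; in likelihood mode (or when
#' `rxn_lik` is supplied) the candidate GPR from the likelihood
#' computation is attached, otherwise the GPR is left empty for later
#' post-processing (see [attach_candidate_gprs()]).  Reversibility
#' changes widen the bounds of existing reactions.  The target is then
#' verified to be active on the solution's media.
#'
#' @param draft the draft model the solution was computed against.
#' @param sol a `gapfill_solution`.
#' @param rxn_lik optional `reaction_likelihoods` for GPR attachment.
#' @return the augmented [metabolic_model].
#' @export
integrate_solution <- function(draft, sol, rxn_lik = NULL) {
  model <- draft
  if (nrow(sol$added)) {
    slice <- sol$universal_slice
    gprs <- if (!is.null(rxn_lik))
      reaction_gpr(rxn_lik, unique(sol$added$reaction_id))
    else if (sol$mode == "likelihood")
      stats::setNames(sol$added$gpr[!duplicated(sol$added$reaction_id)],
                      unique(sol$added$reaction_id))
    else
      stats::setNames(rep("", length(unique(sol$added$reaction_id))),
                      unique(sol$added$reaction_id))
    for (rid in unique(sol$added$reaction_id)) {
      dirs <- sol$added$direction[sol$added$reaction_id == rid]
      lbv <- if ("reverse" %in% dirs) -DEFAULT_UPTAKE else 0
      ubv <- if ("forward" %in% dirs) DEFAULT_UPTAKE else 0
      r <- slice$reactions[slice$reactions$id == rid, ]
      st <- slice$stoichiometry[[rid]]
      new_mets <- setdiff(names(st), model$metabolites$id)
      if (length(new_mets)) {
        mm <- slice$metabolites[match(new_mets, slice$metabolites$id), ]
        model$metabolites <- rbind(model$metabolites, mm)
      }
      model <- add_reaction(model, rid, st, lower_bound = lbv,
                            upper_bound = ubv,
                            gpr = gprs[[rid]],
                            delta_g = r$delta_g,
                            is_transporter = r$is_transporter,
                            source_confidence = r$source_confidence,
                            priority_class = r$priority_class)
    }
  }
  for (i in seq_len(nrow(sol$reversed))) {
    rid <- sol$reversed$reaction_id[i]
    if (sol$reversed$new_direction[i] == "reverse")
      model <- set_bounds(model, rid, lb = -DEFAULT_UPTAKE)
    else
      model <- set_bounds(model, rid, ub = DEFAULT_UPTAKE)
  }
  mm <- apply_media(model, sol$media)
  chk <- run_fba(mm, sol$target, "max")
  if (chk$status != "optimal" || chk$objective_value < GAPFILL_EPSILON * 0.99)
    stop("internal consistency error: target ", sol$target,
         " inactive after integrating solution")
  model
}

#' Attach candidate GPRs to gap-filled reactions (post-processing)
#'
#' The parsimony-mode comparator: after gap filling without likelihoods,
#' attach the likelihood-derived candidate GPR to every listed reaction
#' that has positive likelihood and no GPR yet.
#'
#' @param model a [metabolic_model].
#' @param rxn_lik a `reaction_likelihoods` object.
#' @param ids reactions to post-process (default: all with empty GPR).
#' @export
attach_candidate_gprs <- function(model, rxn_lik,
                                  ids = model$reactions$id[!nzchar(model$reactions$gpr)]) {
  g <- reaction_gpr(rxn_lik, ids)
  for (rid in ids) {
    i <- match(rid, model$reactions$id)
    if (!is.na(i) && !nzchar(model$reactions$gpr[i]) && nzchar(g[[rid]]))
      model$reactions$gpr[i] <- g[[rid]]
  }
  model
}

#' Complete media of a draft model
#'
#' The medium containing every extracellular compound touched by a
#' transport reaction of the draft, at the default uptake limit.
#'
#' @param draft a [metabolic_model].
#' @param default_uptake uptake limit per compound.
#' @return a [new_media] object named `"complete"`.
#' @export
complete_media <- function(draft, default_uptake = DEFAULT_UPTAKE) {
  emets <- draft$metabolites$id[draft$metabolites$compartment == "e"]
  trans <- draft$reactions$id[draft$reactions$is_transporter]
  touched <- unique(unlist(lapply(trans, function(r)
    intersect(names(draft$stoichiometry[[r]]), emets))))
  lims <- stats::setNames(rep(default_uptake, length(touched)), sort(touched))
  new_media("complete", lims)
}
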