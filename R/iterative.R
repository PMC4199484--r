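#' Iterative gap filling with sensitivity pruning
#'
#' Iterative gap filling loops over every inactive gene-associated
#' reaction of a model (already gap filled for biomass) in priority
#' order -- central carbon first, then biosynthesis of essential
#' metabolites, then peripheral utilization/degradation, then everything
#' else -- re-checking activity by FVA immediately before each target
#' (earlier integrations may have activated it), running
#' [gapfill_target()] on the still-inactive ones, and integrating each
#' solution before moving on.  Per-target failures (infeasible/timeout)
#' are recorded and skipped, never fatal.
#'
#' Because it maximizes the number of active reactions, the result often
#' contains redundant or weakly supported additions;
#' [reaction_sensitivity()] classifies each gap-filled reaction
#' (essential for biomass? does removing it inactivate other
#' reactions?) and [prune_noncontributing()] greedily removes the
#' non-contributing ones, re-evaluating after each removal so that two
#' mutually redundant additions are never both removed.
#'
#' @name iterative
NULL

#' Order gap-filling targets by priority class
#'
#' @param model a [metabolic_model].
#' @param inactive character vector of inactive reaction ids.
#' @return the ids sorted central < biosynthesis < peripheral < other,
#'   ties broken lexicographically by id.
#' @export
order_targets <- function(model, inactive) {
  if (!length(inactive)) return(character())
  cls <- model$reactions$priority_class[match(inactive, model$reactions$id)]
  rank <- match(cls, PRIORITY_CLASSES)
  inactive[order(rank, inactive)]
}

#' Iterative gap filling
#'
#' @param draft model already gap filled for biomass on `media`.
#' @param universal universal reaction database model.
#' @param costs cost table from [compute_costs()].
#' @param media gap-filling medium.
#' @param inactivity_tol FVA inactivity tolerance.
#' @param fraction_of_optimum biomass constraint used in the FVA
#'   inactivity checks (default 0, i.e. none).
#' @param time_limit per-target initial time limit, seconds.
#' @return list with `model` (final model) and `solutions` (list; each
#'   element a `gapfill_solution`, or a record with `failed = TRUE` and
#'   the error message for targets that could not be filled).
#' @export
iterative_gapfill <- function(draft, universal, costs, media,
                              inactivity_tol = 1e-9,
                              fraction_of_optimum = 0,
                              time_limit = 600) {
  rxn_lik <- attr(costs, "rxn_lik")
  model <- draft
  inactive <- find_inactive_reactions(model, media, tol = inactivity_tol,
                                      gene_associated_only = TRUE,
                                      fraction_of_optimum = fraction_of_optimum)
  targets <- order_targets(model, inactive)
  solutions <- list()
  for (tg in targets) {
    # re-check: an earlier integration may have activated this target
    mm <- apply_media(model, media)
    fva <- run_fva(mm, tg, fraction_of_optimum = fraction_of_optimum)
    if (fva$max > inactivity_tol || fva$min < -inactivity_tol) next
    sol <- tryCatch(
      gapfill_target(model, universal, costs, tg, media,
                     time_limit = time_limit),
      error = function(e) e)
    if (inherits(sol, "error")) {
      solutions[[length(solutions) + 1L]] <-
        list(target = tg, failed = TRUE, message = conditionMessage(sol))
      next
    }
    model <- integrate_solution(model, sol, rxn_lik)
    solutions[[length(solutions) + 1L]] <- sol
  }
  list(model = model, solutions = solutions)
}

# ids added or reversed by a list of solutions, with addition order and
# likelihood (reversals carry NA likelihood)
gapfilled_reactions <- function(solutions) {
  rows <- list()
  ord <- 0L
  for (s in solutions) {
    if (isTRUE(s$failed)) next
    for (rid in unique(s$added$reaction_id)) {
      ord <- ord + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        reaction_id = rid, kind = "addition",
        likelihood = s$added$likelihood[match(rid, s$added$reaction_id)],
        order = ord, stringsAsFactors = FALSE)
    }
    for (rid in s$reversed$reaction_id) {
      ord <- ord + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        reaction_id = rid, kind = "reversal", likelihood = NA_real_,
        order = ord, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(reaction_id = character(), kind = character(),
                      likelihood = numeric(), order = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[!duplicated(out$reaction_id), , drop = FALSE]
}

# processing order for sensitivity analysis / pruning
sensitivity_order <- function(gapfilled, mode) {
  if (mode == "likelihood") {
    lik <- ifelse(is.na(gapfilled$likelihood), 0, gapfilled$likelihood)
    gapfilled$reaction_id[order(lik, gapfilled$reaction_id)]
  } else {
    gapfilled$reaction_id[order(-gapfilled$order)]
  }
}

# close a gap-filled modification: additions are removed outright,
# reversals have the re-opened direction closed again
without_gapfilled <- function(model, rid, kind) {
  if (kind == "addition") return(remove_reactions(model, rid))
  i <- match(rid, model$reactions$id)
  if (model$reactions$lower_bound[i] < 0)
    model$reactions$lower_bound[i] <- 0
  else
    model$reactions$upper_bound[i] <- 0
  model
}

#' Reaction sensitivity analysis of gap-filled reactions
#'
#' Processes gap-filled reactions in reverse addition order (parsimony)
#' or from lowest to highest likelihood (likelihood mode).  Each is
#' temporarily removed; it is *essential* if biomass then falls below
#' `growth_threshold`, and its *activated* set is the reactions newly
#' inactive relative to the intact model.  Non-contributing = neither.
#'
#' @param model gap-filled [metabolic_model].
#' @param gapfilled data.frame from the iterative run (columns
#'   `reaction_id`, `kind`, `likelihood`, `order`), or a character
#'   vector of added reaction ids.
#' @param mode `"parsimony"` or `"likelihood"` (sets processing order).
#' @param media medium for the analysis.
#' @param growth_threshold lethality threshold (default 1e-9).
#' @param inactivity_tol FVA inactivity tolerance.
#' @return data.frame of class `sensitivity_report`: `reaction_id`,
#'   `kind`, `essential`, `activated` (list column), `non_contributing`,
#'   in processing order.
#' @export
reaction_sensitivity <- function(model, gapfilled,
                                 mode = c("parsimony", "likelihood"),
                                 media, growth_threshold = GROWTH_THRESHOLD,
                                 inactivity_tol = 1e-9) {
  mode <- match.arg(mode)
  if (is.character(gapfilled))
    gapfilled <- data.frame(reaction_id = gapfilled, kind = "addition",
                            likelihood = NA_real_,
                            order = seq_along(gapfilled),
                            stringsAsFactors = FALSE)
  missing <- setdiff(gapfilled$reaction_id, model$reactions$id)
  if (length(missing))
    stop("validation error: gap-filled ids not in model: ",
         paste(missing, collapse = ", "))
  ord <- sensitivity_order(gapfilled, mode)
  mm <- apply_media(model, media)
  base_inactive <- find_inactive_reactions(mm, NULL, tol = inactivity_tol)
  out <- data.frame(reaction_id = ord,
                    kind = gapfilled$kind[match(ord, gapfilled$reaction_id)],
                    essential = rep(NA, length(ord)),
                    non_contributing = rep(NA, length(ord)))
  out$activated <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    m2 <- without_gapfilled(mm, ord[k], out$kind[k])
    fba <- run_fba(m2)
    out$essential[k] <- fba$status != "optimal" ||
      fba$objective_value < growth_threshold
    newly <- if (out$essential[k]) character()
      else setdiff(find_inactive_reactions(m2, NULL, tol = inactivity_tol),
                   c(base_inactive, ord[k]))
    out$activated[[k]] <- newly
    out$non_contributing[k] <- !out$essential[k] && length(newly) == 0
  }
  structure(out, class = c("sensitivity_report", "data.frame"))
}

#' Prune non-contributing gap-filled reactions
#'
#' Greedily removes reactions flagged non-contributing, in the report's
#' processing order, re-evaluating essentiality and activation against
#' the current (already pruned) model before each removal -- a removal
#' can change later verdicts, and re-evaluation guarantees that of two
#' mutually redundant additions only one is removed.
#'
#' @param model gap-filled [metabolic_model].
#' @param report a `sensitivity_report` computed against `model`.
#' @param media medium used for the analysis.
#' @param growth_threshold,inactivity_tol as in [reaction_sensitivity()].
#' @return the pruned [metabolic_model].
#' @export
prune_noncontributing <- function(model, report, media,
                                  growth_threshold = GROWTH_THRESHOLD,
                                  inactivity_tol = 1e-9) {
  mm <- apply_media(model, media)
  base_inactive <- find_inactive_reactions(mm, NULL, tol = inactivity_tol)
  for (k in seq_len(nrow(report))) {
    if (!report$non_contributing[k]) next
    rid <- report$reaction_id[k]
    if (!rid %in% model$reactions$id) next
    mm <- apply_media(model, media)
    m2 <- without_gapfilled(mm, rid, report$kind[k])
    fba <- run_fba(m2)
    if (fba$status != "optimal" || fba$objective_value < growth_threshold)
      next                                  # became essential after earlier prunes
    newly <- setdiff(find_inactive_reactions(m2, NULL, tol = inactivity_tol),
                     c(base_inactive, rid))
    if (length(newly)) next                 # became contributing
    model <- without_gapfilled(model, rid, report$kind[k])
  }
  mm <- apply_media(model, media)
  fba <- run_fba(mm)
  if (fba$status != "optimal" || fba$objective_value < growth_threshold)
    stop("internal consistency error: biomass lost during pruning")
  model
}
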