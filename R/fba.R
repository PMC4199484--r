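#' Flux balance analysis primitives
#'
#' Steady-state flux analysis on a [metabolic_model]: applying media to
#' exchange bounds, maximizing/minimizing a flux objective (FBA),
#' per-reaction flux ranges (FVA), and detection of inactive (blocked)
#' reactions.  Default uptake for complete media is 100 mmol/gDW/hr.
#'
#' @name fba
NULL

DEFAULT_UPTAKE <- 100
GROWTH_THRESHOLD <- 1e-9

#' Constrain a model's exchange bounds to a medium
#'
#' Each exchange reaction's uptake bound (the negative lower bound, in
#' the export convention) is set to the medium's limit for its compound,
#' or to 0 if the compound is absent; secretion (upper) bounds are left
#' untouched.  Complete media opens every uptake to `default_uptake`.
#' Compounds named in the medium with no exchange reaction are ignored
#' with a warning.  The operation is idempotent.
#'
#' @param model a [metabolic_model].
#' @param media a [new_media] object.
#' @param default_uptake uptake bound used for complete media.
#' @return modified copy of the model.
#' @export
apply_media <- function(model, media, default_uptake = DEFAULT_UPTAKE) {
  ex <- exchange_reactions(model)
  ex_met <- vapply(ex, function(r) exchange_metabolite(model, r), character(1))
  if (!media$complete) {
    missing <- setdiff(names(media$uptake_limits), ex_met)
    if (length(missing))
      warning("media ", media$name, " names compounds with no exchange reaction: ",
              paste(missing, collapse = ", "))
  }
  for (k in seq_along(ex)) {
    lim <- if (media$complete) default_uptake
           else if (ex_met[k] %in% names(media$uptake_limits))
             media$uptake_limits[[ex_met[k]]]
           else 0
    i <- match(ex[k], model$reactions$id)
    model$reactions$lower_bound[i] <- -lim
  }
  model
}

fba_lp <- function(model) {
  list(S = model_smatrix(model),
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound)
}

#' Run flux balance analysis
#'
#' Solves `max/min v_obj` subject to `S v = 0` and the model's bounds.
#'
#' @param model a [metabolic_model] (media already applied).
#' @param objective_reaction reaction id to optimize; defaults to the
#'   biomass reaction.
#' @param direction `"max"` or `"min"`.
#' @return list with `status` (`"optimal"`/`"infeasible"`),
#'   `objective_value`, and `fluxes` (named vector).
#' @export
run_fba <- function(model, objective_reaction = model$biomass_reaction_id,
                    direction = c("max", "min")) {
  direction <- match.arg(direction)
  j <- match(objective_reaction, model$reactions$id)
  if (is.na(j)) stop("unknown objective reaction: ", objective_reaction)
  p <- fba_lp(model)
  obj <- numeric(nrow(model$reactions)); obj[j] <- 1
  res <- solve_lp(obj, p$S, numeric(nrow(p$S)), p$lb, p$ub,
                  maximize = direction == "max")
  list(status = res$status,
       objective_value = res$objective,
       fluxes = if (res$status == "optimal")
         stats::setNames(res$x, model$reactions$id) else NULL)
}

#' Run flux variability analysis
#'
#' For each reaction, the minimum and maximum feasible flux with the
#' biomass flux constrained to at least `fraction_of_optimum` times the
#' FBA optimum (`fraction_of_optimum = 0`: no growth constraint).  Two
#' LPs are solved per reaction.
#'
#' @param model a [metabolic_model] (media applied).
#' @param reaction_ids reactions to analyze (default: all).
#' @param fraction_of_optimum number in `[0, 1]`.
#' @return data.frame with columns `reaction_id`, `min`, `max`.
#' @export
run_fva <- function(model, reaction_ids = model$reactions$id,
                    fraction_of_optimum = 0) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  unknown <- setdiff(reaction_ids, model$reactions$id)
  if (length(unknown)) stop("unknown reactions: ", paste(unknown, collapse = ", "))
  if (fraction_of_optimum > 0) {
    base <- run_fba(model)
    if (base$status != "optimal") stop("FVA: base model infeasible")
    i <- match(model$biomass_reaction_id, model$reactions$id)
    model$reactions$lower_bound[i] <-
      max(model$reactions$lower_bound[i],
          fraction_of_optimum * base$objective_value)
  }
  p <- fba_lp(model)
  b <- numeric(nrow(p$S))
  n <- nrow(model$reactions)
  out <- data.frame(reaction_id = reaction_ids, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reaction_ids)) {
    j <- match(reaction_ids[k], model$reactions$id)
    obj <- numeric(n); obj[j] <- 1
    lo <- solve_lp(obj, p$S, b, p$lb, p$ub, maximize = FALSE)
    hi <- solve_lp(obj, p$S, b, p$lb, p$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA: infeasible model")
    out$min[k] <- lo$objective; out$max[k] <- hi$objective
  }
  out
}

#' Find inactive (blocked) reactions
#'
#' Reactions whose FVA range on the given medium lies within
#' `[-tol, +tol]` in both directions.  With `gene_associated_only =
#' TRUE` only reactions carrying a non-empty GPR are examined (the set
#' targeted by iterative gap filling).
#'
#' @param model a [metabolic_model].
#' @param media a [new_media] object, or `NULL` to use current bounds.
#' @param tol inactivity tolerance (flux).
#' @param gene_associated_only restrict to gene-associated reactions?
#' @param fraction_of_optimum biomass constraint for the FVA (default 0).
#' @return character vector of inactive reaction ids (sorted).
#' @export
find_inactive_reactions <- function(model, media = NULL, tol = 1e-9,
                                    gene_associated_only = FALSE,
                                    fraction_of_optimum = 0) {
  if (!is.null(media)) model <- apply_media(model, media)
  ids <- model$reactions$id
  if (gene_associated_only) ids <- ids[nzchar(model$reactions$gpr)]
  if (!length(ids)) return(character())
  fva <- run_fva(model, ids, fraction_of_optimum = fraction_of_optimum)
  sort(fva$reaction_id[fva$min >= -tol & fva$max <= tol])
}
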