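#' Metabolic model objects
#'
#' A `metabolic_model` is a stoichiometric network over two compartments,
#' cytosol `"c"` and extracellular space `"e"`.  It holds:
#'
#' * `metabolites`: data.frame with columns `id`, `name`, `compartment`;
#' * `reactions`: data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound` (mmol/gDW/hr), `gpr` (canonical GPR string, `""` if
#'   none), `delta_g` (estimated standard Gibbs energy, kcal/mol, `NA` =
#'   unknown), `is_transporter`, `source_confidence` (`"high"`/`"low"`),
#'   `priority_class` (`"central"`, `"biosynthesis"`, `"peripheral"`,
#'   `"other"`);
#' * `stoichiometry`: named list, reaction id -> named numeric vector of
#'   signed coefficients over metabolite ids;
#' * `biomass_reaction_id`: id of the biomass (growth) reaction.
#'
#' Exchange reactions are identified structurally: a single-metabolite
#' stoichiometry on an extracellular metabolite, written in the export
#' convention (coefficient -1, so positive flux secretes and negative
#' flux takes the compound up).
#'
#' @name metabolic_model
NULL

PRIORITY_CLASSES <- c("central", "biosynthesis", "peripheral", "other")

reaction_defaults <- function(n) {
  data.frame(id = character(n), name = character(n),
             lower_bound = numeric(n), upper_bound = numeric(n),
             gpr = character(n), delta_g = rep(NA_real_, n),
             is_transporter = logical(n),
             source_confidence = rep("high", n),
             priority_class = rep("other", n),
             stringsAsFactors = FALSE)
}

#' Construct a metabolic model
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name` (optional),
#'   `compartment`.
#' @param reactions data.frame with at least `id`; missing attribute
#'   columns take their defaults (see [metabolic_model]).
#' @param stoichiometry named list, reaction id -> named numeric vector.
#' @param biomass_reaction_id id of the biomass reaction.
#' @return validated object of class `metabolic_model`.
#' @export
new_model <- function(id, metabolites, reactions, stoichiometry,
                      biomass_reaction_id) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  def <- reaction_defaults(nrow(reactions))
  for (col in names(def)) if (is.null(reactions[[col]])) reactions[[col]] <- def[[col]]
  reactions <- reactions[names(def)]
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL
  m <- structure(list(id = id,
                      metabolites = metabolites,
                      reactions = reactions,
                      stoichiometry = stoichiometry,
                      biomass_reaction_id = biomass_reaction_id),
                 class = "metabolic_model")
  # infer transporter flags where not supplied explicitly
  m$reactions$is_transporter <- vapply(m$reactions$id, function(r)
    isTRUE(m$reactions$is_transporter[m$reactions$id == r]) ||
      reaction_spans_compartments(m, r), logical(1), USE.NAMES = FALSE)
  validate_model(m)
}

reaction_compartments <- function(model, rxn_id) {
  mets <- names(model$stoichiometry[[rxn_id]])
  unique(model$metabolites$compartment[match(mets, model$metabolites$id)])
}

reaction_spans_compartments <- function(model, rxn_id) {
  length(reaction_compartments(model, rxn_id)) > 1
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, bound ordering, stoichiometry references,
#' enum-valued attributes, GPR parsability and the presence of the
#' biomass reaction.  Returns the model invisibly augmented with
#' canonicalized GPR strings.
#'
#' @param model a `metabolic_model`.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites; rxns <- model$reactions
  if (anyDuplicated(mets$id))
    stop("validation error: duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (anyDuplicated(rxns$id))
    stop("validation error: duplicate reaction ids: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  if (!all(mets$compartment %in% c("c", "e")))
    stop("validation error: compartments must be 'c' or 'e'")
  if (any(!is.finite(rxns$lower_bound)) || any(!is.finite(rxns$upper_bound)))
    stop("validation error: non-finite flux bound")
  bad <- rxns$id[rxns$lower_bound > rxns$upper_bound]
  if (length(bad))
    stop("validation error: lower_bound > upper_bound for: ",
         paste(bad, collapse = ", "))
  if (!setequal(names(model$stoichiometry), rxns$id) ||
      length(model$stoichiometry) != nrow(rxns))
    stop("validation error: stoichiometry list does not match reaction ids")
  for (r in rxns$id) {
    st <- model$stoichiometry[[r]]
    if (length(st) == 0) stop("validation error: empty stoichiometry for ", r)
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown))
      stop("validation error: reaction ", r, " references unknown metabolites: ",
           paste(unknown, collapse = ", "))
  }
  if (!all(rxns$source_confidence %in% c("high", "low")))
    stop("validation error: source_confidence must be 'high' or 'low'")
  if (!all(rxns$priority_class %in% PRIORITY_CLASSES))
    stop("validation error: bad priority_class value")
  if (is.null(model$biomass_reaction_id) || is.na(model$biomass_reaction_id) ||
      !model$biomass_reaction_id %in% rxns$id)
    stop("validation error: biomass_reaction_id missing or not a reaction id")
  model$reactions$gpr <- vapply(rxns$gpr, function(g)
    gpr_string(gpr_parse(g)), character(1), USE.NAMES = FALSE)
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", x$id, "\n",
      " metabolites:", nrow(x$metabolites),
      " reactions:", nrow(x$reactions),
      " biomass:", x$biomass_reaction_id, "\n")
  invisible(x)
}

#' Exchange reaction ids of a model
#'
#' Exchange reactions have a single-metabolite stoichiometry on an
#' extracellular metabolite.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  emets <- model$metabolites$id[model$metabolites$compartment == "e"]
  keep <- vapply(model$reactions$id, function(r) {
    st <- model$stoichiometry[[r]]
    length(st) == 1 && names(st) %in% emets
  }, logical(1), USE.NAMES = FALSE)
  model$reactions$id[keep]
}

# extracellular metabolite drained by an exchange reaction
exchange_metabolite <- function(model, rxn_id) {
  names(model$stoichiometry[[rxn_id]])
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites x reactions.
#' @export
model_smatrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (r in model$reactions$id) {
    st <- model$stoichiometry[[r]]
    S[names(st), r] <- st
  }
  S
}

#' Add a reaction to a model
#'
#' @param model a `metabolic_model`.
#' @param id new (unique) reaction id.
#' @param stoichiometry named numeric vector over metabolite ids;
#'   metabolites not yet in the model are created (compartment inferred
#'   from a trailing `_e` in the id, else `"c"`).
#' @param lower_bound,upper_bound flux bounds.
#' @param gpr GPR string (default none).
#' @param ... further reaction attribute columns (`delta_g`,
#'   `source_confidence`, `priority_class`, ...).
#' @export
add_reaction <- function(model, id, stoichiometry, lower_bound = 0,
                         upper_bound = 100, gpr = "", ...) {
  if (id %in% model$reactions$id)
    stop("validation error: duplicate reaction id: ", id)
  new_mets <- setdiff(names(stoichiometry), model$metabolites$id)
  if (length(new_mets)) {
    comp <- ifelse(grepl("_e$", new_mets), "e", "c")
    model$metabolites <- rbind(model$metabolites,
      data.frame(id = new_mets, name = new_mets, compartment = comp,
                 stringsAsFactors = FALSE))
  }
  row <- reaction_defaults(1)
  row$id <- id; row$name <- id
  row$lower_bound <- lower_bound; row$upper_bound <- upper_bound
  row$gpr <- gpr_string(gpr)
  extra <- list(...)
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  model$reactions <- rbind(model$reactions, row[names(model$reactions)])
  model$stoichiometry[[id]] <- stoichiometry
  model$reactions$is_transporter[model$reactions$id == id] <-
    isTRUE(extra$is_transporter) || reaction_spans_compartments(model, id)
  validate_model(model)
}

#' Remove reactions from a model
#'
#' Unreferenced metabolites are retained; the biomass reaction cannot be
#' removed.
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids to remove (all must exist).
#' @export
remove_reactions <- function(model, ids) {
  unknown <- setdiff(ids, model$reactions$id)
  if (length(unknown))
    stop("validation error: unknown reaction ids: ", paste(unknown, collapse = ", "))
  if (model$biomass_reaction_id %in% ids)
    stop("validation error: cannot remove the biomass reaction")
  keep <- !(model$reactions$id %in% ids)
  model$reactions <- model$reactions[keep, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model$stoichiometry <- model$stoichiometry[model$reactions$id]
  model
}

set_bounds <- function(model, rxn_id, lb = NULL, ub = NULL) {
  i <- match(rxn_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", rxn_id)
  if (!is.null(lb)) model$reactions$lower_bound[i] <- lb
  if (!is.null(ub)) model$reactions$upper_bound[i] <- ub
  model
}

get_reaction <- function(model, rxn_id) {
  i <- match(rxn_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", rxn_id)
  model$reactions[i, , drop = FALSE]
}

#' Media definitions
#'
#' A growth medium is a named set of maximum uptake fluxes for
#' extracellular compounds.  `complete = TRUE` denotes complete media:
#' every compound the model can exchange is available at the default
#' uptake limit, and `uptake_limits` must be empty.
#'
#' @param name media name.
#' @param uptake_limits named numeric vector, extracellular metabolite id
#'   -> maximum uptake flux (mmol/gDW/hr, non-negative).
#' @param complete logical; complete media flag.
#' @return object of class `media`.
#' @export
new_media <- function(name, uptake_limits = numeric(), complete = FALSE) {
  uptake_limits <- unlist(uptake_limits)
  if (length(uptake_limits) == 0) uptake_limits <- stats::setNames(numeric(), character())
  if (any(uptake_limits < 0)) stop("validation error: uptake limits must be >= 0")
  if (complete && length(uptake_limits))
    stop("validation error: complete media cannot list uptake limits")
  structure(list(name = name, uptake_limits = uptake_limits,
                 complete = complete), class = "media")
}

#' @export
print.media <- function(x, ...) {
  cat("<media>", x$name,
      if (x$complete) "(complete)" else paste0("(", length(x$uptake_limits), " compounds)"),
      "\n")
  invisible(x)
}

#' Field-level model equality
#'
#' Compares metabolites, reaction attributes (canonical GPR strings
#' included), stoichiometries and the biomass id; row order is ignored.
#'
#' @param a,b `metabolic_model` objects.
#' @param tol numeric tolerance on coefficients and bounds.
#' @return logical scalar.
#' @export
models_equal <- function(a, b, tol = 1e-9) {
  if (!setequal(a$metabolites$id, b$metabolites$id)) return(FALSE)
  if (!setequal(a$reactions$id, b$reactions$id)) return(FALSE)
  if (!identical(a$biomass_reaction_id, b$biomass_reaction_id)) return(FALSE)
  ma <- a$metabolites[order(a$metabolites$id), ]
  mb <- b$metabolites[order(b$metabolites$id), ]
  if (!all(ma$compartment == mb$compartment)) return(FALSE)
  ra <- a$reactions[order(a$reactions$id), ]
  rb <- b$reactions[order(b$reactions$id), ]
  num_ok <- max(abs(ra$lower_bound - rb$lower_bound),
                abs(ra$upper_bound - rb$upper_bound)) <= tol
  dg_ok <- all(is.na(ra$delta_g) == is.na(rb$delta_g)) &&
    all(abs(ra$delta_g - rb$delta_g) <= tol, na.rm = TRUE)
  attr_ok <- all(ra$gpr == rb$gpr) && all(ra$is_transporter == rb$is_transporter) &&
    all(ra$source_confidence == rb$source_confidence) &&
    all(ra$priority_class == rb$priority_class)
  if (!(num_ok && dg_ok && attr_ok)) return(FALSE)
  for (r in ra$id) {
    sa <- a$stoichiometry[[r]]; sb <- b$stoichiometry[[r]]
    if (!setequal(names(sa), names(sb))) return(FALSE)
    if (max(abs(sa[names(sa)] - sb[names(sa)])) > tol) return(FALSE)
  }
  TRUE
}
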