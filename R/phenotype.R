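#' Phenotype simulation and scoring
#'
#' Knockout-lethality and Biolog-style growth simulations compared
#' against observed phenotypes.  A knockout is simulated by evaluating
#' every reaction's GPR with the gene removed and closing both bounds
#' of reactions whose GPR evaluates FALSE; growth is then the FBA
#' biomass optimum, called positive at the 1e-9 /hr threshold.  Biolog
#' simulation first augments the model once with a reversible
#' transporter and exchange for every compound appearing in any of the
#' assay media, then tests growth on each medium in turn.
#'
#' @name phenotype
NULL

#' Construct a phenotype set
#'
#' @param entries data.frame with columns `kind` (`"knockout"` or
#'   `"biolog"`), `key` (gene id / media name), `media_name` (for
#'   knockout entries), `observed_growth` (logical or 0/1).
#' @return data.frame of class `phenotype_set`.
#' @export
phenotype_set <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("kind", "key", "observed_growth") %in% names(entries)))
  if (is.null(entries$media_name)) entries$media_name <- NA_character_
  if (!all(entries$kind %in% c("knockout", "biolog")))
    stop("validation error: kind must be 'knockout' or 'biolog'")
  dup <- duplicated(entries[c("kind", "key")])
  if (any(dup))
    stop("validation error: duplicate phenotype keys: ",
         paste(entries$key[dup], collapse = ", "))
  ko <- entries$kind == "knockout"
  if (any(ko & (is.na(entries$media_name) | !nzchar(entries$media_name))))
    stop("validation error: knockout entries must name a media")
  og <- entries$observed_growth
  entries$observed_growth <- if (is.logical(og)) og else as.integer(og) != 0
  structure(entries[c("kind", "key", "media_name", "observed_growth")],
            class = c("phenotype_set", "data.frame"))
}

#' Read a phenotype set TSV (`kind, key, media_name, observed_growth`)
#' @param path file path.
#' @export
read_phenotype_set <- function(path) {
  phenotype_set(utils::read.delim(path, stringsAsFactors = FALSE,
                                  na.strings = ""))
}

#' Write a phenotype set TSV
#' @param pheno a [phenotype_set].
#' @param path output path.
#' @export
write_phenotype_set <- function(pheno, path) {
  out <- as.data.frame(pheno)
  out$observed_growth <- as.integer(out$observed_growth)
  out$media_name[is.na(out$media_name)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate single-gene knockout lethality
#'
#' @param model a [metabolic_model] that grows on `media` (biomass at
#'   least `threshold`); otherwise a precondition error instructs to gap
#'   fill first.
#' @param media assay medium.
#' @param genes gene ids to knock out, one at a time.
#' @param threshold growth threshold, /hr (default 1e-9).
#' @return named logical vector, gene -> predicted growth.
#' @export
simulate_knockouts <- function(model, media, genes,
                               threshold = GROWTH_THRESHOLD) {
  mm <- apply_media(model, media)
  base <- run_fba(mm)
  if (base$status != "optimal" || base$objective_value < threshold)
    stop("precondition error: model does not grow on media ", media$name,
         "; gap fill the model to this media first")
  gprs <- lapply(mm$reactions$gpr, gpr_parse)
  out <- stats::setNames(logical(length(genes)), genes)
  for (g in genes) {
    off <- vapply(gprs, function(e) !evaluate_gpr(e, g), logical(1))
    m2 <- mm
    m2$reactions$lower_bound[off] <- 0
    m2$reactions$upper_bound[off] <- 0
    fba <- run_fba(m2)
    out[g] <- fba$status == "optimal" && fba$objective_value >= threshold
  }
  out
}

# augment a model with a reversible transporter + exchange for every
# extracellular compound appearing in any of the given media
augment_transporters <- function(model, media_list,
                                 bound = DEFAULT_UPTAKE) {
  compounds <- sort(unique(unlist(lapply(media_list, function(m)
    names(m$uptake_limits)))))
  ex_mets <- vapply(exchange_reactions(model), function(r)
    exchange_metabolite(model, r), character(1))
  for (met_e in compounds) {
    met_c <- sub("_e$", "_c", met_e)
    if (!met_e %in% model$metabolites$id)
      model$metabolites <- rbind(model$metabolites,
        data.frame(id = met_e, name = met_e, compartment = "e",
                   stringsAsFactors = FALSE))
    if (!met_c %in% model$metabolites$id)
      model$metabolites <- rbind(model$metabolites,
        data.frame(id = met_c, name = met_c, compartment = "c",
                   stringsAsFactors = FALSE))
    tid <- paste0("T_biolog_", met_e)
    if (!any(vapply(model$reactions$id, function(r) {
          st <- model$stoichiometry[[r]]
          setequal(names(st), c(met_e, met_c))
        }, logical(1))))
      model <- add_reaction(model, tid,
                            stats::setNames(c(-1, 1), c(met_e, met_c)),
                            lower_bound = -bound, upper_bound = bound)
    if (!met_e %in% ex_mets)
      model <- add_reaction(model, paste0("EX_biolog_", met_e),
                            stats::setNames(-1, met_e),
                            lower_bound = -bound, upper_bound = bound)
  }
  model
}

#' Simulate Biolog-style growth phenotypes
#'
#' @param model a [metabolic_model].
#' @param media_list list of [new_media] objects (one per assay well).
#' @param threshold growth threshold (default 1e-9).
#' @return named logical vector, media name -> predicted growth.  The
#'   transporter augmentation is performed once for the whole batch, so
#'   predictions are independent of media order.
#' @export
simulate_biolog <- function(model, media_list, threshold = GROWTH_THRESHOLD) {
  if (!length(media_list)) return(stats::setNames(logical(), character()))
  model <- augment_transporters(model, media_list)
  out <- stats::setNames(logical(length(media_list)),
                         vapply(media_list, `[[`, character(1), "name"))
  for (k in seq_along(media_list)) {
    mm <- apply_media(model, media_list[[k]])
    fba <- run_fba(mm)
    out[k] <- fba$status == "optimal" && fba$objective_value >= threshold
  }
  out
}

#' Score predictions against observed phenotypes
#'
#' @param predicted named logical vector (from [simulate_knockouts()] or
#'   [simulate_biolog()]); names must cover the phenotype set's keys.
#' @param observed a [phenotype_set] (or data.frame with `key`,
#'   `observed_growth`).
#' @return list of class `phenotype_result`: the 2x2 counts (`tp`, `fp`,
#'   `tn`, `fn`), `sensitivity`, `specificity`, `ppv`, `npv` (each
#'   `NA` when its denominator is zero -- undefined, never reported as
#'   0), and the per-entry table.
#' @export
score_predictions <- function(predicted, observed) {
  obs <- as.data.frame(observed)
  missing <- setdiff(obs$key, names(predicted))
  if (length(missing))
    stop("validation error: no prediction for: ",
         paste(missing, collapse = ", "))
  pred <- predicted[obs$key]
  tp <- sum(obs$observed_growth & pred)
  fn <- sum(obs$observed_growth & !pred)
  tn <- sum(!obs$observed_growth & !pred)
  fp <- sum(!obs$observed_growth & pred)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 ppv = rate(tp, tp + fp),
                 npv = rate(tn, tn + fn),
                 table = data.frame(key = obs$key,
                                    observed = obs$observed_growth,
                                    predicted = unname(pred))),
            class = "phenotype_result")
}

#' @export
print.phenotype_result <- function(x, ...) {
  cat("<phenotype_result> TP", x$tp, "FP", x$fp, "TN", x$tn, "FN", x$fn, "\n",
      sprintf(" sensitivity %.3f specificity %.3f ppv %.3f npv %.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}
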