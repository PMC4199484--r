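#' Run configuration
#'
#' Collects every numeric parameter of the pipeline with its default:
#' pseudocount `PC = 40`, log-score guard `k = 1e-200`, BLAST E-value
#' cutoff `1e-5`, retention fraction `0.8`, growth threshold `1e-9`,
#' minimum target flux `epsilon = 1e-5`, FVA inactivity tolerance
#' `1e-9`, penalties (transporter 25, reversibility 12, low-confidence
#' database 5), initial solver time limit and its `t_max` cap, and the
#' RNG seed.  Overrides are recorded in output provenance.
#'
#' @param ... overrides of the defaults listed above.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(PC = 40, k = 1e-200, e_cutoff = 1e-5, retain_fraction = 0.8,
              growth_threshold = 1e-9, epsilon = 1e-5, inactivity_tol = 1e-9,
              transporter_penalty = 25, reversibility_penalty = 12,
              low_confidence_penalty = 5,
              time_limit = 600, t_max = 86400, seed = 1,
              default_uptake = 100, prune = TRUE,
              minimal_media = "minimal_glc")
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("usage error: unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  cfg$overridden <- names(overrides)
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

config_penalties <- function(cfg)
  gapfill_penalties(transporter = cfg$transporter_penalty,
                    unfavorable_reversibility = cfg$reversibility_penalty,
                    low_confidence_db = cfg$low_confidence_penalty)

solution_to_list <- function(sol) {
  if (isTRUE(sol$failed))
    return(list(target = sol$target, failed = TRUE, message = sol$message))
  list(target = sol$target, media = sol$media_name, mode = sol$mode,
       objective = sol$objective_value, status = sol$solver_status,
       added = sol$added[c("reaction_id", "direction", "cost",
                           "likelihood", "gpr")],
       reversed = sol$reversed)
}

#' Run a complete gap-filling workflow
#'
#' Executes one of the four workflows on file inputs: (likelihood
#' modes) compute reaction likelihoods; targeted gap filling of biomass
#' on complete media; (iterative modes) iterative gap filling plus
#' reaction sensitivity and pruning; targeted gap filling on the
#' configured minimal medium; then writes the final model, the solution
#' list and a provenance-stamped report.
#'
#' @param name one of `"targeted-parsimony"`, `"targeted-likelihood"`,
#'   `"iterative-parsimony"`, `"iterative-likelihood"`.
#' @param inputs named list of paths: `model` (draft), `universal`,
#'   `media_dir` (directory of media TSVs, containing
#'   `<minimal_media>.tsv`), and for likelihood modes either
#'   `likelihoods` (TSV) or `blast` + `reference` + `template_dir`.
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return (invisibly) list with the final `model`, `solutions`, and
#'   the path of the written report.
#' @export
run_workflow <- function(name, inputs, out_dir, config = run_config()) {
  name <- match.arg(name, c("targeted-parsimony", "targeted-likelihood",
                            "iterative-parsimony", "iterative-likelihood"))
  mode <- if (grepl("likelihood", name)) "likelihood" else "parsimony"
  iterative <- grepl("iterative", name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- "read-inputs"
  result <- tryCatch({
    draft <- read_model(inputs$model)
    universal <- read_model(inputs$universal)
    rxn_lik <- NULL
    if (mode == "likelihood") {
      stage <- "likelihoods"
      rxn_lik <- if (!is.null(inputs$likelihoods)) {
        read_reaction_likelihoods(inputs$likelihoods)
      } else {
        hits <- read_blast_table(inputs$blast, e_cutoff = config$e_cutoff)
        ref <- read_reference_db(inputs$reference)
        tpl <- read_template(
          file.path(inputs$template_dir, "annotation_roles.tsv"),
          file.path(inputs$template_dir, "complex_roles.tsv"),
          file.path(inputs$template_dir, "complex_reactions.tsv"))
        compute_likelihoods(hits, ref, tpl, PC = config$PC, k = config$k,
                            retain_fraction = config$retain_fraction)
      }
      write_reaction_likelihoods(rxn_lik, file.path(out_dir, "likelihoods.tsv"))
    }
    costs <- compute_costs(universal, draft, rxn_lik,
                           pen = config_penalties(config), mode = mode)
    solutions <- list()
    stage <- "targeted-complete"
    cm <- complete_media(draft, config$default_uptake)
    sol <- gapfill_target(draft, universal, costs, draft$biomass_reaction_id,
                          cm, time_limit = config$time_limit,
                          t_max = config$t_max, epsilon = config$epsilon)
    model <- integrate_solution(draft, sol, rxn_lik)
    solutions[[length(solutions) + 1L]] <- sol
    if (iterative) {
      stage <- "iterative"
      costs <- compute_costs(universal, model, rxn_lik,
                             pen = config_penalties(config), mode = mode)
      it <- iterative_gapfill(model, universal, costs, cm,
                              inactivity_tol = config$inactivity_tol,
                              time_limit = config$time_limit)
      model <- it$model
      solutions <- c(solutions, it$solutions)
      stage <- "sensitivity-prune"
      gf <- gapfilled_reactions(it$solutions)
      report <- reaction_sensitivity(model, gf, mode, cm,
                                     growth_threshold = config$growth_threshold,
                                     inactivity_tol = config$inactivity_tol)
      if (isTRUE(config$prune))
        model <- prune_noncontributing(model, report, cm,
                                       growth_threshold = config$growth_threshold,
                                       inactivity_tol = config$inactivity_tol)
    } else report <- NULL
    stage <- "targeted-minimal"
    minimal <- read_media(file.path(inputs$media_dir,
                                    paste0(config$minimal_media, ".tsv")))
    costs <- compute_costs(universal, model, rxn_lik,
                           pen = config_penalties(config), mode = mode)
    sol <- gapfill_target(model, universal, costs, model$biomass_reaction_id,
                          minimal, time_limit = config$time_limit,
                          t_max = config$t_max, epsilon = config$epsilon)
    model <- integrate_solution(model, sol, rxn_lik)
    solutions[[length(solutions) + 1L]] <- sol
    stage <- "write-outputs"
    write_model(model, file.path(out_dir, "model.json"), "json", sidecar = TRUE)
    jsonlite::write_json(lapply(solutions, solution_to_list),
                         file.path(out_dir, "solutions.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep_list <- list(
      workflow = name, mode = mode,
      provenance = list(config = unclass(config),
                        config_hash = config_hash(config),
                        seed = config$seed),
      n_solutions = length(solutions),
      sensitivity = if (!is.null(report))
        lapply(seq_len(nrow(report)), function(i)
          list(reaction_id = report$reaction_id[i],
               essential = report$essential[i],
               activated = report$activated[[i]],
               non_contributing = report$non_contributing[i])))
    jsonlite::write_json(rep_list, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(model = model, solutions = solutions,
         report = file.path(out_dir, "report.json"))
  }, error = function(e) {
    stop("workflow stage [", stage, "]: ", conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
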