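#' Model readers and writers
#'
#' Two on-disk formats are supported.
#'
#' **JSON dialect** (defined by this package): one object with fields
#' `id`, `biomass_reaction_id`, `metabolites` (array of `{id, name,
#' compartment}`) and `reactions` (array of `{id, name, lower_bound,
#' upper_bound, gpr, delta_g, is_transporter, source_confidence,
#' priority_class, stoichiometry}` where `stoichiometry` maps metabolite
#' id to signed coefficient and `delta_g` is `null` when unknown).
#'
#' **SBML** Level 3 Version 1 with fbc-style flux bounds (per-reaction
#' bound parameters), gene-product associations (`fbc:and` / `fbc:or` /
#' `fbc:geneProductRef`) and an active biomass objective.  SBML cannot
#' carry the gap-filling attributes (`delta_g`, `source_confidence`,
#' `priority_class`), so [write_model()] emits a sidecar attribute TSV
#' `<path>.attrs.tsv` which [read_model()] picks up automatically; a
#' sidecar can also be named explicitly for either format.  The sidecar
#' header is `reaction_id, delta_g, is_transporter, source_confidence,
#' priority_class`; missing entries default to unknown delta-G,
#' compartment-inferred transporter flag, high confidence and class
#' `"other"`.
#'
#' @name model_io
NULL

#' Read a metabolic model
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"` (default: from file extension,
#'   `.xml`/`.sbml` meaning SBML).
#' @param sidecar optional path to a reaction attribute TSV; default
#'   `<path>.attrs.tsv` if that file exists.
#' @return a validated [metabolic_model].
#' @export
read_model <- function(path, format = c("auto", "json", "sbml"), sidecar = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  model <- switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
  if (is.null(sidecar)) {
    cand <- paste0(path, ".attrs.tsv")
    if (file.exists(cand)) sidecar <- cand
  }
  if (!is.null(sidecar)) model <- apply_sidecar(model, sidecar)
  validate_model(model)
}

#' Write a metabolic model
#'
#' @param model a [metabolic_model].
#' @param path output file path.
#' @param format `"json"` or `"sbml"`.
#' @param sidecar write the attribute sidecar TSV next to the model file
#'   (`<path>.attrs.tsv`)?  Default `TRUE` for SBML (which cannot hold
#'   the attributes inline), `FALSE` for JSON.
#' @export
write_model <- function(model, path, format = c("json", "sbml"), sidecar = NULL) {
  format <- match.arg(format)
  model <- validate_model(model)
  if (is.null(sidecar)) sidecar <- format == "sbml"
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  if (sidecar) write_sidecar(model, paste0(path, ".attrs.tsv"))
  invisible(path)
}

model_to_list <- function(model) {
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[r$id]]
    list(id = r$id, name = r$name,
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gpr = r$gpr,
         delta_g = if (is.na(r$delta_g)) NULL else r$delta_g,
         is_transporter = r$is_transporter,
         source_confidence = r$source_confidence,
         priority_class = r$priority_class,
         stoichiometry = as.list(st))
  })
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i)
    as.list(model$metabolites[i, c("id", "name", "compartment")]))
  list(id = model$id, biomass_reaction_id = model$biomass_reaction_id,
       metabolites = mets, reactions = rxns)
}

write_model_json <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
}

read_model_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path),
                error = function(e) stop("format error: invalid JSON in ",
                                         path, ": ", conditionMessage(e)))
  for (f in c("metabolites", "reactions", "biomass_reaction_id"))
    if (is.null(x[[f]]))
      stop("validation error: JSON model missing field ", sQuote(f))
  mets <- do.call(rbind, lapply(x$metabolites, function(m)
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "",
               stringsAsFactors = FALSE)))
  rxns <- reaction_defaults(length(x$reactions))
  stoich <- list()
  for (i in seq_along(x$reactions)) {
    r <- x$reactions[[i]]
    rxns$id[i] <- r$id
    rxns$name[i] <- r$name %||% r$id
    rxns$lower_bound[i] <- as.numeric(r$lower_bound)
    rxns$upper_bound[i] <- as.numeric(r$upper_bound)
    rxns$gpr[i] <- r$gpr %||% ""
    rxns$delta_g[i] <- if (is.null(r$delta_g)) NA_real_ else as.numeric(r$delta_g)
    rxns$is_transporter[i] <- isTRUE(r$is_transporter)
    rxns$source_confidence[i] <- r$source_confidence %||% "high"
    rxns$priority_class[i] <- r$priority_class %||% "other"
    stoich[[r$id]] <- unlist(r$stoichiometry)
  }
  new_model(x$id %||% basename(path), mets, rxns, stoich,
            x$biomass_reaction_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- sidecar attribute TSV ------------------------------------------------

#' Write the reaction attribute sidecar TSV
#' @param model a [metabolic_model].
#' @param path output path.
#' @export
write_sidecar <- function(model, path) {
  r <- model$reactions
  out <- data.frame(reaction_id = r$id,
                    delta_g = ifelse(is.na(r$delta_g), "", format(r$delta_g)),
                    is_transporter = as.integer(r$is_transporter),
                    source_confidence = r$source_confidence,
                    priority_class = r$priority_class,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

apply_sidecar <- function(model, path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("reaction_id", "delta_g", "is_transporter",
            "source_confidence", "priority_class")
  if (!all(need %in% names(tab)))
    stop("format error: sidecar ", path, " must have columns ",
         paste(need, collapse = ", "))
  i <- match(tab$reaction_id, model$reactions$id)
  known <- !is.na(i)
  i <- i[known]; tab <- tab[known, , drop = FALSE]
  dg <- suppressWarnings(as.numeric(tab$delta_g))
  model$reactions$delta_g[i] <- dg
  model$reactions$is_transporter[i] <- tab$is_transporter %in% c("1", "TRUE", "true")
  model$reactions$source_confidence[i] <- tab$source_confidence
  model$reactions$priority_class[i] <- tab$priority_class
  model
}

## ---- media TSV ------------------------------------------------------------

#' Read a media definition TSV
#'
#' Header `compound_id, max_uptake`.  A single row whose `compound_id` is
#' `*` denotes complete media (all transportable compounds available).
#'
#' @param path file path.
#' @param name media name; defaults to the file name without extension.
#' @return a [new_media] object.
#' @export
read_media <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "max_uptake") %in% names(tab)))
    stop("format error: media TSV needs columns compound_id, max_uptake")
  if (nrow(tab) == 1 && tab$compound_id[1] == "*")
    return(new_media(name, complete = TRUE))
  new_media(name, stats::setNames(as.numeric(tab$max_uptake), tab$compound_id))
}

#' Write a media definition TSV
#' @param media a [new_media] object.
#' @param path output path.
#' @export
write_media <- function(media, path) {
  tab <- if (media$complete)
    data.frame(compound_id = "*", max_uptake = 100)
  else
    data.frame(compound_id = names(media$uptake_limits),
               max_uptake = unname(media$uptake_limits))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- SBML -----------------------------------------------------------------

sbml_id <- function(prefix, id) paste0(prefix, gsub("[^A-Za-z0-9_]", "_", id))

write_model_sbml <- function(model, path) {
  ns_sbml <- "http://www.sbml.org/sbml/level3/version1/core"
  ns_fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root("sbml",
    xmlns = ns_sbml, "xmlns:fbc" = ns_fbc,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_id("", model$id),
                             "fbc:strict" = "false")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in unique(model$metabolites$compartment))
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")
  sp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml2::xml_add_child(sp, "species", id = sbml_id("M_", m$id),
                        name = m$name, compartment = m$compartment,
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  genes <- sort(unique(unlist(lapply(model$reactions$gpr, gpr_genes))))
  gp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in genes)
    xml2::xml_add_child(gp, "fbc:geneProduct", "fbc:id" = sbml_id("G_", g),
                        "fbc:label" = g)
  rl <- xml2::xml_add_child(mdl, "listOfReactions")
  add_assoc <- function(parent, node) {
    if (is.character(node)) {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = sbml_id("G_", node))
    } else {
      sub <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
      for (a in node$args) add_assoc(sub, a)
    }
  }
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rid <- sbml_id("R_", r$id)
    lbid <- paste0(rid, "_lb"); ubid <- paste0(rid, "_ub")
    xml2::xml_add_child(pars, "parameter", id = lbid,
                        value = format(r$lower_bound, digits = 17),
                        constant = "true")
    xml2::xml_add_child(pars, "parameter", id = ubid,
                        value = format(r$upper_bound, digits = 17),
                        constant = "true")
    rx <- xml2::xml_add_child(rl, "reaction", id = rid, name = r$name,
                              reversible = tolower(r$lower_bound < 0),
                              fast = "false",
                              "fbc:lowerFluxBound" = lbid,
                              "fbc:upperFluxBound" = ubid)
    st <- model$stoichiometry[[r$id]]
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in names(reac))
        xml2::xml_add_child(lr, "speciesReference",
                            species = sbml_id("M_", m),
                            stoichiometry = format(-reac[[m]], digits = 17),
                            constant = "true")
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in names(prod))
        xml2::xml_add_child(lp, "speciesReference",
                            species = sbml_id("M_", m),
                            stoichiometry = format(prod[[m]], digits = 17),
                            constant = "true")
    }
    g <- gpr_parse(r$gpr)
    if (!is.null(g)) {
      assoc <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      add_assoc(assoc, g)
    }
  }
  objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  fl <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(fl, "fbc:fluxObjective",
                      "fbc:reaction" = sbml_id("R_", model$biomass_reaction_id),
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("format error: invalid XML in ",
                                           path, ": ", conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  mdl <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(mdl, "xml_missing"))
    stop("format error: no <model> element in ", path)
  strip <- function(ids, prefix) sub(paste0("^", prefix), "", ids)
  spn <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = strip(xml2::xml_attr(spn, "id"), "M_"),
    name = xml2::xml_attr(spn, "name"),
    compartment = xml2::xml_attr(spn, "compartment"),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  parn <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(parn, "value")),
                          xml2::xml_attr(parn, "id"))
  # gene product id -> label
  gpn <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  glab <- stats::setNames(xml2::xml_attr(gpn, "label"),
                          xml2::xml_attr(gpn, "id"))
  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      lab <- glab[[ref]]
      return(if (is.null(lab) || is.na(lab)) strip(ref, "G_") else lab)
    }
    kids <- xml2::xml_children(node)
    if (nm %in% c("and", "or"))
      return(list(op = nm, args = lapply(kids, parse_assoc)))
    if (length(kids) == 1) return(parse_assoc(kids[[1]]))
    stop("format error: unsupported gene association element <", nm, ">")
  }
  rxnn <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rxns <- reaction_defaults(length(rxnn))
  stoich <- list()
  for (i in seq_along(rxnn)) {
    rn <- rxnn[[i]]
    rid <- strip(xml2::xml_attr(rn, "id"), "R_")
    rxns$id[i] <- rid
    nm <- xml2::xml_attr(rn, "name")
    rxns$name[i] <- if (is.na(nm)) rid else nm
    lb <- pars[[xml2::xml_attr(rn, "lowerFluxBound")]]
    ub <- pars[[xml2::xml_attr(rn, "upperFluxBound")]]
    if (is.null(lb) || is.null(ub))
      stop("format error: reaction ", rid, " lacks fbc flux bound parameters")
    rxns$lower_bound[i] <- lb; rxns$upper_bound[i] <- ub
    st <- numeric()
    for (sr in xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns)) {
      m <- strip(xml2::xml_attr(sr, "species"), "M_")
      st[m] <- -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns)) {
      m <- strip(xml2::xml_attr(sr, "species"), "M_")
      cur <- if (m %in% names(st)) st[[m]] else 0
      st[m] <- cur + as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    stoich[[rid]] <- st
    assoc <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
    if (!inherits(assoc, "xml_missing")) {
      kids <- xml2::xml_children(assoc)
      if (length(kids)) rxns$gpr[i] <- gpr_string(parse_assoc(kids[[1]]))
    }
  }
  fo <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (inherits(fo, "xml_missing"))
    stop("validation error: SBML model lacks an active flux objective (biomass)")
  biomass <- strip(xml2::xml_attr(fo, "reaction"), "R_")
  mid <- xml2::xml_attr(mdl, "id")
  new_model(if (is.na(mid)) basename(path) else mid, mets, rxns, stoich, biomass)
}

## ---- likelihood / evidence tables -----------------------------------------

#' Read a BLAST tabular hit table
#'
#' Accepts a headered TSV with columns `qseqid`, `sseqid`, `evalue`, or a
#' headerless BLAST `-outfmt 6` file (12 columns; columns 1, 2 and 11 are
#' used).  Hits are filtered at the E-value cutoff and de-duplicated,
#' keeping the best E-value per (query, target) pair.
#'
#' @param path file path.
#' @param e_cutoff ingest E-value cutoff (default `1e-5`).
#' @return data.frame with columns `query`, `target`, `evalue`.
#' @export
read_blast_table <- function(path, e_cutoff = 1e-5) {
  first <- readLines(path, n = 1)
  has_header <- grepl("evalue", first)
  tab <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (has_header) {
    tab <- tab[c("qseqid", "sseqid", "evalue")]
  } else {
    if (ncol(tab) < 11)
      stop("format error: headerless BLAST table must be outfmt 6 (>= 11 columns)")
    tab <- tab[c(1, 2, 11)]
  }
  names(tab) <- c("query", "target", "evalue")
  tab$evalue <- as.numeric(tab$evalue)
  blast_hit_table(tab, e_cutoff = e_cutoff)
}

#' Construct/normalize a BLAST hit table
#'
#' @param hits data.frame with columns `query`, `target`, `evalue`.
#' @param e_cutoff E-value cutoff applied on ingest.
#' @return filtered, de-duplicated data.frame (best E-value per pair).
#' @export
blast_hit_table <- function(hits, e_cutoff = 1e-5) {
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  stopifnot(all(c("query", "target", "evalue") %in% names(hits)))
  if (any(hits$evalue < 0)) stop("validation error: negative E-value")
  hits <- hits[hits$evalue <= e_cutoff, , drop = FALSE]
  hits <- hits[order(hits$query, hits$target, hits$evalue), , drop = FALSE]
  hits <- hits[!duplicated(hits[c("query", "target")]), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Read a high-confidence reference annotation TSV
#'
#' Format: `gene_id<TAB>annotation`, header optional.  Annotation strings
#' are normalized (trimmed, internal whitespace collapsed).  Each target
#' gene must map to exactly one annotation.
#'
#' @param path file path.
#' @return named character vector, gene id -> annotation.
#' @export
read_reference_db <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  has_header <- identical(first[1], "gene_id")
  tab <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("gene_id", "annotation")
  reference_db(stats::setNames(tab$annotation, tab$gene_id))
}

#' Construct/normalize a reference annotation database
#' @param ref named character vector, target gene id -> annotation string.
#' @export
reference_db <- function(ref) {
  if (anyDuplicated(names(ref)))
    stop("validation error: reference gene mapped to more than one annotation: ",
         paste(unique(names(ref)[duplicated(names(ref))]), collapse = ", "))
  stats::setNames(normalize_annotation(ref), names(ref))
}

normalize_annotation <- function(x) gsub("[[:space:]]+", " ", trimws(x))

#' Biochemistry template (annotation -> role -> complex -> reaction)
#'
#' @param annotation_roles data.frame `annotation`, `role` (multimap).
#' @param complex_roles data.frame `complex`, `role`.
#' @param complex_reactions data.frame `complex`, `reaction`.
#' @return object of class `biochem_template`; roles used by complexes
#'   that no annotation maps to are flagged in `$orphan_roles`.
#' @export
new_template <- function(annotation_roles, complex_roles, complex_reactions) {
  annotation_roles <- as.data.frame(annotation_roles, stringsAsFactors = FALSE)
  complex_roles <- as.data.frame(complex_roles, stringsAsFactors = FALSE)
  complex_reactions <- as.data.frame(complex_reactions, stringsAsFactors = FALSE)
  stopifnot(all(c("annotation", "role") %in% names(annotation_roles)),
            all(c("complex", "role") %in% names(complex_roles)),
            all(c("complex", "reaction") %in% names(complex_reactions)))
  annotation_roles$annotation <- normalize_annotation(annotation_roles$annotation)
  orphan <- setdiff(complex_roles$role, annotation_roles$role)
  structure(list(annotation_roles = unique(annotation_roles),
                 complex_roles = unique(complex_roles),
                 complex_reactions = unique(complex_reactions),
                 orphan_roles = orphan),
            class = "biochem_template")
}

#' Read a biochemistry template from its three TSVs
#'
#' @param annotation_roles_path TSV with header `annotation, role`.
#' @param complex_roles_path TSV with header `complex, role`.
#' @param complex_reactions_path TSV with header `complex, reaction`.
#' @export
read_template <- function(annotation_roles_path, complex_roles_path,
                          complex_reactions_path) {
  rd <- function(p) utils::read.delim(p, stringsAsFactors = FALSE)
  new_template(rd(annotation_roles_path), rd(complex_roles_path),
               rd(complex_reactions_path))
}

#' Write a biochemistry template to three TSVs
#' @param template a [new_template] object.
#' @param dir output directory; files `annotation_roles.tsv`,
#'   `complex_roles.tsv`, `complex_reactions.tsv` are created.
#' @export
write_template <- function(template, dir) {
  wr <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(template$annotation_roles, "annotation_roles.tsv")
  wr(template$complex_roles, "complex_roles.tsv")
  wr(template$complex_reactions, "complex_reactions.tsv")
  invisible(dir)
}

#' Write reaction likelihoods to TSV (`reaction_id, likelihood, gpr`)
#' @param rxn_lik a `reaction_likelihoods` object.
#' @param path output path.
#' @export
write_reaction_likelihoods <- function(rxn_lik, path) {
  utils::write.table(
    data.frame(reaction_id = rxn_lik$reaction_id,
               likelihood = rxn_lik$likelihood, gpr = rxn_lik$gpr),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read reaction likelihoods from TSV
#' @param path TSV written by [write_reaction_likelihoods()].
#' @export
read_reaction_likelihoods <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "numeric", "character"))
  tab$gpr[is.na(tab$gpr)] <- ""
  structure(tab, class = c("reaction_likelihoods", "data.frame"))
}
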