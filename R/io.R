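#' Model file input/output
#'
#' Two dialects are supported: the community COBRA JSON schema
#' (`metabolites`/`reactions`/`genes` arrays; read and write) and SBML
#' Level 3 with the FBC extension (read). GPR strings are parsed into rule
#' trees on load. The biomass reaction is taken from the objective
#' coefficients; the carbon-source and product reactions have no standard
#' slot in either format, so they are accepted as arguments or (for files
#' this package wrote) from a `moeko` extension block in the JSON.
#'
#' @name model_io
NULL

#' Read a metabolic model
#'
#' @param path File path.
#' @param dialect `"cobra-json"` or `"sbml-fbc"` (`"auto"` guesses from the
#'   file extension).
#' @param biomass_reaction,carbon_source_exchange,product_reaction Reaction
#'   ids; when `NULL`, the biomass reaction is inferred from the objective,
#'   and the others from the file's `moeko` block (JSON) or left to error
#'   if unavailable.
#' @param gene_chromosome Optional named character map gene -> chromosome.
#' @return A validated `stoich_model`.
#' @export
read_model <- function(path, dialect = c("auto", "cobra-json", "sbml-fbc"),
                       biomass_reaction = NULL,
                       carbon_source_exchange = NULL,
                       product_reaction = NULL,
                       gene_chromosome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("model file not found: '%s'", path),
                               call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml-fbc" else "cobra-json"
  }
  switch(dialect,
    `cobra-json` = read_model_json(path, biomass_reaction,
                                   carbon_source_exchange, product_reaction,
                                   gene_chromosome),
    `sbml-fbc` = read_model_sbml(path, biomass_reaction,
                                 carbon_source_exchange, product_reaction,
                                 gene_chromosome)
  )
}

read_model_json <- function(path, biomass_reaction, carbon_source_exchange,
                            product_reaction, gene_chromosome) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("malformed JSON in '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  for (part in c("metabolites", "reactions", "genes")) {
    if (is.null(doc[[part]])) {
      stop(sprintf("malformed model '%s': missing '%s' array", path, part),
           call. = FALSE)
    }
  }
  mets <- vapply(doc$metabolites, function(m) as.character(m$id), character(1))
  genes <- vapply(doc$genes, function(g) as.character(g$id), character(1))
  rids <- vapply(doc$reactions, function(r) as.character(r$id), character(1))

  n <- length(rids)
  S <- Matrix::Matrix(0, length(mets), n, sparse = TRUE,
                      dimnames = list(mets, rids))
  lb <- ub <- obj <- numeric(n)
  gpr <- list()
  for (j in seq_len(n)) {
    r <- doc$reactions[[j]]
    st <- unlist(r$metabolites)
    if (length(st)) {
      idx <- match(names(st), mets)
      if (anyNA(idx)) {
        stop(sprintf("reaction '%s' references unknown metabolite '%s'",
                     r$id, names(st)[which(is.na(idx))[1]]), call. = FALSE)
      }
      S[idx, j] <- as.numeric(st)
    }
    lb[j] <- as.numeric(r$lower_bound %||% -1000)
    ub[j] <- as.numeric(r$upper_bound %||% 1000)
    obj[j] <- as.numeric(r$objective_coefficient %||% 0)
    gtext <- r$gene_reaction_rule %||% ""
    if (nzchar(trimws(gtext))) {
      rule <- parse_gpr(gtext)
      bad <- setdiff(gpr_genes(rule), genes)
      if (length(bad)) {
        stop(sprintf("reaction '%s' GPR references unknown gene '%s'",
                     r$id, bad[1]), call. = FALSE)
      }
      gpr[[r$id]] <- rule
    }
  }

  ext <- doc$moeko %||% list()
  biomass_reaction <- biomass_reaction %||% ext$biomass_reaction %||% {
    hit <- which(obj != 0)
    if (length(hit) != 1L) {
      stop("cannot infer biomass reaction: supply biomass_reaction=",
           call. = FALSE)
    }
    rids[hit]
  }
  carbon_source_exchange <- carbon_source_exchange %||%
    ext$carbon_source_exchange %||%
    stop("carbon_source_exchange not given and not recorded in the file",
         call. = FALSE)
  product_reaction <- product_reaction %||% ext$product_reaction %||%
    stop("product_reaction not given and not recorded in the file",
         call. = FALSE)
  gene_chromosome <- gene_chromosome %||%
    (if (!is.null(ext$gene_chromosome))
       unlist(ext$gene_chromosome) else NULL)

  stoich_model(mets, rids, S, lb, ub, obj, genes = genes, gpr = gpr,
               biomass_reaction = biomass_reaction,
               carbon_source_exchange = carbon_source_exchange,
               product_reaction = product_reaction,
               gene_chromosome = gene_chromosome,
               id = doc$id %||% basename(path))
}

#' Write a model as COBRA JSON
#'
#' Emits the community schema plus a `moeko` block recording the
#' carbon-source/product designations and gene-chromosome map, so
#' `read_model()` round-trips to an equal model.
#'
#' @param model A `stoich_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  rxns <- lapply(seq_along(model$reaction_ids), function(j) {
    rid <- model$reaction_ids[j]
    col <- model$S[, j]
    nz <- which(col != 0)
    list(
      id = rid,
      metabolites = as.list(stats::setNames(as.numeric(col[nz]),
                                            model$metabolite_ids[nz])),
      lower_bound = unname(model$lb[j]),
      upper_bound = unname(model$ub[j]),
      objective_coefficient = unname(model$obj[j]),
      gene_reaction_rule = format_gpr(model$gpr[[rid]])
    )
  })
  doc <- list(
    id = model$id,
    metabolites = lapply(model$metabolite_ids, function(m) list(id = m)),
    reactions = rxns,
    genes = lapply(model$genes, function(g) list(id = g)),
    moeko = list(
      biomass_reaction = model$biomass_reaction,
      carbon_source_exchange = model$carbon_source_exchange,
      product_reaction = model$product_reaction,
      gene_chromosome = as.list(model$gene_chromosome %||% list())
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# --- SBML Level 3 + FBC (read-only subset) ----------------------------------

read_model_sbml <- function(path, biomass_reaction, carbon_source_exchange,
                            product_reaction, gene_chromosome) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop(sprintf("malformed SBML in '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id"))

  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  mets <- xml2::xml_attr(species, "id")[!boundary]

  gps <- xml2::xml_find_all(
    doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_ids <- xml2::xml_attr(gps, "id")
  gp_labels <- xml2::xml_attr(gps, "label")
  gp_labels[is.na(gp_labels)] <- gp_ids[is.na(gp_labels)]
  gp_map <- stats::setNames(gp_labels, gp_ids)

  rnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rids <- xml2::xml_attr(rnodes, "id")
  n <- length(rids)
  if (n == 0L) stop(sprintf("no reactions in SBML file '%s'", path),
                    call. = FALSE)
  S <- Matrix::Matrix(0, length(mets), n, sparse = TRUE,
                      dimnames = list(mets, rids))
  lb <- ub <- numeric(n)
  gpr <- list()
  for (j in seq_len(n)) {
    rn <- rnodes[[j]]
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "s:listOfReactants" else "s:listOfProducts"
      refs <- xml2::xml_find_all(rn, paste0("./", tag, "/s:speciesReference"),
                                 ns)
      for (ref in refs) {
        sp <- xml2::xml_attr(ref, "species")
        coef <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
        if (is.na(coef)) coef <- 1
        i <- match(sp, mets)
        if (!is.na(i)) S[i, j] <- S[i, j] + side * coef
        # boundary species are dropped: their rows are unconstrained
      }
    }
    lbref <- xml2::xml_attr(rn, "lowerFluxBound")
    ubref <- xml2::xml_attr(rn, "upperFluxBound")
    lb[j] <- if (!is.na(lbref) && lbref %in% names(pvals)) pvals[[lbref]]
             else -1000
    ub[j] <- if (!is.na(ubref) && ubref %in% names(pvals)) pvals[[ubref]]
             else 1000
    gnode <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
    if (!inherits(gnode, "xml_missing")) {
      child <- xml2::xml_find_first(gnode, "./*")
      rule <- sbml_gpr_tree(child, gp_map, ns)
      if (!is.null(rule)) gpr[[rids[j]]] <- rule
    }
  }
  genes <- unname(gp_map)

  # objective from the active fbc objective list
  obj <- numeric(n)
  fluxobjs <- xml2::xml_find_all(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  for (fo in fluxobjs) {
    rid <- xml2::xml_attr(fo, "reaction")
    coef <- as.numeric(xml2::xml_attr(fo, "coefficient"))
    if (is.na(coef)) coef <- 1
    i <- match(rid, rids)
    if (!is.na(i)) obj[i] <- coef
  }

  biomass_reaction <- biomass_reaction %||% {
    hit <- which(obj != 0)
    if (length(hit) != 1L) {
      stop("cannot infer biomass reaction from SBML objectives",
           call. = FALSE)
    }
    rids[hit]
  }
  if (is.null(carbon_source_exchange) || is.null(product_reaction)) {
    stop("SBML carries no carbon-source/product designation: pass carbon_source_exchange= and product_reaction=",
         call. = FALSE)
  }
  mid <- xml2::xml_attr(xml2::xml_find_first(doc, ".//s:model", ns), "id")
  stoich_model(mets, rids, S, lb, ub, obj, genes = genes, gpr = gpr,
               biomass_reaction = biomass_reaction,
               carbon_source_exchange = carbon_source_exchange,
               product_reaction = product_reaction,
               gene_chromosome = gene_chromosome,
               id = if (is.na(mid)) basename(path) else mid)
}

sbml_gpr_tree <- function(node, gp_map, ns) {
  if (is.null(node) || inherits(node, "xml_missing")) return(NULL)
  name <- xml2::xml_name(node)
  if (name == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    label <- if (gid %in% names(gp_map)) gp_map[[gid]] else gid
    return(gpr_literal(label))
  }
  if (name %in% c("and", "or")) {
    kids <- lapply(xml2::xml_find_all(node, "./*"), sbml_gpr_tree,
                   gp_map = gp_map, ns = ns)
    kids <- Filter(Negate(is.null), kids)
    if (length(kids) == 1L) return(kids[[1]])
    return(gpr_node(name, kids))
  }
  stop(sprintf("unsupported geneProductAssociation element '%s'", name),
       call. = FALSE)
}
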