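#' Stoichiometric metabolic models
#'
#' A `stoich_model` holds the standard constraint-based representation of a
#' metabolic network: the sparse stoichiometric matrix S (m metabolites x
#' n reactions), per-reaction flux bounds lb/ub (mmol gDW^-1 h^-1), linear
#' objective weights c (usually an indicator of the biomass reaction), the
#' gene list, per-reaction GPR rules, and bookkeeping identifiers for the
#' biomass, carbon-source exchange and product reactions. Models are
#' immutable values: every mutation-like operation returns a modified copy.
#'
#' Sign convention for exchange reactions: uptake is negative, secretion is
#' positive. A glucose exchange flux of -10 means 10 mmol gDW^-1 h^-1 of
#' glucose enters the cell.
#'
#' @param metabolite_ids,reaction_ids Character vectors of identifiers.
#' @param S Stoichiometric matrix, m x n (anything coercible to a sparse
#'   `Matrix::dgCMatrix`).
#' @param lb,ub Numeric flux bounds, length n.
#' @param obj Numeric objective weights, length n.
#' @param genes Character vector of gene identifiers.
#' @param gpr Named list (by reaction id) of `gpr_rule` trees; reactions
#'   absent from the list carry no rule and are always active.
#' @param biomass_reaction,carbon_source_exchange,product_reaction Reaction
#'   identifiers (must be members of `reaction_ids`).
#' @param gene_chromosome Optional named character vector mapping gene id to
#'   chromosome label, for models whose identifiers do not encode the locus.
#' @param pathways Optional named list of [pathway_definition()] objects
#'   available for knock-in by a [strain_design()].
#' @param id Model identifier string.
#' @return A validated `stoich_model`.
#' @export
stoich_model <- function(metabolite_ids, reaction_ids, S, lb, ub, obj,
                         genes = character(), gpr = list(),
                         biomass_reaction, carbon_source_exchange,
                         product_reaction,
                         gene_chromosome = NULL, pathways = list(),
                         id = "model") {
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "dMatrix"),
                   "CsparseMatrix")
  dimnames(S) <- list(metabolite_ids, reaction_ids)
  m <- structure(list(
    id = id,
    metabolite_ids = as.character(metabolite_ids),
    reaction_ids = as.character(reaction_ids),
    S = S,
    lb = stats::setNames(as.numeric(lb), reaction_ids),
    ub = stats::setNames(as.numeric(ub), reaction_ids),
    obj = stats::setNames(as.numeric(obj), reaction_ids),
    genes = as.character(genes),
    gpr = gpr,
    biomass_reaction = biomass_reaction,
    carbon_source_exchange = carbon_source_exchange,
    product_reaction = product_reaction,
    gene_chromosome = gene_chromosome,
    pathways = pathways,
    knockins_applied = character()
  ), class = "stoich_model")
  validate_model(m)
  m
}

#' Validate a stoichiometric model's invariants
#'
#' Checks matrix dimensions (m rows, n columns, m < n: reconstructions have
#' more reactions than metabolites), `lb <= ub` elementwise, membership of
#' the designated reactions, and that every gene referenced by a GPR rule is
#' in the gene list.
#'
#' @param model A `stoich_model`.
#' @return The model, invisibly; errors on any violation.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "stoich_model"))
  m <- length(model$metabolite_ids); n <- length(model$reaction_ids)
  if (m == 0L || n == 0L) stop("degenerate model: no metabolites or reactions")
  if (!all(dim(model$S) == c(m, n))) {
    stop(sprintf("S must be %d x %d, got %d x %d", m, n,
                 nrow(model$S), ncol(model$S)))
  }
  if (m >= n) {
    stop(sprintf("expected m < n (more reactions than metabolites), got m=%d n=%d",
                 m, n))
  }
  if (anyDuplicated(model$reaction_ids)) stop("duplicate reaction ids")
  if (anyDuplicated(model$metabolite_ids)) stop("duplicate metabolite ids")
  if (length(model$lb) != n || length(model$ub) != n || length(model$obj) != n) {
    stop("lb, ub and obj must have one entry per reaction")
  }
  if (any(model$lb > model$ub + 1e-12)) {
    bad <- model$reaction_ids[which(model$lb > model$ub + 1e-12)[1]]
    stop(sprintf("lb > ub for reaction '%s'", bad))
  }
  for (field in c("biomass_reaction", "carbon_source_exchange",
                  "product_reaction")) {
    rid <- model[[field]]
    if (!is.character(rid) || length(rid) != 1L ||
        !(rid %in% model$reaction_ids)) {
      stop(sprintf("%s ('%s') is not a reaction of the model", field,
                   as.character(rid)[1]))
    }
  }
  if (length(model$gpr)) {
    unknown_rxn <- setdiff(names(model$gpr), model$reaction_ids)
    if (length(unknown_rxn)) {
      stop(sprintf("GPR given for unknown reaction '%s'", unknown_rxn[1]))
    }
    referenced <- unique(unlist(lapply(model$gpr, gpr_genes)))
    missing <- setdiff(referenced, model$genes)
    if (length(missing)) {
      stop(sprintf("GPR references gene '%s' absent from the gene list",
                   missing[1]))
    }
  }
  invisible(model)
}

#' @export
print.stoich_model <- function(x, ...) {
  cat(sprintf("<stoich_model> %s: %d metabolites x %d reactions, %d genes\n",
              x$id, length(x$metabolite_ids), length(x$reaction_ids),
              length(x$genes)))
  cat(sprintf("  biomass: %s | carbon source: %s | product: %s\n",
              x$biomass_reaction, x$carbon_source_exchange,
              x$product_reaction))
  if (length(x$knockins_applied)) {
    cat("  knock-ins applied:", paste(x$knockins_applied, collapse = ", "), "\n")
  }
  invisible(x)
}

#' A candidate strain: gene deletions plus knock-in pathway flags
#'
#' The MOEA's individual. Genes in `deletions` are state 0 (knocked out);
#' all other model genes are state 1. `knockins` names pathways (registered
#' on the model) whose reactions are added before knockouts are applied.
#'
#' @param deletions Character vector of gene ids to knock out.
#' @param knockins Character vector of pathway ids to enable.
#' @return A `strain_design`.
#' @export
strain_design <- function(deletions = character(), knockins = character()) {
  structure(list(deletions = sort(unique(as.character(deletions))),
                 knockins = sort(unique(as.character(knockins)))),
            class = "strain_design")
}

#' @export
print.strain_design <- function(x, ...) {
  cat(sprintf("<strain_design> %d deletion(s)%s\n", length(x$deletions),
              if (length(x$knockins))
                paste0(", knock-ins: ", paste(x$knockins, collapse = ","))
              else ""))
  if (length(x$deletions)) cat(" ", paste(x$deletions, collapse = ", "), "\n")
  invisible(x)
}

design_key <- function(design) {
  paste(paste(design$deletions, collapse = ","),
        paste(design$knockins, collapse = ","), sep = "|")
}

validate_design <- function(model, design, max_deletions = Inf) {
  stopifnot(inherits(design, "strain_design"))
  all_genes <- model$genes
  for (ki in design$knockins) {
    if (!(ki %in% names(model$pathways))) {
      stop(sprintf("unknown knock-in pathway '%s'", ki))
    }
    all_genes <- c(all_genes, model$pathways[[ki]]$new_genes)
  }
  unknown <- setdiff(design$deletions, all_genes)
  if (length(unknown)) {
    stop(sprintf("deletion of unknown gene '%s'", unknown[1]))
  }
  if (length(design$deletions) > max_deletions) {
    stop(sprintf("design has %d deletions, maximum is %d",
                 length(design$deletions), max_deletions))
  }
  invisible(design)
}

#' Define a heterologous knock-in pathway
#'
#' Describes reactions, genes and metabolites to be grafted onto a model,
#' mirroring the addition of a heterologous product pathway (e.g. a
#' three-gene carotenoid route) to a host network.
#'
#' @param id Pathway identifier.
#' @param new_reactions List of reaction descriptions, each a list with
#'   `id`, `stoichiometry` (named numeric: metabolite -> coefficient),
#'   `lb`, `ub` and optional `gpr` (string or `gpr_rule`).
#' @param new_genes Character vector of genes introduced by the pathway.
#' @param new_metabolites Character vector of metabolites introduced.
#' @return A `pathway_definition`.
#' @export
pathway_definition <- function(id, new_reactions, new_genes = character(),
                               new_metabolites = character()) {
  new_reactions <- lapply(new_reactions, function(r) {
    if (is.character(r$gpr)) r$gpr <- parse_gpr(r$gpr)
    r
  })
  structure(list(id = id, new_reactions = new_reactions,
                 new_genes = as.character(new_genes),
                 new_metabolites = as.character(new_metabolites)),
            class = "pathway_definition")
}

#' Graft a pathway onto a model
#'
#' Adds the pathway's metabolites (rows), reactions (columns), genes and GPR
#' rules. Idempotent: adding an already-applied pathway id is a no-op.
#' Stoichiometries may only reference existing metabolites or the pathway's
#' own `new_metabolites`; a reaction id already present with a different
#' stoichiometry is a conflict error.
#'
#' @param model A `stoich_model`.
#' @param pathway A [pathway_definition()].
#' @return A new `stoich_model` with the pathway applied.
#' @export
add_pathway <- function(model, pathway) {
  stopifnot(inherits(model, "stoich_model"),
            inherits(pathway, "pathway_definition"))
  if (pathway$id %in% model$knockins_applied) return(model)

  known_mets <- c(model$metabolite_ids, pathway$new_metabolites)
  for (r in pathway$new_reactions) {
    bad <- setdiff(names(r$stoichiometry), known_mets)
    if (length(bad)) {
      stop(sprintf("pathway '%s' reaction '%s' references unknown metabolite '%s'",
                   pathway$id, r$id, bad[1]))
    }
    if (r$id %in% model$reaction_ids) {
      old <- model$S[, r$id]
      new <- stats::setNames(numeric(length(model$metabolite_ids)),
                             model$metabolite_ids)
      common <- intersect(names(r$stoichiometry), model$metabolite_ids)
      new[common] <- r$stoichiometry[common]
      if (max(abs(old - new)) > 1e-12 ||
          length(setdiff(names(r$stoichiometry), model$metabolite_ids))) {
        stop(sprintf("reaction '%s' already exists with different stoichiometry",
                     r$id))
      }
    }
  }

  new_mets <- setdiff(pathway$new_metabolites, model$metabolite_ids)
  mets <- c(model$metabolite_ids, new_mets)
  new_rxns <- Filter(function(r) !(r$id %in% model$reaction_ids),
                     pathway$new_reactions)
  rxns <- c(model$reaction_ids, vapply(new_rxns, `[[`, character(1), "id"))

  S <- model$S
  if (length(new_mets)) {
    S <- rbind(S, Matrix::Matrix(0, length(new_mets), ncol(S), sparse = TRUE))
    rownames(S) <- mets
  }
  if (length(new_rxns)) {
    cols <- Matrix::Matrix(0, length(mets), length(new_rxns), sparse = TRUE)
    for (k in seq_along(new_rxns)) {
      st <- new_rxns[[k]]$stoichiometry
      cols[match(names(st), mets), k] <- as.numeric(st)
    }
    S <- cbind(S, cols)
    colnames(S) <- rxns
  }

  lb <- c(model$lb, stats::setNames(
    vapply(new_rxns, function(r) as.numeric(r$lb), numeric(1)),
    vapply(new_rxns, `[[`, character(1), "id")))
  ub <- c(model$ub, stats::setNames(
    vapply(new_rxns, function(r) as.numeric(r$ub), numeric(1)),
    vapply(new_rxns, `[[`, character(1), "id")))
  obj <- c(model$obj, stats::setNames(rep(0, length(new_rxns)),
    vapply(new_rxns, `[[`, character(1), "id")))

  gpr <- model$gpr
  for (r in new_rxns) if (!is.null(r$gpr)) gpr[[r$id]] <- r$gpr

  out <- model
  out$metabolite_ids <- mets
  out$reaction_ids <- rxns
  out$S <- S
  out$lb <- lb; out$ub <- ub; out$obj <- obj
  out$genes <- unique(c(model$genes, pathway$new_genes))
  out$gpr <- gpr
  out$knockins_applied <- c(model$knockins_applied, pathway$id)
  validate_model(out)
  out
}

#' Apply a strain design to a model
#'
#' Knock-in pathways named by the design are grafted first; then every
#' reaction whose GPR rule evaluates inactive under the design's gene states
#' (deleted genes 0, all others 1) has its bounds forced to `lb = ub = 0`,
#' which is how a gene deletion is simulated in constraint-based models.
#' Reactions without a GPR rule are never touched. The input model is not
#' modified.
#'
#' @param model A `stoich_model`.
#' @param design A [strain_design()].
#' @return A new `stoich_model` with the design applied.
#' @export
apply_design <- function(model, design) {
  stopifnot(inherits(model, "stoich_model"))
  validate_design(model, design)
  out <- model
  for (ki in design$knockins) out <- add_pathway(out, model$pathways[[ki]])
  states <- stats::setNames(rep(1L, length(out$genes)), out$genes)
  states[intersect(design$deletions, out$genes)] <- 0L
  for (rid in names(out$gpr)) {
    if (!evaluate_gpr(out$gpr[[rid]], states)) {
      out$lb[rid] <- 0
      out$ub[rid] <- 0
    }
  }
  out
}

#' Genes that a design search may knock out
#'
#' Knockable genes are those appearing in at least one GPR rule (deleting a
#' gene never referenced by a rule cannot change the network) minus any
#' configured essential genes. Knock-in pathway genes are included when the
#' pathway is applied/registered and `include_pathways` is `TRUE`.
#'
#' @param model A `stoich_model`.
#' @param essential Character vector of protected genes.
#' @param knockins Pathway ids whose genes should also be considered.
#' @return Character vector of gene ids.
#' @export
knockable_genes <- function(model, essential = character(),
                            knockins = character()) {
  m <- model
  for (ki in knockins) m <- add_pathway(m, model$pathways[[ki]])
  in_rules <- unique(unlist(lapply(m$gpr, gpr_genes)))
  setdiff(in_rules, essential)
}
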