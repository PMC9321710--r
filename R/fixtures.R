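#' Synthetic toy metabolic models
#'
#' Small hand-designed and randomly generated models with known optima stand
#' in for genome-scale reconstructions so the whole stack (GPR evaluation,
#' LP analyses, MOEA search) is testable with no downloads. The core model
#' emulates the structure that makes strain design non-trivial in real
#' hosts: a carbon uptake step gated by an essential enzyme complex,
#' parallel carbon-conversion routes of different efficiency, a futile
#' cycle, an ATP-like cofactor, and a product reachable only through a
#' three-gene heterologous knock-in pathway.
#'
#' @name fixtures
NULL

#' The hand-written core toy model
#'
#' Seven metabolites, ten reactions. Layout:
#' \itemize{
#'   \item `EX_glc`: glucose exchange, bounds (-10, 0) (uptake negative).
#'   \item `UPT`: glc -> A + 0.5 atp, GPR `gU1 and gU2` (both essential).
#'   \item `CNV1`: A -> B, capacity 6, GPR `gE1 or gE2` (isozymes).
#'   \item `CNV3`: A -> B, capacity 4, GPR `gE3`.
#'   \item `CNV2`: A -> 0.5 B + 0.5 C, GPR `gL` (lossy route whose byproduct
#'     C has no sink in the wild type).
#'   \item `BIOMASS`: B -> (objective), `EX_prd`: prd -> , `ATPM`: atp ->.
#'   \item `F1`/`F2`: B <-> Bx futile cycle (bounds 0..50 each way).
#' }
#' The registered knock-in pathway `"bcar"` (genes `GGS1`, `carRP`, `carB`)
#' converts C -> M1 -> M2 -> prd, making the lossy route productive.
#'
#' Closed-form wild-type optimum: uptake 10 splits over CNV1 (6) and CNV3
#' (4), so the FBA growth rate is exactly 10 and product flux is exactly 0.
#' With the knock-in enabled and both `gE` isozymes plus `gE3` deleted, all
#' carbon runs through the lossy route: growth 5, product 5.
#'
#' @return A `stoich_model` with the `"bcar"` pathway registered (not
#'   applied).
#' @export
make_core_model <- function() {
  mets <- c("glc_e", "A", "B", "C", "prd", "Bx", "atp")
  rxns <- c("EX_glc", "UPT", "CNV1", "CNV3", "CNV2", "BIOMASS",
            "EX_prd", "F1", "F2", "ATPM")
  S <- Matrix::Matrix(0, length(mets), length(rxns), sparse = TRUE,
                      dimnames = list(mets, rxns))
  S["glc_e", "EX_glc"] <- -1
  S["glc_e", "UPT"] <- -1; S["A", "UPT"] <- 1; S["atp", "UPT"] <- 0.5
  S["A", "CNV1"] <- -1; S["B", "CNV1"] <- 1
  S["A", "CNV3"] <- -1; S["B", "CNV3"] <- 1
  S["A", "CNV2"] <- -1; S["B", "CNV2"] <- 0.5; S["C", "CNV2"] <- 0.5
  S["B", "BIOMASS"] <- -1
  S["prd", "EX_prd"] <- -1
  S["B", "F1"] <- -1; S["Bx", "F1"] <- 1
  S["Bx", "F2"] <- -1; S["B", "F2"] <- 1
  S["atp", "ATPM"] <- -1

  lb <- c(-10, 0, 0, 0, 0, 0, 0, 0, 0, 0)
  ub <- c(0, 1000, 6, 4, 1000, 1000, 1000, 50, 50, 1000)
  obj <- c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0)

  genes <- c("YALI0A00011g", "YALI0B00022g",  # gU1, gU2: uptake subunits
             "YALI0F00101g", "YALI0F00202g",  # gE1, gE2: CNV1 isozymes
             "YALI0E00303g",                  # gE3
             "YALI0C00404g")                  # gL
  gpr <- list(
    UPT  = parse_gpr("YALI0A00011g and YALI0B00022g"),
    CNV1 = parse_gpr("YALI0F00101g or YALI0F00202g"),
    CNV3 = parse_gpr("YALI0E00303g"),
    CNV2 = parse_gpr("YALI0C00404g")
  )

  bcar <- pathway_definition(
    id = "bcar",
    new_reactions = list(
      list(id = "KI1", stoichiometry = c(C = -1, M1 = 1),
           lb = 0, ub = 1000, gpr = "GGS1"),
      list(id = "KI2", stoichiometry = c(M1 = -1, M2 = 1),
           lb = 0, ub = 1000, gpr = "carRP"),
      list(id = "KI3", stoichiometry = c(M2 = -1, prd = 1),
           lb = 0, ub = 1000, gpr = "carB")
    ),
    new_genes = c("GGS1", "carRP", "carB"),
    new_metabolites = c("M1", "M2")
  )

  stoich_model(
    metabolite_ids = mets, reaction_ids = rxns, S = S,
    lb = lb, ub = ub, obj = obj,
    genes = genes, gpr = gpr,
    biomass_reaction = "BIOMASS",
    carbon_source_exchange = "EX_glc",
    product_reaction = "EX_prd",
    pathways = list(bcar = bcar),
    id = "core_toy"
  )
}

#' Essential genes of the core toy model
#'
#' The two uptake subunits: deleting either abolishes growth by
#' construction.
#' @return Character vector of two gene ids.
#' @export
core_essential_genes <- function() c("YALI0A00011g", "YALI0B00022g")

#' Parameters for the random toy generator
#'
#' @param n_carbon_steps Length of the linear carbon backbone (>= 1).
#' @param n_isozyme_reactions Number of backbone steps whose GPR gains an
#'   OR'd backup gene.
#' @param n_subunit_reactions Number of backbone steps whose GPR gains an
#'   AND'd subunit gene.
#' @param product_pathway_length Reactions in the branch from the backbone
#'   to the secreted product (>= 1).
#' @param essential_fraction Probability that a backbone step has no
#'   fallback route, making its gene essential.
#' @param rng_seed Integer seed; the generator is fully reproducible.
#' @return A `toy_spec`.
#' @export
toy_spec <- function(n_carbon_steps = 3, n_isozyme_reactions = 1,
                     n_subunit_reactions = 1, product_pathway_length = 2,
                     essential_fraction = 0.25, rng_seed = 1L) {
  stopifnot(n_carbon_steps >= 1, n_isozyme_reactions >= 0,
            n_subunit_reactions >= 0, product_pathway_length >= 1,
            essential_fraction >= 0, essential_fraction <= 1)
  structure(list(n_carbon_steps = n_carbon_steps,
                 n_isozyme_reactions = n_isozyme_reactions,
                 n_subunit_reactions = n_subunit_reactions,
                 product_pathway_length = product_pathway_length,
                 essential_fraction = essential_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "toy_spec")
}

random_sgd_gene <- function(k) {
  # synthetic systematic-style names: Y + chromosome letter + arm + ORF + strand
  sprintf("Y%s%s%03d%s",
          sample(LETTERS[1:16], k, replace = TRUE),
          sample(c("L", "R"), k, replace = TRUE),
          sample(100:999, k),
          sample(c("W", "C"), k, replace = TRUE))
}

#' Generate a random toy model
#'
#' A linear carbon backbone with gene-gated steps, optional isozyme/subunit
#' GPR structure, ungated lower-yield fallback routes on non-essential
#' steps, and a lossy product branch coupled to one step's fallback so that
#' deleting that step's gene growth-couples production. Gene identifiers
#' follow the 16-chromosome systematic naming convention so locus parsing
#' is exercised end-to-end. Resamples (bounded retries) until the wild type
#' grows.
#'
#' @param spec A [toy_spec()].
#' @return A `stoich_model` with attribute `"essential_genes"`.
#' @export
make_random_toy <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  for (attempt in seq_len(25L)) {
    model <- with_seed(spec$rng_seed + 7919L * (attempt - 1L),
                       build_random_toy(spec))
    wt <- fba(model)
    if (wt$status == "optimal" && wt$objective_value > 1e-6) return(model)
  }
  stop("random toy generation retry budget exhausted", call. = FALSE)
}

build_random_toy <- function(spec) {
  k <- spec$n_carbon_steps
  uptake_cap <- round(stats::runif(1, 5, 15), 2)

  mets <- c("carb_e", paste0("M", 0:k), "P0", "prd")
  if (spec$product_pathway_length > 1) {
    mets <- c(mets, paste0("P", seq_len(spec$product_pathway_length - 1L)))
  }
  step_genes <- random_sgd_gene(k)
  essential <- stats::runif(k) < spec$essential_fraction
  nones <- which(!essential)
  branch_step <- if (length(nones)) safe_sample(nones, 1L)
                 else safe_sample(seq_len(k), 1L)

  rxn <- list()
  addr <- function(id, st, lb, ub, gpr = NULL, obj = 0) {
    rxn[[length(rxn) + 1L]] <<- list(id = id, st = st, lb = lb, ub = ub,
                                     gpr = gpr, obj = obj)
  }
  addr("EX_carb", c(carb_e = -1), -uptake_cap, 0)
  addr("UPT", c(carb_e = -1, M0 = 1), 0, 1000)
  for (i in seq_len(k)) {
    from <- paste0("M", i - 1L); to <- paste0("M", i)
    yield <- round(stats::runif(1, 0.7, 1), 2)
    st <- stats::setNames(c(-1, yield), c(from, to))
    addr(paste0("STEP", i), st, 0, 1000, gpr = step_genes[i])
    if (!essential[i]) {
      fb_yield <- round(yield * stats::runif(1, 0.4, 0.8), 2)
      if (i == branch_step) {
        leak <- round(stats::runif(1, 0.2, 0.5), 2)
        st_fb <- stats::setNames(c(-1, fb_yield, leak), c(from, to, "P0"))
      } else {
        st_fb <- stats::setNames(c(-1, fb_yield), c(from, to))
      }
      addr(paste0("FB", i), st_fb, 0, 1000)
    }
  }
  addr("BIOMASS", stats::setNames(-1, paste0("M", k)), 0, 1000, obj = 1)
  # product branch: P0 -> ... -> prd
  pchain <- c("P0", if (spec$product_pathway_length > 1)
                paste0("P", seq_len(spec$product_pathway_length - 1L)), "prd")
  branch_genes <- random_sgd_gene(spec$product_pathway_length)
  for (i in seq_len(spec$product_pathway_length)) {
    st <- stats::setNames(c(-1, 1), c(pchain[i], pchain[i + 1L]))
    addr(paste0("PB", i), st, 0, 1000, gpr = branch_genes[i])
  }
  addr("EX_prd", c(prd = -1), 0, 1000)

  # decorate GPRs: isozymes (OR) and subunits (AND) on random backbone steps
  iso_genes <- random_sgd_gene(spec$n_isozyme_reactions)
  sub_genes <- random_sgd_gene(spec$n_subunit_reactions)
  iso_steps <- if (spec$n_isozyme_reactions > 0)
    sample(seq_len(k), min(spec$n_isozyme_reactions, k)) else integer()
  sub_steps <- if (spec$n_subunit_reactions > 0)
    sample(seq_len(k), min(spec$n_subunit_reactions, k)) else integer()
  gpr_str <- stats::setNames(step_genes, paste0("STEP", seq_len(k)))
  for (j in seq_along(iso_steps)) {
    s <- iso_steps[j]
    gpr_str[paste0("STEP", s)] <-
      sprintf("%s or %s", gpr_str[paste0("STEP", s)], iso_genes[j])
  }
  for (j in seq_along(sub_steps)) {
    s <- sub_steps[j]
    gpr_str[paste0("STEP", s)] <-
      sprintf("(%s) and %s", gpr_str[paste0("STEP", s)], sub_genes[j])
  }

  ids <- vapply(rxn, `[[`, character(1), "id")
  S <- Matrix::Matrix(0, length(mets), length(ids), sparse = TRUE,
                      dimnames = list(mets, ids))
  for (j in seq_along(rxn)) {
    S[match(names(rxn[[j]]$st), mets), j] <- as.numeric(rxn[[j]]$st)
  }
  gpr <- list()
  for (j in seq_along(rxn)) {
    id <- ids[j]
    if (id %in% names(gpr_str)) gpr[[id]] <- parse_gpr(gpr_str[[id]])
    else if (!is.null(rxn[[j]]$gpr)) gpr[[id]] <- parse_gpr(rxn[[j]]$gpr)
  }
  genes <- unique(c(step_genes, branch_genes,
                    iso_genes[seq_along(iso_steps)],
                    sub_genes[seq_along(sub_steps)]))
  model <- stoich_model(
    metabolite_ids = mets, reaction_ids = ids, S = S,
    lb = vapply(rxn, `[[`, numeric(1), "lb"),
    ub = vapply(rxn, `[[`, numeric(1), "ub"),
    obj = vapply(rxn, `[[`, numeric(1), "obj"),
    genes = genes, gpr = gpr,
    biomass_reaction = "BIOMASS",
    carbon_source_exchange = "EX_carb",
    product_reaction = "EX_prd",
    id = sprintf("random_toy_seed%d", spec$rng_seed)
  )
  attr(model, "essential_genes") <- step_genes[essential]
  model
}

safe_sample <- function(x, n) x[sample.int(length(x), n)]

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
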