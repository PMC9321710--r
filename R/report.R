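#' Strain tables and archive export
#'
#' Reporting mirrors the strain tables of growth-coupled design studies: a
#' wild-type row first, then one row per archived strain with biomass (and
#' WT-variation %), product flux, cofactor production flux-sums (and
#' WT-variation %), knockout count and list, and the chromosome
#' co-location score, ordered by ascending knockout count.
#'
#' @name reporting
NULL

#' Build the strain report table
#'
#' @param archive A `pareto_archive` from [run_moea()] or
#'   [brute_force_front()].
#' @param digits Decimal places for the percent columns (default 2, as
#'   printed in strain tables).
#' @return A data frame: WT row first, strains sorted by ascending knockout
#'   count; columns `strain`, `biomass`, `biomass_wt_var_pct`,
#'   `product_flux`, `yield`, `productivity`, one pair of columns per
#'   reported cofactor, `n_knockouts`, `knockouts`, `chromosome_score`.
#' @export
strain_table <- function(archive, digits = 2) {
  stopifnot(inherits(archive, "pareto_archive"))
  if (!length(archive$strains)) stop("empty archive", call. = FALSE)
  wt <- archive$wt
  cof_ids <- names(wt$metrics$cofactor_production)
  strains <- archive$strains[order(vapply(archive$strains, function(s)
    length(s$design$deletions), numeric(1)))]

  row_of <- function(ev, label) {
    m <- ev$metrics
    out <- data.frame(
      strain = label,
      biomass = m$growth_rate,
      biomass_wt_var_pct = round(
        wt_variation(m$growth_rate, wt$metrics$growth_rate), digits),
      product_flux = m$product_flux,
      yield = m$yield,
      productivity = m$productivity,
      stringsAsFactors = FALSE)
    for (cid in cof_ids) {
      out[[paste0(cid, "_production")]] <- m$cofactor_production[[cid]]
      out[[paste0(cid, "_wt_var_pct")]] <- round(
        wt_variation(m$cofactor_production[[cid]],
                     wt$metrics$cofactor_production[[cid]]), digits)
    }
    out$n_knockouts <- length(ev$design$deletions)
    out$knockouts <- paste(ev$design$deletions, collapse = "; ")
    out$chromosome_score <- same_chromosome_score(ev$design)
    out
  }
  rows <- c(list(row_of(wt, "WT")),
            lapply(seq_along(strains), function(i)
              row_of(strains[[i]], as.character(i))))
  do.call(rbind, rows)
}

#' Export a Pareto archive
#'
#' JSON export is lossless (designs, objectives, metrics scalars) and can
#' be read back with [import_front()]; CSV export is the human-readable
#' [strain_table()].
#'
#' @param archive A `pareto_archive`.
#' @param path Output file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_front <- function(archive, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(strain_table(archive), path, row.names = FALSE)
    return(invisible(path))
  }
  ser <- function(ev) list(
    deletions = as.list(ev$design$deletions),
    knockins = as.list(ev$design$knockins),
    objectives = as.list(ev$objectives),
    feasible = ev$feasible,
    metrics = list(
      growth_rate = ev$metrics$growth_rate,
      product_flux = ev$metrics$product_flux,
      carbon_uptake = ev$metrics$carbon_uptake,
      yield = ev$metrics$yield,
      productivity = ev$metrics$productivity,
      cofactor_production = as.list(ev$metrics$cofactor_production)
    )
  )
  doc <- list(
    objectives = as.list(archive$config$objectives),
    directions = as.list(archive$config$directions),
    wt = ser(archive$wt),
    strains = lapply(archive$strains, ser)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a JSON archive export
#'
#' @param path File written by [export_front()] with `format = "json"`.
#' @return A list with `objectives`, `directions`, `wt` and `strains`
#'   (each strain: `design`, `objectives`, `metrics`).
#' @export
import_front <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  de <- function(x) list(
    design = strain_design(deletions = unlist(x$deletions) %||% character(),
                           knockins = unlist(x$knockins) %||% character()),
    objectives = unlist(x$objectives),
    feasible = x$feasible,
    metrics = lapply(x$metrics, function(v)
      if (is.list(v)) unlist(v) else v)
  )
  list(objectives = unlist(doc$objectives),
       directions = unlist(doc$directions),
       wt = de(doc$wt),
       strains = lapply(doc$strains, de))
}
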