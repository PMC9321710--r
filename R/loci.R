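#' Chromosome loci of genes
#'
#' Knockouts co-located on one chromosome are easier to realize in vitro,
#' so the search can score deletion sets by chromosome co-location. Two
#' identifier conventions are decoded directly:
#' \itemize{
#'   \item `"yali"` — *Y. lipolytica* style (`YALI0F17996g`): the sixth
#'     character is the chromosome letter.
#'   \item `"sgd-systematic"` — budding-yeast systematic names
#'     (`YPR160W`): second letter maps A..P to chromosomes I..XVI, the
#'     third letter gives the left/right arm, a trailing W/C gives the
#'     Watson/Crick strand.
#' }
#' Anything else falls back to the model's custom gene-to-chromosome map;
#' identifiers matching neither yield an unknown locus (not an error).
#'
#' @name loci
NULL

ROMAN_16 <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
              "XI", "XII", "XIII", "XIV", "XV", "XVI")

gene_locus <- function(gene_id, chromosome = NA_character_,
                       arm = "unknown", strand = "unknown") {
  structure(list(gene_id = gene_id, chromosome = chromosome,
                 arm = arm, strand = strand), class = "gene_locus")
}

#' @export
print.gene_locus <- function(x, ...) {
  cat(sprintf("<gene_locus> %s: chromosome %s (arm %s, strand %s)\n",
              x$gene_id, x$chromosome, x$arm, x$strand))
  invisible(x)
}

#' Locate a gene on a chromosome from its identifier
#'
#' @param gene_id Gene identifier (non-empty string).
#' @param convention One of `"auto"`, `"yali"`, `"sgd-systematic"`,
#'   `"custom-map"`. `"auto"` tries yali, then sgd-systematic, then the
#'   custom map.
#' @param custom_map Optional named character vector gene -> chromosome
#'   label (e.g. a model's `gene_chromosome`).
#' @return A `gene_locus`; `chromosome` is `NA` when the identifier matches
#'   no convention and is absent from the map.
#' @examples
#' chromosome_of("YALI0F17996g")$chromosome   # "F"
#' chromosome_of("YPR160W")                   # XVI, right arm, Watson
#' @export
chromosome_of <- function(gene_id,
                          convention = c("auto", "yali", "sgd-systematic",
                                         "custom-map"),
                          custom_map = NULL) {
  convention <- match.arg(convention)
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))

  try_yali <- function() {
    if (grepl("^YALI[0-9A-Z][A-Z][0-9]+g?$", gene_id)) {
      gene_locus(gene_id, chromosome = substr(gene_id, 6, 6))
    } else NULL
  }
  try_sgd <- function() {
    if (grepl("^Y[A-P][LR][0-9]{3}[WC]?(-[A-Z])?$", gene_id)) {
      chr_idx <- match(substr(gene_id, 2, 2), LETTERS[1:16])
      arm <- if (substr(gene_id, 3, 3) == "L") "left" else "right"
      last <- substr(gene_id, 7, 7)
      strand <- if (last == "W") "Watson" else if (last == "C") "Crick"
                else "unknown"
      gene_locus(gene_id, chromosome = ROMAN_16[chr_idx],
                 arm = arm, strand = strand)
    } else NULL
  }
  try_map <- function() {
    if (!is.null(custom_map) && gene_id %in% names(custom_map)) {
      gene_locus(gene_id, chromosome = unname(custom_map[[gene_id]]))
    } else NULL
  }

  res <- switch(convention,
    yali = try_yali(),
    `sgd-systematic` = try_sgd(),
    `custom-map` = try_map(),
    auto = try_yali() %||% try_sgd() %||% try_map()
  )
  res %||% gene_locus(gene_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chromosome co-location score of a deletion set
#'
#' Fraction of knockouts lying on the modal chromosome: deletions with an
#' unknown locus count in the denominator but never in the numerator. A
#' design with zero deletions scores 1 by convention (vacuously
#' co-located). Enters the MOEA as a maximized secondary objective.
#'
#' @param design A [strain_design()] (or a character vector of gene ids).
#' @param convention,custom_map Passed to [chromosome_of()].
#' @return Score in (0, 1].
#' @examples
#' same_chromosome_score(c("YALI0A05379g", "YALI0F11935g", "YALI0F17996g"))
#' # 2/3: one knockout on chromosome A, two on F
#' @export
same_chromosome_score <- function(design, convention = "auto",
                                  custom_map = NULL) {
  genes <- if (inherits(design, "strain_design")) design$deletions
           else as.character(design)
  if (length(genes) == 0L) return(1)
  chroms <- vapply(genes, function(g)
    chromosome_of(g, convention, custom_map)$chromosome, character(1))
  known <- chroms[!is.na(chroms)]
  if (!length(known)) return(0)
  max(table(known)) / length(genes)
}
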