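#' Describe a full diallel mating design
#'
#' A full (Griffing Method I) diallel over `n` parents contains all `n^2`
#' ordered (mother, father) genotypes: the `n` selfs plus both reciprocals of
#' every pairwise cross. Phenotyping is replicated at two temperatures with
#' `b_replicates` biological replicates per genotype per temperature, each
#' contributing at least `min_flowers` individual flowers.
#'
#' @param parents Character vector of parent (accession) identifiers; order is
#'   kept and used for deterministic tie-breaks.
#' @param temperatures Numeric pair `(T_low, T_high)` in degrees Celsius.
#' @param b_replicates Integer, biological replicates per genotype per
#'   temperature.
#' @param min_flowers Integer, minimum flowers measured per replicate.
#' @return An object of class `diallel_design`.
#' @examples
#' diallel_design(paste0("P", 1:4))
#' @export
diallel_design <- function(parents, temperatures = c(17, 23),
                           b_replicates = 2L, min_flowers = 6L) {
  parents <- as.character(parents)
  if (anyDuplicated(parents)) stop("duplicated parent identifiers")
  if (length(parents) < 2L) stop("a diallel design needs at least 2 parents")
  if (length(temperatures) != 2L || !is.numeric(temperatures))
    stop("temperatures must be a numeric pair (T_low, T_high)")
  if (temperatures[1] >= temperatures[2])
    stop("temperatures must be ordered (T_low, T_high)")
  b_replicates <- as.integer(b_replicates)
  min_flowers <- as.integer(min_flowers)
  if (b_replicates < 1L) stop("b_replicates must be >= 1")
  if (min_flowers < 1L) stop("min_flowers must be >= 1")
  structure(
    list(parents = parents,
         n_parents = length(parents),
         temperatures = as.numeric(temperatures),
         b_replicates = b_replicates,
         min_flowers = min_flowers),
    class = "diallel_design")
}

#' @export
print.diallel_design <- function(x, ...) {
  cat("Full diallel design (Griffing Method I)\n")
  cat(sprintf("  %d parents -> %d ordered genotypes (incl. %d selfs)\n",
              x$n_parents, x$n_parents^2, x$n_parents))
  cat(sprintf("  temperatures: %g / %g degC; %d biological replicate(s) each; >= %d flowers per replicate\n",
              x$temperatures[1], x$temperatures[2], x$b_replicates,
              x$min_flowers))
  cat(sprintf("  parents: %s\n", paste(x$parents, collapse = ", ")))
  invisible(x)
}

#' All ordered genotype cells of a design
#'
#' @param design A `diallel_design`.
#' @param selfs Include self genotypes (mother == father)?
#' @return Data frame with columns `mother`, `father`.
#' @export
design_cells <- function(design, selfs = TRUE) {
  stopifnot(inherits(design, "diallel_design"))
  g <- expand.grid(father = design$parents, mother = design$parents,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("mother", "father")]
  if (!selfs) g <- g[g$mother != g$father, , drop = FALSE]
  rownames(g) <- NULL
  g
}

genotype_id <- function(mother, father) paste(mother, father, sep = " x ")
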