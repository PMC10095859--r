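#' Read and validate a per-flower phenotype table
#'
#' Reads a long-format CSV/TSV of per-flower diameter measurements keyed by
#' (mother, father, temperature, biological replicate, flower) and validates
#' every record against the declared diallel design. The canonical dialect
#' carries a `diameter_mm` column holding the per-flower mean of the two
#' measured diagonals; a raw dialect with `diag1_mm`/`diag2_mm` columns is
#' also accepted and averaged on read.
#'
#' @param path CSV (`.csv`) or TSV (`.tsv`/`.txt`/`.tab`) file with header
#'   columns `mother`, `father`, `temperature_C`, `bio_replicate`,
#'   `flower_id`, and either `diameter_mm` or `diag1_mm` + `diag2_mm`.
#' @param design A [diallel_design()]; parents and temperatures in the file
#'   must belong to it.
#' @return Data frame of validated flower records with columns `mother`,
#'   `father`, `temperature_C`, `bio_replicate`, `flower_id`, `diameter_mm`.
#' @export
read_phenotypes <- function(path, design) {
  stopifnot(inherits(design, "diallel_design"))
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = TRUE,
                           colClasses = "character", fileEncoding = "UTF-8")
  needed <- c("mother", "father", "temperature_C", "bio_replicate",
              "flower_id")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  has_mean <- "diameter_mm" %in% names(raw)
  has_diag <- all(c("diag1_mm", "diag2_mm") %in% names(raw))
  if (!has_mean && !has_diag)
    stop("format error: missing column diameter_mm (or diag1_mm + diag2_mm)")

  num_col <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    bad <- c(bad, which(is.na(raw[[col]]) | !nzchar(raw[[col]])))
    if (length(bad))
      stop(sprintf("parse error: non-numeric %s at data row %d", col,
                   min(bad)))
    v
  }
  diameter <- if (has_mean) num_col("diameter_mm")
              else (num_col("diag1_mm") + num_col("diag2_mm")) / 2
  rec <- data.frame(mother = raw$mother,
                    father = raw$father,
                    temperature_C = num_col("temperature_C"),
                    bio_replicate = as.integer(num_col("bio_replicate")),
                    flower_id = as.integer(num_col("flower_id")),
                    diameter_mm = diameter,
                    stringsAsFactors = FALSE)
  validate_phenotypes(rec, design)
}

#' Validate flower records against a design
#'
#' @param records Data frame as returned by [read_phenotypes()].
#' @param design A [diallel_design()].
#' @return The records, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_phenotypes <- function(records, design) {
  stopifnot(inherits(design, "diallel_design"))
  unknown <- setdiff(unique(c(records$mother, records$father)),
                     design$parents)
  if (length(unknown))
    stop("validation error: unknown parent id(s): ",
         paste(unknown, collapse = ", "))
  bad_t <- setdiff(unique(records$temperature_C), design$temperatures)
  if (length(bad_t))
    stop("validation error: temperature(s) outside the design pair: ",
         paste(bad_t, collapse = ", "))
  if (any(!is.finite(records$diameter_mm) | records$diameter_mm <= 0)) {
    i <- which(!is.finite(records$diameter_mm) | records$diameter_mm <= 0)[1]
    stop(sprintf("validation error: non-positive diameter_mm at row %d", i))
  }
  if (any(records$bio_replicate < 1L | records$bio_replicate > design$b_replicates))
    stop("validation error: bio_replicate outside 1..",
         design$b_replicates)
  records
}

#' Write a per-flower phenotype table
#'
#' Inverse of [read_phenotypes()]: writes the canonical dialect so that
#' `read_phenotypes(write_phenotypes(x), design)` round-trips. Floats are
#' written with full precision (>= 10 significant digits).
#'
#' @param records Validated flower records.
#' @param path Output path; `.csv` writes comma-separated, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(records, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- records[, c("mother", "father", "temperature_C", "bio_replicate",
                     "flower_id", "diameter_mm")]
  out$diameter_mm <- format_float(out$diameter_mm)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

format_float <- function(x) formatC(x, digits = 15, format = "g")

#' Report missing or under-replicated design cells
#'
#' Checks every (mother, father, temperature, replicate) cell of the design
#' against the records: a full Method I analysis needs all `n^2` genotypes
#' present, and each replicate cell should carry at least `min_flowers`
#' measurements.
#'
#' @param records Validated flower records.
#' @param design A [diallel_design()].
#' @return List with `missing_genotypes` (data frame mother/father),
#'   `under_replicated` (data frame mother/father/temperature_C/
#'   bio_replicate/n_flowers for cells with `0 < n < min_flowers` or absent
#'   cells of present genotypes), and `complete` (TRUE iff both are empty).
#' @export
check_design_completeness <- function(records, design) {
  stopifnot(inherits(design, "diallel_design"))
  expected <- expand.grid(bio_replicate = seq_len(design$b_replicates),
                          temperature_C = design$temperatures,
                          father = design$parents,
                          mother = design$parents,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expected <- expected[, c("mother", "father", "temperature_C",
                           "bio_replicate")]
  key <- function(d) paste(d$mother, d$father, d$temperature_C,
                           d$bio_replicate, sep = "\r")
  counts <- table(key(records))
  expected$n_flowers <- as.integer(counts[key(expected)])
  expected$n_flowers[is.na(expected$n_flowers)] <- 0L

  geno_tot <- tapply(expected$n_flowers,
                     genotype_id(expected$mother, expected$father), sum)
  cells <- design_cells(design)
  absent <- geno_tot[genotype_id(cells$mother, cells$father)] == 0
  missing_genotypes <- cells[absent, , drop = FALSE]
  rownames(missing_genotypes) <- NULL

  present_geno <- !(genotype_id(expected$mother, expected$father) %in%
                      genotype_id(missing_genotypes$mother,
                                  missing_genotypes$father))
  under <- expected[present_geno & expected$n_flowers < design$min_flowers, ,
                    drop = FALSE]
  rownames(under) <- NULL
  list(missing_genotypes = missing_genotypes,
       under_replicated = under,
       complete = nrow(missing_genotypes) == 0L && nrow(under) == 0L)
}
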