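# Tabular containers: species x measurement table and species x binary
# microhabitat descriptor matrix. Both are plain numeric matrices with species
# as rownames, carrying a small amount of validated metadata.

#' Construct a trait table
#'
#' A trait table is a species x variable numeric matrix with a processing
#' `stage` recording where it sits in the measurement workflow: `"raw"`
#' (caliper lengths, mm), `"reduced"` (after variable reduction, mm), `"log"`
#' (natural log scale) or `"size_corrected"` (residuals against isometric
#' size).
#'
#' @param values numeric matrix, species in rows.
#' @param species_ids character vector of unique species labels; defaults to
#'   `rownames(values)`.
#' @param variable_names column labels; defaults to `colnames(values)`.
#' @param stage one of `"raw"`, `"reduced"`, `"log"`, `"size_corrected"`.
#' @return A `trait_table`: a numeric matrix with class and `stage` attributes.
#' @export
trait_table <- function(values, species_ids = rownames(values),
                        variable_names = colnames(values),
                        stage = c("raw", "reduced", "log", "size_corrected")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  species_ids <- trimws(as.character(species_ids))
  if (is.null(species_ids) || length(species_ids) != nrow(values))
    stop("species_ids must label every row")
  if (anyDuplicated(species_ids))
    stop("duplicate species labels: ",
         paste(unique(species_ids[duplicated(species_ids)]), collapse = ", "))
  if (length(variable_names) != ncol(values))
    stop("variable_names length must match the number of columns")
  if (anyNA(values) || any(!is.finite(values)))
    stop("trait table contains missing or non-finite cells")
  if (stage %in% c("raw", "reduced") && any(values <= 0))
    stop("raw/reduced measurements must be strictly positive")
  dimnames(values) <- list(species_ids, variable_names)
  structure(values, class = c("trait_table", "matrix", "array"), stage = stage)
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("Trait table: %d species x %d variables (stage: %s)\n",
              nrow(x), ncol(x), trait_stage(x)))
  print(utils::head(unclass(x), 4L))
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}

#' Processing stage of a trait table
#' @param x a [trait_table()].
#' @return The stage string.
#' @export
trait_stage <- function(x) attr(x, "stage")

#' Construct a microhabitat descriptor matrix
#'
#' Binary presence records (1 = reported use, 0 = no report) of species across
#' microhabitat descriptors such as "loose sand" or "rock crevices". Species
#' with no recorded microhabitat are rejected: an all-zero row carries no
#' ecological information and breaks Jaccard distances.
#'
#' @param values matrix of 0/1 values, species in rows.
#' @param species_ids,descriptor_names row and column labels.
#' @return A `microhabitat_matrix` (integer matrix subclass).
#' @export
microhabitat_matrix <- function(values, species_ids = rownames(values),
                                descriptor_names = colnames(values)) {
  values <- as.matrix(values)
  species_ids <- trimws(as.character(species_ids))
  if (length(species_ids) != nrow(values)) stop("species_ids must label every row")
  if (anyDuplicated(species_ids)) stop("duplicate species labels")
  if (length(descriptor_names) != ncol(values) || anyDuplicated(descriptor_names))
    stop("descriptor names must be unique and label every column")
  if (anyNA(values) || !all(values %in% c(0, 1)))
    stop("microhabitat entries must all be 0 or 1")
  zero <- rowSums(values) == 0
  if (any(zero))
    stop("species has no recorded microhabitat: ",
         paste(species_ids[zero], collapse = ", "))
  storage.mode(values) <- "integer"
  dimnames(values) <- list(species_ids, descriptor_names)
  structure(values, class = c("microhabitat_matrix", "matrix", "array"))
}

#' @export
print.microhabitat_matrix <- function(x, ...) {
  cat(sprintf("Microhabitat matrix: %d species x %d descriptors\n",
              nrow(x), ncol(x)))
  print(utils::head(unclass(x), 4L))
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}

#' Read a species x measurement CSV
#'
#' Expects a header row of variable names and species labels in the first
#' column; comma separated, decimal point, UTF-8.
#'
#' @param path CSV file path.
#' @param stage processing stage of the stored values (see [trait_table()]).
#' @return A [trait_table()] with row order preserved from the file.
#' @export
read_trait_table <- function(path, stage = "raw") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("expected species labels plus at least one variable")
  species <- trimws(as.character(df[[1]]))
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    suppressWarnings(storage.mode(vals) <- "double")
    if (anyNA(vals)) stop("non-numeric cell in trait table ", path)
  }
  trait_table(vals, species_ids = species,
              variable_names = colnames(df)[-1], stage = stage)
}

#' Read a species x binary microhabitat CSV
#'
#' @param path CSV with species labels in the first column and 0/1 cells.
#' @return A [microhabitat_matrix()].
#' @export
read_microhabitat_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("expected species labels plus at least one descriptor")
  species <- trimws(as.character(df[[1]]))
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) stop("non-numeric cell in microhabitat table ", path)
  microhabitat_matrix(vals, species_ids = species,
                      descriptor_names = colnames(df)[-1])
}

#' Write a matrix-like table to CSV with a species column
#'
#' @param x matrix with species rownames.
#' @param path output path.
#' @param id_name header for the species column.
#' @export
write_species_csv <- function(x, path, id_name = "species") {
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_name, colnames(x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
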